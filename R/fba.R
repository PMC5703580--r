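## Growth-maximizing FBA with crowding costs and culture-coupled uptake
## bounds. The linear program at a given xi = X/D:
##
##   max z   s.t.  S (r+ - r-) + u = e + y z        (metabolite balance)
##                 sum(a+ r+ + a- r-) <= C          (crowding budget)
##                 0 <= r+ <= [ub>0], 0 <= r- <= [lb<0]
##                 -L_i <= u_i <= min{V_i, c_i/xi}  (culture coupling)
##
## Exchanges are split into uptake and secretion parts so every LP variable
## is nonnegative.

## Per-metabolite uptake upper bound min{V_i, c_i/xi}, with the xi -> 0
## limit convention: a metabolite absent from the medium can never be
## consumed, one present (even at infinite concentration) is bounded by V.
uptake_bound <- function(V, conc, xi) {
  ifelse(xi == 0 | is.infinite(conc),
         ifelse(conc > 0, V, 0),
         pmin(V, conc / xi))
}

fba_lp <- function(model, med, xi, uptake_ub = NULL) {
  S <- model$S
  nr <- length(model$reactions)
  ext <- model$external
  nx <- length(ext)
  conc <- medium_conc(med, ext)
  ub_up <- if (is.null(uptake_ub)) uptake_bound(model$uptake_max, conc, xi)
           else pmin(model$uptake_max, uptake_ub)

  nvar <- 2 * nr + 2 * nx + 1
  iz <- nvar
  Ux <- matrix(0, nrow(S), nx)
  Ux[cbind(match(ext, model$metabolites), seq_len(nx))] <- 1
  Aeq <- cbind(S, -S, Ux, -Ux, -model$biomass)
  beq <- model$maintenance
  cost_row <- c(model$cost_fwd, model$cost_rev, rep(0, 2 * nx + 1))
  A <- rbind(Aeq, cost_row)
  b <- c(beq, model$budget)
  sense <- c(rep("=", nrow(Aeq)), "<=")

  ub <- c(ifelse(model$ub > 0, Inf, 0),   # r+
          ifelse(model$lb < 0, Inf, 0),   # r-
          ub_up,                          # uptake parts
          model$secretion,                # secretion parts
          Inf)                            # z
  names(ub) <- var_names <- c(paste0(model$reactions, "+"),
                              paste0(model$reactions, "-"),
                              paste0("uptake_", ext),
                              paste0("secretion_", ext), "z")
  list(A = A, b = b, sense = sense, ub = ub, iz = iz, nr = nr, nx = nx,
       ext = ext, conc = conc, var_names = var_names, cost = cost_row)
}

lp_to_solution <- function(model, lp, x, status, xi) {
  nr <- lp$nr; nx <- lp$nx
  r_fwd <- x[seq_len(nr)]
  r_rev <- x[nr + seq_len(nr)]
  u <- x[2 * nr + seq_len(nx)] - x[2 * nr + nx + seq_len(nx)]
  names(r_fwd) <- names(r_rev) <- model$reactions
  names(u) <- lp$ext
  structure(list(
    fluxes = r_fwd - r_rev, r_fwd = r_fwd, r_rev = r_rev,
    exchanges = u, z = x[lp$iz],
    cost = sum(model$cost_fwd * r_fwd + model$cost_rev * r_rev),
    status = status, xi = xi
  ), class = "flux_solution")
}

infeasible_solution <- function(model, xi) {
  z0 <- rep(NA_real_, length(model$reactions)); names(z0) <- model$reactions
  u0 <- rep(NA_real_, length(model$external)); names(u0) <- model$external
  structure(list(fluxes = z0, r_fwd = z0, r_rev = z0, exchanges = u0,
                 z = NA_real_, cost = NA_real_, status = "infeasible",
                 xi = xi), class = "flux_solution")
}

#' Solve the growth-maximizing flux balance problem at a given xi
#'
#' Maximizes the biomass synthesis rate z subject to metabolite balance
#' (including maintenance and biomass drains), the molecular-crowding cost
#' budget, reversibility bounds, and culture-coupled uptake bounds
#' u_i <= min\{V_i, c_i/xi\}, where xi = X/D couples intracellular
#' metabolism to the bioreactor. Among all growth-optimal flux vectors the
#' one of minimum crowding cost is returned (lexicographic selection, see
#' [minimize_cost_at_optimum()]).
#'
#' @param model a [metabolic_model()].
#' @param med a [medium()].
#' @param xi nonnegative scalar, gDW h/L. `xi = 0` is the nutrient-excess
#'   limit: the uptake bound is V_i for metabolites present in the medium and
#'   0 for absent ones.
#' @param lexicographic run the second cost-minimization stage (default TRUE).
#' @param uptake_ub optional named vector of per-metabolite uptake caps that
#'   replace c_i/xi (used by the dynamic simulator, where availability is
#'   s_i/(X dt) rather than the steady-state ratio).
#' @return object of class `flux_solution` with elements `fluxes` (net r_k),
#'   `r_fwd`, `r_rev`, `exchanges` (u_i, positive = consumption), `z`
#'   (biomass rate, 1/h), `cost` (realized crowding cost), `status`
#'   ("optimal" or "infeasible"). Infeasibility signals xi beyond the medium
#'   depth and is reported in the status flag, not as an error; an unbounded
#'   program (a missing bound or cost) is a hard error naming the unbounded
#'   direction.
#' @examples
#' tm <- toy_as_generic_model()
#' sol <- solve_fba(tm$model, tm$medium, xi = 0)
#' sol$exchanges  # S consumed at V, waste secreted
#' @export
solve_fba <- function(model, med, xi, lexicographic = TRUE,
                      uptake_ub = NULL) {
  stopifnot(xi >= 0)
  lp <- fba_lp(model, med, xi, uptake_ub = uptake_ub)
  obj <- numeric(length(lp$ub)); obj[lp$iz] <- 1
  res <- solve_lp(obj, lp$A, lp$b, lp$sense, ub = lp$ub, maximize = TRUE)
  if (res$status == "infeasible") return(infeasible_solution(model, xi))
  if (res$status == "unbounded") {
    dir <- if (res$unbounded_var <= length(lp$var_names))
      lp$var_names[res$unbounded_var] else "internal slack"
    stop("growth objective is unbounded along direction '", dir,
         "': add a bound or cost to the model")
  }
  if (!lexicographic) return(lp_to_solution(model, lp, res$x, "optimal", xi))
  minimize_cost_at_optimum(model, med, xi, res$objval, uptake_ub = uptake_ub)
}

#' Minimize crowding cost among growth-optimal flux vectors
#'
#' Second stage of the lexicographic solve: with the biomass rate pinned to
#' the first-stage optimum (relative tolerance 1e-11), minimizes the
#' realized crowding cost. Resolves degenerate alternate optima in favor of
#' the cheapest flux routing.
#'
#' @inheritParams solve_fba
#' @param z_opt the growth optimum returned by the first stage.
#' @return a `flux_solution` with z = z_opt and minimal cost.
#' @export
minimize_cost_at_optimum <- function(model, med, xi, z_opt,
                                     uptake_ub = NULL) {
  lp <- fba_lp(model, med, xi, uptake_ub = uptake_ub)
  lb <- numeric(length(lp$ub))
  lb[lp$iz] <- z_opt * (1 - 1e-11) - 1e-15
  res <- solve_lp(lp$cost, lp$A, lp$b, lp$sense, lb = lb, ub = lp$ub)
  if (res$status != "optimal")
    stop("cost-minimization stage ", res$status,
         " at fixed z = ", format(z_opt), "; inconsistent two-stage setup")
  lp_to_solution(model, lp, res$x, "optimal", xi)
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> status:", x$status)
  if (x$status == "optimal")
    cat("  z =", format(x$z), "1/h  cost =", format(x$cost))
  cat("  (xi =", format(x$xi), "gDW h/L)\n")
  invisible(x)
}

#' Check a flux solution against every model constraint
#'
#' Recomputes residuals of the metabolite balances, the crowding budget, the
#' reversibility bounds and the culture-coupled exchange bounds for a solved
#' flux distribution. Intended as an independent audit of solver output.
#'
#' @inheritParams solve_fba
#' @param sol a `flux_solution` with status "optimal".
#' @param tol absolute residual tolerance (model units), default 1e-6.
#' @return data frame of violations (constraint, id, residual, tolerance);
#'   zero rows when the solution satisfies everything within `tol`.
#' @export
validate_solution <- function(model, med, xi, sol, tol = 1e-6) {
  stopifnot(inherits(sol, "flux_solution"), sol$status == "optimal")
  viol <- list()
  add <- function(constraint, id, residual)
    viol[[length(viol) + 1]] <<- data.frame(
      constraint = constraint, id = id, residual = residual, tolerance = tol)

  u_full <- rep(0, length(model$metabolites))
  names(u_full) <- model$metabolites
  u_full[names(sol$exchanges)] <- sol$exchanges
  bal <- as.vector(model$S %*% sol$fluxes) + u_full -
    model$maintenance - model$biomass * sol$z
  for (i in which(abs(bal) > tol))
    add("balance", model$metabolites[i], abs(bal[i]))

  alpha <- sum(model$cost_fwd * sol$r_fwd + model$cost_rev * sol$r_rev)
  if (alpha > model$budget + tol)
    add("crowding_budget", "alpha", alpha - model$budget)

  lo <- sol$fluxes - model$lb; hi <- model$ub - sol$fluxes
  for (k in which(lo < -tol)) add("reversibility_lb", model$reactions[k], -lo[k])
  for (k in which(hi < -tol)) add("reversibility_ub", model$reactions[k], -hi[k])
  if (any(sol$r_fwd < -tol) || any(sol$r_rev < -tol))
    add("flux_split", "negative part", max(-c(sol$r_fwd, sol$r_rev)))

  conc <- medium_conc(med, model$external)
  ubx <- uptake_bound(model$uptake_max, conc, xi)
  over <- sol$exchanges - ubx
  under <- -model$secretion - sol$exchanges
  for (i in which(over > tol))
    add("uptake_bound", model$external[i], over[i])
  for (i in which(under > tol))
    add("secretion_bound", model$external[i], under[i])

  if (length(viol)) do.call(rbind, viol)
  else data.frame(constraint = character(0), id = character(0),
                  residual = numeric(0), tolerance = numeric(0))
}
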