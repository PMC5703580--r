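#' Stationary culture concentrations from steady uptakes
#'
#' In steady state the metabolite balance of the bioreactor gives
#' s_i = c_i - u_i xi: what the feed carries minus what the biomass held per
#' unit dilution consumes. Secreted metabolites (u_i < 0) accumulate above
#' their feed concentration; metabolites fed at infinite concentration stay
#' infinite.
#'
#' @param u_star named vector of steady exchange rates (mmol/gDW/h,
#'   positive = consumption).
#' @param xi nonnegative scalar (gDW h/L).
#' @param med a [medium()].
#' @param tol tolerance below zero before a concentration is declared a
#'   constraint violation (values in (-tol, 0) are clipped with a warning).
#' @return named concentration vector (mM).
#' @export
steady_concentrations <- function(u_star, xi, med, tol = 1e-6) {
  conc <- medium_conc(med, names(u_star))
  s <- ifelse(is.infinite(conc), Inf, conc - u_star * xi)
  neg <- is.finite(s) & s < 0
  if (any(s[neg] < -tol))
    stop("negative steady concentration for ",
         paste(names(u_star)[s < -tol], collapse = ", "),
         ": uptake bound violated upstream")
  ## float-level noise (< 1e-12) is zeroed silently; anything larger but
  ## still within tol is a genuine near-violation worth a warning
  if (any(s[neg] < -1e-12))
    warning("clipping concentrations within tolerance of zero: ",
            paste(names(u_star)[is.finite(s) & s < -1e-12], collapse = ", "))
  s[neg] <- 0
  s
}

#' Effective growth rate under toxic feedback
#'
#' Applies a [toxicity_spec()] to the biomass synthesis rate: the
#' death-rate mechanism gives mu = z - sum(tau_j s_j) (possibly negative,
#' meaning net decay), the yield-factor mechanism gives
#' mu = z prod(1 + s_j/K_j)^-1, so 0 <= mu <= z.
#'
#' @param z_star biomass synthesis rate (1/h).
#' @param s_star named concentration vector (mM).
#' @param tox a [toxicity_spec()].
#' @return effective growth rate mu (1/h).
#' @export
effective_growth <- function(z_star, s_star, tox) {
  stopifnot(inherits(tox, "toxicity_spec"), z_star >= 0)
  cf <- tox$coefficients
  if (!length(cf)) return(z_star)
  missing <- setdiff(names(cf), names(s_star))
  if (length(missing))
    stop("toxicity refers to metabolites without concentrations: ",
         paste(missing, collapse = ", "))
  s <- s_star[names(cf)]
  if (any(!is.finite(s)))
    stop("toxic metabolite with non-finite concentration")
  switch(tox$mechanism,
         death_rate = z_star - sum(cf * s),
         yield_factor = z_star * prod(1 / (1 + s / cf)))
}

## Phase signature of one steady point: which metabolites are secreted and
## which nutrients sit at their availability bound c_i/xi.
phase_signature <- function(u, conc, V, xi, eps_u) {
  secreted <- names(u)[u < -eps_u]
  limiting <- character(0)
  if (xi > 0) {
    fin <- is.finite(conc) & conc > 0
    at_bound <- fin & abs(u - conc / xi) < eps_u & conc / xi <= V + eps_u
    limiting <- names(u)[at_bound]
  }
  list(secreted = sort(secreted), limiting = sort(limiting))
}

eps_active <- function(model) {
  Vf <- model$uptake_max[is.finite(model$uptake_max) & model$uptake_max > 0]
  if (length(Vf)) 1e-6 * max(Vf) else 1e-6
}

## Solve one grid point and package it as a one-row record.
scan_point <- function(model, med, tox, xi, phi, eps_u) {
  sol <- solve_fba(model, med, xi)
  ext <- model$external
  if (sol$status != "optimal") {
    s <- u <- rep(NA_real_, length(ext))
    return(c(list(xi = xi, feasible = FALSE, z = NA_real_, mu = NA_real_,
                  D = NA_real_, X = NA_real_, realizable = FALSE,
                  stable = NA, secreted = NA_character_,
                  limiting = NA_character_),
             stats::setNames(as.list(u), paste0("u_", ext)),
             stats::setNames(as.list(s), paste0("s_", ext))))
  }
  s <- steady_concentrations(sol$exchanges, xi, med)
  mu <- effective_growth(sol$z, s, tox)
  sig <- phase_signature(sol$exchanges, medium_conc(med, ext),
                         model$uptake_max, xi, eps_u)
  c(list(xi = xi, feasible = TRUE, z = sol$z, mu = mu,
         D = mu / phi, X = xi * mu / phi, realizable = mu >= 0,
         stable = NA,
         secreted = paste(sig$secreted, collapse = ";"),
         limiting = paste(sig$limiting, collapse = ";")),
    stats::setNames(as.list(sol$exchanges), paste0("u_", ext)),
    stats::setNames(as.list(s), paste0("s_", ext)))
}

#' Scan steady states over a grid of xi = X/D
#'
#' Maps each xi to the full steady-state description of the culture: the
#' lexicographic FBA solve gives z*(xi) and the exchanges u*(xi), the
#' bioreactor balance gives s*(xi), the toxicity model gives mu*(xi), and
#' D* = mu*/phi, X* = xi mu*/phi recover the operating point. Points beyond
#' the medium depth are kept as infeasible markers; points where toxicity
#' drives mu* below zero are kept but flagged unrealizable (no D >= 0 steady
#' state with positive cell density corresponds to them).
#'
#' When no grid is supplied, a geometric grid from xi_m * 1e-4 to xi_m plus
#' the xi = 0 limit point is used, and the grid is locally refined
#' (midpoint bisection) around phase-signature changes and sign changes of
#' the slope of mu*.
#'
#' @inheritParams solve_fba
#' @param tox a [toxicity_spec()].
#' @param xi_grid strictly increasing nonnegative vector, or NULL for the
#'   automatic grid.
#' @param phi bleeding coefficient in (0, 1]; phi = 1 is the chemostat.
#' @param n_grid size of the automatic grid.
#' @param refine_rounds rounds of local midpoint refinement.
#' @return data frame of class `steady_state_curve`, one row per xi, with
#'   columns xi, feasible, z, mu, D, X, realizable, stable (NA until
#'   [classify_stability()]), secreted / limiting phase signatures, and
#'   per-exchange columns u_<met> and s_<met>. Attributes: `phi`, `eps_u`.
#' @export
scan_steady_states <- function(model, med, tox, xi_grid = NULL, phi = 1,
                               n_grid = 80, refine_rounds = 4) {
  stopifnot(phi > 0, phi <= 1)
  eps_u <- eps_active(model)
  if (is.null(xi_grid)) {
    xi_m <- find_xi_max(model, med)
    hi <- if (is.finite(xi_m)) xi_m else
      stop("medium depth is unbounded; supply xi_grid explicitly")
    xi_grid <- c(0, exp(seq(log(hi * 1e-4), log(hi), length.out = n_grid)))
  }
  if (!length(xi_grid)) stop("empty xi grid")
  if (is.unsorted(xi_grid, strictly = TRUE)) stop("xi_grid must be strictly increasing")
  if (any(xi_grid < 0)) stop("xi must be >= 0")

  rows <- lapply(xi_grid, scan_point, model = model, med = med, tox = tox,
                 phi = phi, eps_u = eps_u)
  for (round in seq_len(refine_rounds)) {
    xi <- vapply(rows, `[[`, 0, "xi")
    new_xi <- refinement_targets(rows)
    new_xi <- setdiff(new_xi, xi)
    if (!length(new_xi)) break
    rows <- c(rows, lapply(new_xi, scan_point, model = model, med = med,
                           tox = tox, phi = phi, eps_u = eps_u))
    rows <- rows[order(vapply(rows, `[[`, 0, "xi"))]
  }
  curve <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  if (!any(curve$feasible))
    stop("no feasible steady state on the grid: the medium cannot sustain ",
         "the maintenance demand (degenerate medium depth <= 0)")
  structure(curve, phi = phi, eps_u = eps_u,
            class = c("steady_state_curve", "data.frame"))
}

## Midpoints of intervals whose endpoints change phase signature or change
## the sign of the discrete slope of mu*.
refinement_targets <- function(rows) {
  xi <- vapply(rows, `[[`, 0, "xi")
  feas <- vapply(rows, `[[`, TRUE, "feasible")
  mu <- vapply(rows, function(r) r$mu %||% NA_real_, 0)
  sig <- vapply(rows, function(r)
    paste(r$secreted, r$limiting, sep = "|"), "")
  targets <- numeric(0)
  n <- length(rows)
  if (n < 3) return(targets)
  dmu <- diff(mu) / diff(xi)
  for (i in seq_len(n - 1)) {
    if (feas[i] && feas[i + 1] && sig[i] != sig[i + 1])
      targets <- c(targets, (xi[i] + xi[i + 1]) / 2)
    else if (feas[i] != feas[i + 1])
      targets <- c(targets, (xi[i] + xi[i + 1]) / 2)
    else if (i < n - 1 && feas[i] && feas[i + 1] && feas[i + 2] &&
             !is.na(dmu[i]) && !is.na(dmu[i + 1]) &&
             sign(dmu[i]) != sign(dmu[i + 1]))
      targets <- c(targets, (xi[i] + xi[i + 1]) / 2, (xi[i + 1] + xi[i + 2]) / 2)
  }
  unique(targets)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Washout dilution rate
#'
#' D_max = mu*(0)/phi, the dilution rate above which no steady state with
#' positive cell density exists. Toxic feedback vanishes in this limit for
#' byproducts absent from the feed (their steady concentration goes to zero
#' with xi), but toxic compounds carried by the feed itself still act.
#'
#' @inheritParams scan_steady_states
#' @return washout rate D_max (1/h).
#' @export
washout_rate <- function(model, med, tox, phi = 1) {
  stopifnot(phi > 0, phi <= 1)
  sol <- solve_fba(model, med, 0)
  if (sol$status != "optimal")
    stop("infeasible at xi = 0: the medium cannot support growth at all")
  s0 <- steady_concentrations(sol$exchanges, 0, med)
  effective_growth(sol$z, s0, tox) / phi
}

#' Medium depth: the feasibility boundary in xi
#'
#' The largest xi = X/D at which the maintenance demand can still be met,
#' located by bisection on LP feasibility. Beyond xi_m the balance,
#' reversibility and uptake constraints admit no flux vector.
#'
#' @inheritParams scan_steady_states
#' @param rel_tol relative width at which bisection stops.
#' @param xi_probe upper probe; if the model is still feasible there the
#'   depth is reported as `Inf` (degenerate case, e.g. zero maintenance).
#' @return xi_m (gDW h/L), possibly `Inf`.
#' @export
find_xi_max <- function(model, med, rel_tol = 1e-6, xi_probe = 1e9) {
  feasible_at <- function(xi)
    solve_fba(model, med, xi, lexicographic = FALSE)$status == "optimal"
  if (!feasible_at(0))
    stop("infeasible at xi = 0: degenerate medium depth <= 0")
  lo <- 0; hi <- 1
  while (feasible_at(hi)) {
    lo <- hi; hi <- hi * 8
    if (hi > xi_probe) return(Inf)
  }
  while ((hi - lo) > rel_tol * hi) {
    mid <- (lo + hi) / 2
    if (feasible_at(mid)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Locate metabolic phase boundaries along a steady-state curve
#'
#' A phase is a maximal xi interval with a constant exchange signature (the
#' set of secreted metabolites together with the set of limiting nutrients,
#' i.e. those whose uptake sits at the availability bound c_i/xi). A
#' boundary is emitted between consecutive feasible grid points whose
#' signatures differ; when the model is supplied, each boundary is localized
#' by bisection to `rel_tol` relative precision instead of grid resolution.
#'
#' @param curve a `steady_state_curve` from [scan_steady_states()].
#' @inheritParams scan_steady_states
#' @param rel_tol relative xi precision of the bisection (with `model`).
#' @return data frame with one row per boundary: `xi` (boundary estimate),
#'   `xi_lo`, `xi_hi` (bracketing interval), `before`, `after` (signatures
#'   as "secreted|limiting" strings). Zero rows when the curve has a single
#'   phase.
#' @export
detect_phases <- function(curve, model = NULL, med = NULL, tox = NULL,
                          rel_tol = 1e-6) {
  stopifnot(inherits(curve, "steady_state_curve"))
  feas <- curve[curve$feasible, ]
  if (nrow(feas) < 2) stop("need at least two feasible points")
  sig <- paste(feas$secreted, feas$limiting, sep = "|")
  idx <- which(sig[-1] != sig[-length(sig)])
  if (!length(idx))
    return(data.frame(xi = numeric(0), xi_lo = numeric(0),
                      xi_hi = numeric(0), before = character(0),
                      after = character(0)))
  eps_u <- attr(curve, "eps_u")
  out <- lapply(idx, function(i) {
    lo <- feas$xi[i]; hi <- feas$xi[i + 1]
    if (!is.null(model)) {
      sig_at <- function(xi) {
        sol <- solve_fba(model, med, xi)
        if (sol$status != "optimal") return(NA_character_)
        sg <- phase_signature(sol$exchanges,
                              medium_conc(med, model$external),
                              model$uptake_max, xi, eps_u)
        paste(paste(sg$secreted, collapse = ";"),
              paste(sg$limiting, collapse = ";"), sep = "|")
      }
      while ((hi - lo) > rel_tol * hi) {
        mid <- (lo + hi) / 2
        if (identical(sig_at(mid), sig[i])) lo <- mid else hi <- mid
      }
    }
    data.frame(xi = (lo + hi) / 2, xi_lo = lo, xi_hi = hi,
               before = sig[i], after = sig[i + 1])
  })
  do.call(rbind, out)
}

#' Convert between dry-weight and cell-count based culture units
#'
#' Exact arithmetic conversion between the internal units (hours, gDW) and
#' the cell-count / day units common in the perfusion literature, using a
#' configurable dry weight per cell.
#'
#' Supported units: `"gDW*h/L"` <-> `"1e6cells*day/mL"` (for xi),
#' `"1/h"` <-> `"1/day"` (rates), `"gDW/L"` <-> `"1e6cells/mL"`
#' (cell density).
#'
#' @param value numeric value(s) to convert.
#' @param from,to unit strings as above.
#' @param dw_per_cell dry weight of one cell in grams (default 0.9 ng, a
#'   HeLa-scale mammalian cell; use 350 pg for CHO).
#' @return converted value.
#' @examples
#' convert_units(33.33, "gDW*h/L", "1e6cells*day/mL")  # ~1.543
#' convert_units(0.048958, "1/h", "1/day")             # ~1.175
#' @export
convert_units <- function(value, from, to, dw_per_cell = 0.9e-9) {
  pairs <- list(
    c("gDW*h/L", "1e6cells*day/mL"),
    c("1/h", "1/day"),
    c("gDW/L", "1e6cells/mL"))
  factor_for <- function(from, to) {
    if (identical(c(from, to), pairs[[1]])) return(1 / dw_per_cell / 24 / 1e9)
    if (identical(c(from, to), rev(pairs[[1]]))) return(dw_per_cell * 24 * 1e9)
    if (identical(c(from, to), pairs[[2]])) return(24)
    if (identical(c(from, to), rev(pairs[[2]]))) return(1 / 24)
    if (identical(c(from, to), pairs[[3]])) return(1 / dw_per_cell / 1e9)
    if (identical(c(from, to), rev(pairs[[3]]))) return(dw_per_cell * 1e9)
    if (identical(from, to)) return(1)
    stop("unsupported unit conversion: ", from, " -> ", to)
  }
  value * factor_for(from, to)
}
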