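#' Classify stability of steady states along a scan
#'
#' A steady state is unstable exactly where the effective growth rate
#' mu*(xi) is locally increasing, and stable otherwise (plateaus and
#' decreasing regions are stable). The slope is estimated by centered finite
#' differences on the scan grid and compared against a scale-aware threshold
#' eps_slope = 1e-4 mu*(0)/xi_max, so that numerically flat stretches are
#' not misread as growth. The classification depends only on xi, never on
#' the bleeding coefficient.
#'
#' @param curve a `steady_state_curve` with at least 3 feasible points.
#' @param eps_slope override for the slope threshold (1/h per gDW h/L).
#' @return the curve with its `stable` column filled for feasible points;
#'   the threshold used is attached as attribute `eps_slope`.
#' @export
classify_stability <- function(curve, eps_slope = NULL) {
  stopifnot(inherits(curve, "steady_state_curve"))
  fi <- which(curve$feasible)
  if (length(fi) < 3) stop("need at least 3 feasible points to classify")
  xi <- curve$xi[fi]; mu <- curve$mu[fi]
  if (is.null(eps_slope)) {
    mu0 <- mu[which.min(xi)]
    eps_slope <- 1e-4 * abs(mu0) / max(xi)
  }
  n <- length(fi)
  slope <- numeric(n)
  slope[1] <- (mu[2] - mu[1]) / (xi[2] - xi[1])
  slope[n] <- (mu[n] - mu[n - 1]) / (xi[n] - xi[n - 1])
  if (n > 2)
    slope[2:(n - 1)] <- (mu[3:n] - mu[1:(n - 2)]) / (xi[3:n] - xi[1:(n - 2)])
  curve$stable[fi] <- slope <= eps_slope
  attr(curve, "eps_slope") <- eps_slope
  attr(curve, "mu_slope") <- slope
  curve
}

#' Build the cell-density versus dilution-rate bifurcation diagram
#'
#' Partitions the feasible, realizable part of a classified scan into
#' branches of constant stability class, locates fold points (local extrema
#' of D*(xi)) and derives the multistable dilution-rate windows bounded by
#' the fold D-values. When the model is supplied, folds are sharpened by
#' golden-section search on mu*(xi) to relative xi precision 1e-5; otherwise
#' they are reported at grid resolution. The trivial washout branch (X = 0
#' at any D) is attached as metadata, never merged into the positive-density
#' branches.
#'
#' @param curve a classified `steady_state_curve` (see
#'   [classify_stability()]).
#' @inheritParams scan_steady_states
#' @return object of class `bifurcation_diagram`: list with `branches` (list
#'   of data frames xi, D, X, stable), `folds` (data frame xi, D, X, kind),
#'   `windows` (data frame D_lo, D_hi, n_branches), `washout` (list with
#'   D_max), and `phi`.
#' @export
build_diagram <- function(curve, model = NULL, med = NULL, tox = NULL) {
  stopifnot(inherits(curve, "steady_state_curve"))
  if (all(is.na(curve$stable)))
    stop("classify the curve first (classify_stability)")
  phi <- attr(curve, "phi")
  pts <- curve[curve$feasible & curve$realizable, , drop = FALSE]
  pts <- pts[order(pts$xi), ]

  runs <- rle(pts$stable)
  ends <- cumsum(runs$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  branches <- Map(function(a, b)
    data.frame(xi = pts$xi[a:b], D = pts$D[a:b], X = pts$X[a:b],
               stable = pts$stable[a:b]),
    starts, ends)

  ## folds: interior sign changes of the discrete derivative of D*(xi)
  folds <- data.frame(xi = numeric(0), D = numeric(0), X = numeric(0),
                      kind = character(0))
  dD <- diff(pts$D)
  sg <- sign(dD)
  for (i in seq_len(length(sg) - 1)) {
    if (sg[i] != 0 && sg[i + 1] != 0 && sg[i] != sg[i + 1]) {
      lo <- pts$xi[i]; hi <- pts$xi[i + 2]
      kind <- if (sg[i] < 0) "min" else "max"
      if (!is.null(model)) {
        mu_at <- function(xi) {
          sol <- solve_fba(model, med, xi)
          s <- steady_concentrations(sol$exchanges, xi, med)
          effective_growth(sol$z, s, tox)
        }
        opt <- stats::optimize(mu_at, c(lo, hi), maximum = kind == "max",
                               tol = 1e-5 * hi)
        xif <- if (kind == "max") opt$maximum else opt$minimum
        Df <- opt$objective / phi
      } else {
        xif <- pts$xi[i + 1]; Df <- pts$D[i + 1]
      }
      folds <- rbind(folds, data.frame(xi = xif, D = Df, X = xif * Df,
                                       kind = kind))
    }
  }

  ## windows: D-intervals bounded by fold D-values where more than one
  ## branch coexists (crossing count of the D*(xi) graph)
  windows <- data.frame(D_lo = numeric(0), D_hi = numeric(0),
                        n_branches = integer(0))
  if (nrow(folds)) {
    bounds <- sort(unique(c(folds$D, min(pts$D), max(pts$D))))
    count_at <- function(Dv) {
      f <- pts$D - Dv
      sum(f[-1] * f[-length(f)] < 0) + sum(f == 0)
    }
    for (i in seq_len(length(bounds) - 1)) {
      mid <- (bounds[i] + bounds[i + 1]) / 2
      k <- count_at(mid)
      if (k > 1)
        windows <- rbind(windows, data.frame(
          D_lo = bounds[i], D_hi = bounds[i + 1], n_branches = k))
    }
    ## merge adjacent windows with equal multiplicity
    if (nrow(windows) > 1) {
      keep <- list(windows[1, ])
      for (i in 2:nrow(windows)) {
        last <- keep[[length(keep)]]
        if (isTRUE(all.equal(last$D_hi, windows$D_lo[i])) &&
            last$n_branches == windows$n_branches[i])
          keep[[length(keep)]]$D_hi <- windows$D_hi[i]
        else keep[[length(keep) + 1]] <- windows[i, ]
      }
      windows <- do.call(rbind, keep)
    }
  }

  structure(list(branches = branches, folds = folds, windows = windows,
                 washout = list(D_max = max(pts$D)), phi = phi),
            class = "bifurcation_diagram")
}

#' @export
print.bifurcation_diagram <- function(x, ...) {
  cat("<bifurcation_diagram> phi =", x$phi, "\n",
      length(x$branches), "branch(es),", nrow(x$folds), "fold(s),",
      nrow(x$windows), "multistable window(s)\n")
  if (nrow(x$windows)) {
    for (i in seq_len(nrow(x$windows)))
      cat(sprintf("  window %d: D in (%.5g, %.5g) 1/h = (%.4g, %.4g) 1/day, %d branches\n",
                  i, x$windows$D_lo[i], x$windows$D_hi[i],
                  x$windows$D_lo[i] * 24, x$windows$D_hi[i] * 24,
                  x$windows$n_branches[i]))
  }
  cat("  washout branch: X = 0 for any D (D_max =",
      format(x$washout$D_max), "1/h)\n")
  invisible(x)
}

#' Numerical Jacobian eigenvalues at a steady state
#'
#' Independent stability check for low-dimensional models: builds the
#' dynamical system for cell density and the finite-concentration culture
#' metabolites at fixed dilution rate (with the steady-state uptake coupling
#' u_i <= min\{V_i, c_i D/X\}), verifies that the supplied point is an
#' equilibrium, and computes the central-difference Jacobian and its
#' eigenvalues. Stable points have all real parts negative; a positive
#' maximum real part flags instability. Cross-validates
#' [classify_stability()].
#'
#' @inheritParams scan_steady_states
#' @param point one row of a `steady_state_curve` (or an equivalent list
#'   with xi, D, X and the s_<met> entries).
#' @param phi bleeding coefficient used for the scan.
#' @param perturbation relative finite-difference step.
#' @param equilibrium_tol relative residual above which the point is
#'   rejected as not being an equilibrium.
#' @return list with `jacobian`, `eigenvalues`, `max_re`.
#' @export
jacobian_eigen_check <- function(model, med, tox, point, phi = 1,
                                 perturbation = 1e-6,
                                 equilibrium_tol = 1e-6) {
  ext <- model$external
  conc <- medium_conc(med, ext)
  tracked <- ext[is.finite(conc)]
  if (length(tracked) > 10)
    stop("Jacobian check is intended for <= 10 tracked metabolites")
  D <- point$D
  x0 <- c(X = point$X,
          stats::setNames(vapply(paste0("s_", tracked),
                                 function(nm) point[[nm]], 0), tracked))

  rhs <- function(x) {
    X <- max(x[1], 0); s <- x[-1]
    cap <- rep(Inf, length(ext)); names(cap) <- ext
    if (X > 0) cap[tracked] <- conc[tracked] * D / X
    sol <- solve_fba(model, med, xi = 0, uptake_ub = cap)
    if (sol$status != "optimal")
      stop("FBA infeasible while perturbing around the steady state")
    sfull <- stats::setNames(rep(Inf, length(ext)), ext)
    sfull[tracked] <- s
    mu <- effective_growth(sol$z, sfull, tox)
    u <- sol$exchanges[tracked]
    c(X = (mu - phi * D) * X,
      -u * X - (s - conc[tracked]) * D)
  }

  f0 <- rhs(x0)
  tolv <- equilibrium_tol * pmax(abs(x0), 1) * max(abs(D), 1e-9)
  if (any(abs(f0) > tolv))
    stop("point is not an equilibrium of the dynamical system (residual ",
         format(max(abs(f0))), ")")

  n <- length(x0)
  J <- matrix(0, n, n, dimnames = list(names(x0), names(x0)))
  for (j in seq_len(n)) {
    h <- perturbation * max(abs(x0[j]), 1e-3)
    xp <- x0; xm <- x0
    if (x0[j] - h < 0) {            # one-sided at the nonnegativity boundary
      xp[j] <- x0[j] + h
      J[, j] <- (rhs(xp) - f0) / h
    } else {
      xp[j] <- x0[j] + h; xm[j] <- x0[j] - h
      J[, j] <- (rhs(xp) - rhs(xm)) / (2 * h)
    }
  }
  ev <- eigen(J, only.values = TRUE)$values
  list(jacobian = J, eigenvalues = ev, max_re = max(Re(ev)))
}
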