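#' Define a dilution-rate schedule
#'
#' Either a constant dilution rate or a piecewise-linear profile through
#' (time, D) knots; between knots the rate is linearly interpolated, beyond
#' the last knot it stays at the last value. Times are hours, rates 1/h.
#'
#' @param D constant dilution rate (1/h); ignored when `knots` is given.
#' @param knots data frame with columns `time` (h, strictly increasing) and
#'   `D` (1/h, nonnegative).
#' @param phi bleeding coefficient in (0, 1].
#' @return object of class `dilution_schedule`.
#' @export
dilution_schedule <- function(D = NULL, knots = NULL, phi = 1) {
  stopifnot(phi > 0, phi <= 1)
  if (is.null(knots)) {
    stopifnot(is.numeric(D), length(D) == 1, D >= 0)
    sched <- list(mode = "constant", D = D, phi = phi)
  } else {
    stopifnot(is.data.frame(knots), all(c("time", "D") %in% names(knots)),
              nrow(knots) >= 1, all(knots$D >= 0),
              !is.unsorted(knots$time, strictly = TRUE))
    sched <- list(mode = "piecewise_linear", knots = knots, phi = phi)
  }
  structure(sched, class = "dilution_schedule")
}

#' Evaluate a dilution schedule at given times
#'
#' @param schedule a [dilution_schedule()].
#' @param t time(s) in hours, >= 0.
#' @return dilution rate(s) in 1/h.
#' @export
evaluate_schedule <- function(schedule, t) {
  stopifnot(inherits(schedule, "dilution_schedule"), all(t >= 0))
  if (schedule$mode == "constant") return(rep(schedule$D, length(t)))
  k <- schedule$knots
  if (nrow(k) == 1) return(rep(k$D, length(t)))
  stats::approx(k$time, k$D, xout = t, rule = 2)$y
}

#' Simulate the bioreactor dynamics with instantaneous FBA
#'
#' Integrates the cell-density and culture-concentration balances under a
#' dilution schedule, re-solving the growth-maximizing flux program at every
#' step (dynamic FBA). During transients the steady-state uptake coupling is
#' replaced by the availability bound
#' u_i <= min\{V_i, s_i/(X h) + c_i D/X\} with h the current step: the cell
#' may consume at most the current stock plus the feed inflow, so no
#' metabolite is driven below zero within a step, and at s_i = 0 the bound
#' reduces exactly to the steady-state coupling c_i D/X (no artificial
#' boundary layer). Integration is explicit Heun with step halving on negative
#' concentration overshoot and on large local error, the natural choice for
#' a right-hand side that is only piecewise smooth (LP vertex switches).
#'
#' If the flux program becomes infeasible mid-trajectory (maintenance can no
#' longer be met), cells stop producing biomass: z = 0, exchanges 0, and the
#' effective growth is whatever the toxicity mechanism yields at z = 0; the
#' event is logged and integration continues. A washout event is logged when
#' X drops below 1e-12 of the inoculum.
#'
#' @inheritParams scan_steady_states
#' @param schedule a [dilution_schedule()].
#' @param X0 inoculum density (gDW/L), > 0.
#' @param s0 named initial concentrations (mM); defaults to the feed medium.
#' @param t_end simulation horizon (h).
#' @param output_dt output sampling interval (h); also the maximum step.
#' @param rtol local-error tolerance of the adaptive Heun step.
#' @return data frame of class `culture_trajectory` with columns time, D, X,
#'   z, mu and per-metabolite s_<met>, u_<met>; the event log is attached as
#'   attribute `events` (data frame time, event).
#' @export
simulate_culture <- function(model, med, tox, schedule, X0, s0 = NULL,
                             t_end, output_dt = 1, rtol = 1e-4) {
  stopifnot(X0 > 0, t_end > 0, output_dt > 0)
  phi <- schedule$phi
  ext <- model$external
  conc <- medium_conc(med, ext)
  tracked <- ext[is.finite(conc)]
  if (is.null(s0)) s0 <- conc[tracked]
  else {
    s0 <- fill_named(s0, tracked, 0)
    if (any(s0 < 0)) stop("initial concentrations must be >= 0")
  }

  events <- data.frame(time = numeric(0), event = character(0))
  log_event <- function(t, what)
    events <<- rbind(events, data.frame(time = t, event = what))

  deriv <- function(t, X, s, h) {
    D <- evaluate_schedule(schedule, t)
    cap <- rep(Inf, length(ext)); names(cap) <- ext
    ## what a cell may consume over the step: the current stock plus the
    ## feed inflow; at s = 0 this reduces to the steady coupling c D / X
    cap[tracked] <- pmax(s, 0) / max(X * h, 1e-300) +
      conc[tracked] * D / max(X, 1e-300)
    sol <- solve_fba(model, med, xi = 0, uptake_ub = cap)
    if (sol$status != "optimal") {
      z <- 0; u <- stats::setNames(rep(0, length(ext)), ext)
      infeasible <- TRUE
    } else {
      z <- sol$z; u <- sol$exchanges; infeasible <- FALSE
    }
    sfull <- stats::setNames(rep(Inf, length(ext)), ext)
    sfull[tracked] <- pmax(s, 0)
    mu <- effective_growth(z, sfull, tox)
    list(dX = (mu - phi * D) * X,
         ds = -u[tracked] * X - (s - conc[tracked]) * D,
         z = z, mu = mu, u = u, D = D, infeasible = infeasible)
  }

  n_out <- floor(t_end / output_dt) + 1
  out_times <- seq(0, by = output_dt, length.out = n_out)
  rec <- vector("list", n_out)
  record <- function(i, t, X, s, d)
    rec[[i]] <<- c(list(time = t, D = d$D, X = X, z = d$z, mu = d$mu),
                   stats::setNames(as.list(s), paste0("s_", tracked)),
                   stats::setNames(as.list(d$u), paste0("u_", ext)))

  t <- 0; X <- X0; s <- s0
  h <- output_dt
  d0 <- deriv(t, X, s, h)
  record(1, t, X, s, d0)
  iout <- 2
  was_infeasible <- FALSE; washed_out <- FALSE
  exhausted <- character(0); n_rejected <- 0L
  h_min <- output_dt * 1e-8

  while (t < t_end - 1e-12 && iout <= n_out) {
    h <- min(h, out_times[iout] - t)
    repeat {
      d1 <- deriv(t, X, s, h)
      X1 <- X + h * d1$dX
      s1 <- s + h * unlist(d1$ds)
      if ((any(s1 < -1e-9 * max(conc[tracked], 1)) || X1 < 0) && h > h_min) {
        h <- h / 2; n_rejected <- n_rejected + 1L; next
      }
      s1 <- pmax(s1, 0); X1 <- max(X1, 0)
      d2 <- deriv(t + h, X1, s1, h)
      Xh <- X + h * (d1$dX + d2$dX) / 2
      sh <- s + h * (unlist(d1$ds) + unlist(d2$ds)) / 2
      if ((any(sh < -1e-9 * max(conc[tracked], 1)) || Xh < 0) && h > h_min) {
        h <- h / 2; n_rejected <- n_rejected + 1L; next
      }
      sh <- pmax(sh, 0); Xh <- max(Xh, 0)
      err <- max(abs(Xh - X1) / max(abs(Xh), X0),
                 if (length(sh)) max(abs(sh - s1) / pmax(abs(sh), 1)) else 0)
      if (err > rtol && h > h_min) {
        h <- h / 2; n_rejected <- n_rejected + 1L; next
      }
      t <- t + h; X <- Xh; s <- sh
      if (err < rtol / 8) h <- min(h * 2, output_dt)
      break
    }
    if (d1$infeasible && !was_infeasible) {
      log_event(t, "maintenance_infeasible"); was_infeasible <- TRUE
    }
    if (!d1$infeasible) was_infeasible <- FALSE
    if (!washed_out && X < 1e-12 * X0) {
      log_event(t, "washout_reached"); washed_out <- TRUE
    }
    gone <- tracked[s < 1e-6 * conc[tracked] & conc[tracked] > 0]
    for (g in setdiff(gone, exhausted)) {
      log_event(t, paste0("nutrient_exhausted:", g))
      exhausted <- c(exhausted, g)
    }
    if (abs(t - out_times[iout]) < 1e-9 * max(1, t)) {
      record(iout, t, X, s, deriv(t, X, s, max(h, h_min)))
      iout <- iout + 1
    }
  }
  if (n_rejected > 0)
    log_event(t, paste0("steps_rejected:", n_rejected))
  rec <- rec[!vapply(rec, is.null, TRUE)]
  traj <- do.call(rbind, lapply(rec, as.data.frame))
  structure(traj, events = events, phi = phi,
            class = c("culture_trajectory", "data.frame"))
}

#' Demonstrate path dependence inside a multistable window
#'
#' Runs two protocols that end at the same dilution rate: (a) the target
#' rate applied from the start to a small inoculum, and (b) a ramp schedule
#' that approaches the target gradually. Inside a multistable window the two
#' protocols settle on different branches (low versus high cell density);
#' outside any window, or without toxicity, they coincide.
#'
#' @inheritParams simulate_culture
#' @param D_target final dilution rate (1/h), ideally inside a window of
#'   `diagram`.
#' @param ramp_schedule a [dilution_schedule()] whose late-time value is
#'   `D_target`.
#' @param diagram optional `bifurcation_diagram` used to warn when D_target
#'   lies outside every multistable window and to assign terminal branches.
#' @param X0 inoculum (gDW/L) for both runs.
#' @return list with `constant` and `ramped` trajectories and, when a
#'   diagram is given, `branch_constant` / `branch_ramped` (indices into
#'   `diagram$branches` nearest to each terminal state).
#' @export
path_dependence_experiment <- function(model, med, tox, D_target,
                                       ramp_schedule, t_end,
                                       X0 = 1e-3, diagram = NULL,
                                       output_dt = 1) {
  phi <- ramp_schedule$phi
  if (!is.null(diagram) &&
      (!nrow(diagram$windows) ||
       !any(D_target > diagram$windows$D_lo &
            D_target < diagram$windows$D_hi)))
    warning("D_target lies outside every multistable window; ",
            "both protocols should reach the same branch")
  ta <- simulate_culture(model, med, tox,
                         dilution_schedule(D = D_target, phi = phi),
                         X0 = X0, t_end = t_end, output_dt = output_dt)
  tb <- simulate_culture(model, med, tox, ramp_schedule,
                         X0 = X0, t_end = t_end, output_dt = output_dt)
  out <- list(constant = ta, ramped = tb)
  if (!is.null(diagram)) {
    out$branch_constant <- nearest_branch(diagram, D_target,
                                          utils::tail(ta$X, 1))
    out$branch_ramped <- nearest_branch(diagram, D_target,
                                        utils::tail(tb$X, 1))
  }
  out
}

## Index of the diagram branch closest to (D_term, X_term), relative metric.
nearest_branch <- function(diagram, D_term, X_term) {
  d <- vapply(diagram$branches, function(br)
    min(sqrt(((br$D - D_term) / max(abs(D_term), 1e-12))^2 +
             ((br$X - X_term) / max(abs(X_term), 1e-12))^2)), 0)
  which.min(d)
}
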