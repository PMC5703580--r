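toy <- toy_as_generic_model()

test_that("schedules interpolate linearly and extrapolate flat", {
  ## hold at 0.2/day for 5 days, ramp to 0.6/day by day 10, hold to day 20
  per_day <- function(d) d / 24
  sch <- dilution_schedule(knots = data.frame(
    time = c(0, 5, 10, 20) * 24,
    D = per_day(c(0.2, 0.2, 0.6, 0.6))))
  expect_equal(evaluate_schedule(sch, 7.5 * 24), per_day(0.4))
  expect_equal(evaluate_schedule(sch, 0), per_day(0.2))
  expect_equal(evaluate_schedule(sch, 30 * 24), per_day(0.6))  # flat beyond
  cst <- dilution_schedule(D = per_day(0.6))
  expect_equal(evaluate_schedule(cst, c(0, 100, 1e4)), rep(per_day(0.6), 3))
  expect_error(dilution_schedule(knots = data.frame(time = c(5, 1),
                                                    D = c(0, 0))))
})

test_that("supercritical dilution washes the culture out and s returns to the feed", {
  D_max <- washout_rate(toy$model, toy$medium, toy$toxicity)
  tr <- simulate_culture(toy$model, toy$medium, toy$toxicity,
                         dilution_schedule(D = 1.3 * D_max), X0 = 0.01,
                         t_end = 400, output_dt = 10)
  expect_lt(tail(tr$X, 1), 0.01)
  expect_equal(tail(tr$s_S, 1), 15, tolerance = 1e-2)
  expect_true(all(tr$X >= 0), all(tr$s_S >= 0))
})

test_that("the batch limit (D = 0) consumes the feed monotonically", {
  tr <- simulate_culture(toy$model, toy$medium, toy$toxicity,
                         dilution_schedule(D = 0), X0 = 0.05,
                         t_end = 400, output_dt = 5)
  expect_true(all(diff(tr$s_S) <= 1e-9))
  ## cells grow while substrate lasts
  while_fed <- tr$s_S > 0.1
  expect_true(all(diff(tr$X[while_fed]) >= -1e-9))
  ev <- attr(tr, "events")
  expect_true(any(grepl("nutrient_exhausted:S", ev$event)))
})

test_that("long constant-D runs land on the steady-state curve within 1%", {
  D <- 0.040  # below the multistable window: unique positive steady state
  tr <- simulate_culture(toy$model, toy$medium, toy$toxicity,
                         dilution_schedule(D = D), X0 = 0.5,
                         t_end = 3000, output_dt = 20)
  xi_star <- 600 / (D * 348 + 1.0625)     # closed form on the upper branch
  expect_equal(tail(tr$X, 1), xi_star * D, tolerance = 1e-2)
  expect_equal(tail(tr$s_S, 1), 0, tolerance = 0.15)
  expect_equal(tail(tr$mu, 1), D, tolerance = 1e-3)
})

test_that("the culture balance residual vanishes along trajectories", {
  tr <- simulate_culture(toy$model, toy$medium, toy$toxicity,
                         dilution_schedule(D = 0.03), X0 = 0.2,
                         t_end = 300, output_dt = 2)
  ## ds/dt + u X + (s - c) D = 0, discretized with trapezoidal fluxes.
  ## Checked away from the substrate-depletion front, where the uptake
  ## bound switches between output samples and the quotient is only O(h).
  smooth <- which(tr$s_S > 0.5)
  smooth <- smooth[-length(smooth)]
  dt <- diff(tr$time)
  for (met in c("S", "W")) {
    s <- tr[[paste0("s_", met)]]
    u <- tr[[paste0("u_", met)]]
    cfeed <- if (met == "S") 15 else 0
    flux <- -u * tr$X - (s - cfeed) * tr$D
    resid <- diff(s) / dt - (flux[-1] + flux[-length(flux)]) / 2
    expect_lt(max(abs(resid[smooth])), 5e-3 * max(abs(flux)))
  }
})

test_that("terminal state is robust to halving the output step", {
  run <- function(dt) simulate_culture(
    toy$model, toy$medium, toy$toxicity, dilution_schedule(D = 0.035),
    X0 = 0.8, t_end = 600, output_dt = dt)
  X1 <- tail(run(10)$X, 1)
  X2 <- tail(run(5)$X, 1)
  expect_lt(abs(X1 - X2) / X2, 1e-3)
})

test_that("ramping the dilution rate reaches the high-density branch, constant D does not", {
  cv <- classify_stability(scan_steady_states(toy$model, toy$medium,
                                              toy$toxicity))
  dg <- build_diagram(cv, toy$model, toy$medium, toy$toxicity)
  expect_identical(nrow(dg$windows), 1L)
  Dt <- (dg$windows$D_lo + dg$windows$D_hi) / 2
  ramp <- dilution_schedule(knots = data.frame(
    time = c(0, 2200, 4200, 7000), D = c(0.042, 0.042, Dt, Dt)))
  pd <- path_dependence_experiment(toy$model, toy$medium, toy$toxicity,
                                   Dt, ramp, t_end = 7000, X0 = 1e-3,
                                   diagram = dg, output_dt = 25)
  expect_false(pd$branch_constant == pd$branch_ramped)
  expect_gt(tail(pd$ramped$X, 1), 1.8 * tail(pd$constant$X, 1))
  ## both terminal branches are stable ones
  expect_true(dg$branches[[pd$branch_constant]]$stable[1])
  expect_true(dg$branches[[pd$branch_ramped]]$stable[1])
  ## restarting the constant protocol from the ramped end state stays high
  keep <- simulate_culture(
    toy$model, toy$medium, toy$toxicity, dilution_schedule(D = Dt),
    X0 = tail(pd$ramped$X, 1),
    s0 = c(S = tail(pd$ramped$s_S, 1), W = tail(pd$ramped$s_W, 1)),
    t_end = 1200, output_dt = 25)
  expect_equal(tail(keep$X, 1), tail(pd$ramped$X, 1), tolerance = 0.02)
})

test_that("without toxicity both protocols settle on the same branch", {
  toy0 <- toy_as_generic_model(toy_params(tau = 0))
  cv0 <- classify_stability(scan_steady_states(toy0$model, toy0$medium,
                                               toy0$toxicity))
  dg0 <- build_diagram(cv0)
  D <- 0.046
  ramp <- dilution_schedule(knots = data.frame(
    time = c(0, 1500, 3000, 5000), D = c(0.04, 0.04, D, D)))
  expect_warning(
    pd <- path_dependence_experiment(toy0$model, toy0$medium, toy0$toxicity,
                                     D, ramp, t_end = 5000, X0 = 1e-3,
                                     diagram = dg0, output_dt = 25),
    "outside every multistable window")
  expect_equal(tail(pd$constant$X, 1), tail(pd$ramped$X, 1),
               tolerance = 1e-2)
})

test_that("small perturbations decay at stable points and flee unstable ones", {
  cv <- classify_stability(scan_steady_states(toy$model, toy$medium,
                                              toy$toxicity))
  run_from <- function(pt, fac, t_end = 1500) {
    tr <- simulate_culture(
      toy$model, toy$medium, toy$toxicity, dilution_schedule(D = pt$D),
      X0 = fac * pt$X, s0 = c(S = pt$s_S, W = pt$s_W),
      t_end = t_end, output_dt = 10)
    tail(tr$X, 1)
  }
  ## stable point: a 1% offset shrinks (the slowest toy mode relaxes over
  ## ~2000 h, so full convergence is not expected within the horizon)
  stab <- cv[cv$feasible & cv$stable & cv$xi > 5 & cv$xi < 25, ][1, ]
  for (fac in c(1.01, 0.99)) {
    off0 <- abs(fac - 1) * stab$X
    expect_lt(abs(run_from(stab, fac) - stab$X), 0.6 * off0)
  }
  unst <- cv[cv$feasible & !cv$stable & cv$xi > 31 & cv$xi < 32.5, ][1, ]
  up <- run_from(unst, 1.01, t_end = 3000)
  dn <- run_from(unst, 0.99, t_end = 3000)
  ## diverge toward the two adjacent stable branches
  expect_gt(abs(up - dn) / unst$X, 0.05)
})
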