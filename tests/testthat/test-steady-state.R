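toy <- toy_as_generic_model()

test_that("stationary concentrations follow the bioreactor balance", {
  expect_equal(steady_concentrations(c(S = 0), 25, medium(S = 15)),
               c(S = 15))
  expect_equal(steady_concentrations(c(S = 0.5), 10, medium(S = 15)),
               c(S = 10))
  ## secretion accumulates above the (zero) feed level
  expect_equal(steady_concentrations(c(W = -0.05), 10, medium()),
               c(W = 0.5))
  ## an uptake that would overdraw the feed is a hard error
  expect_error(steady_concentrations(c(S = 2), 10, medium(S = 15)),
               "negative steady concentration")
})

test_that("toxic feedback mechanisms give the documented growth corrections", {
  ## hyperbolic yield factors halve growth at their half-inhibition constants
  tox_k <- toxicity_spec("yield_factor", c(nh4 = 1.05, lac = 8))
  expect_equal(effective_growth(0.04, c(nh4 = 0, lac = 0), tox_k), 0.04)
  expect_equal(effective_growth(0.04, c(nh4 = 1.05, lac = 8), tox_k),
               0.25 * 0.04)
  ## linear death rate: sigma = tau * w
  tox_d <- toxicity_spec("death_rate", c(W = 0.0022))
  expect_equal(0.04 - effective_growth(0.04, c(W = 1.5), tox_d),
               0.0022 * 1.5)
  ## death can exceed growth: negative mu is legal
  expect_lt(effective_growth(0.001, c(W = 10), tox_d), 0)
  expect_error(toxicity_spec("osmotic"), "arg")
})

test_that("scan reproduces the growth curve and its phi scaling", {
  cv <- scan_steady_states(toy$model, toy$medium, toy$toxicity,
                           xi_grid = c(0, 10, 20), refine_rounds = 0)
  expect_equal(cv$mu[1], 17.0375 / 348, tolerance = 1e-9)
  expect_true(all(diff(cv$mu) < 0))
  ## halving phi doubles D* and X* pointwise, leaves u*, s*, mu* unchanged
  cv5 <- scan_steady_states(toy$model, toy$medium, toy$toxicity,
                            xi_grid = c(0, 10, 20), phi = 0.5,
                            refine_rounds = 0)
  expect_equal(cv5$D, 2 * cv$D)
  expect_equal(cv5$X, 2 * cv$X)
  expect_equal(cv5$mu, cv$mu)
  expect_equal(cv5$u_S, cv$u_S)
  expect_equal(cv5$s_W, cv$s_W)
  ## grid points beyond xi_m are marked infeasible without disturbing others
  cvb <- scan_steady_states(toy$model, toy$medium, toy$toxicity,
                            xi_grid = c(10, 600), refine_rounds = 0)
  expect_identical(cvb$feasible, c(TRUE, FALSE))
  expect_equal(cvb$mu[1], cv$mu[2])
})

test_that("washout rate is the xi -> 0 growth limit, scaled by bleeding", {
  D_max <- washout_rate(toy$model, toy$medium, toy$toxicity)
  expect_equal(D_max, 17.0375 / 348, tolerance = 1e-9)
  expect_equal(D_max * 24, 1.175, tolerance = 1e-4)          # per day
  expect_equal(washout_rate(toy$model, toy$medium, toy$toxicity, phi = 0.5),
               2 * D_max)
  ## toxicity does not act at xi -> 0 (secreted waste concentration vanishes)
  tox0 <- toxicity_spec("death_rate")
  expect_equal(washout_rate(toy$model, toy$medium, tox0), D_max)
})

test_that("medium depth matches the maintenance threshold and scales with the feed", {
  xi_m <- find_xi_max(toy$model, toy$medium)
  expect_equal(xi_m, 15 * 40 / 1.0625, tolerance = 1e-5)     # 564.706
  ## doubling the feed doubles the depth
  expect_equal(find_xi_max(toy$model, medium(S = 30)), 2 * xi_m,
               tolerance = 1e-5)
  ## zero maintenance: feasible at any xi (degenerate infinite depth)
  free <- toy$model
  free$maintenance["E"] <- 0
  expect_identical(find_xi_max(free, toy$medium, xi_probe = 1e6), Inf)
})

test_that("phase boundaries sit at the closed-form thresholds", {
  cv <- scan_steady_states(toy$model, toy$medium, toy$toxicity)
  ph <- detect_phases(cv, toy$model, toy$medium, toy$toxicity)
  expect_identical(nrow(ph), 2L)
  expect_equal(ph$xi[1], 30, tolerance = 1e-4)       # substrate limitation
  expect_equal(ph$xi[2], 100 / 3, tolerance = 1e-4)  # secretion stops
  ## boundaries do not involve toxicity
  tm0 <- toy_as_generic_model(toy_params(tau = 0))
  cv0 <- scan_steady_states(tm0$model, tm0$medium, tm0$toxicity)
  ph0 <- detect_phases(cv0, tm0$model, tm0$medium, tm0$toxicity)
  expect_equal(ph0$xi, ph$xi, tolerance = 1e-4)
  ## a single-phase stretch of a secretion-free chain yields no boundary
  fx <- generate_fixture("chain", n_reactions = 3, seed = 2)
  xi0 <- fx$info$conc / fx$info$V
  xi_m <- fx$info$conc * fx$info$yield / fx$info$e
  cvc <- scan_steady_states(fx$model, fx$medium, fx$toxicity,
                            xi_grid = seq(xi0 * 1.05, xi_m * 0.95,
                                          length.out = 8),
                            refine_rounds = 0)
  expect_identical(nrow(detect_phases(cvc)), 0L)
})

test_that("mass balance u* X* = (c - s*) D* holds at every feasible point", {
  cv <- scan_steady_states(toy$model, toy$medium, toy$toxicity)
  f <- cv[cv$feasible & cv$xi > 0, ]
  lhs_S <- f$u_S * f$X
  rhs_S <- (15 - f$s_S) * f$D
  expect_equal(lhs_S, rhs_S, tolerance = 1e-8)
  lhs_W <- f$u_W * f$X
  rhs_W <- (0 - f$s_W) * f$D
  expect_equal(lhs_W, rhs_W, tolerance = 1e-8)
})

test_that("unit conversions are exact and invertible", {
  expect_equal(convert_units(100 / 3, "gDW*h/L", "1e6cells*day/mL"),
               1.543, tolerance = 1e-3)
  expect_equal(convert_units(0.048958, "1/h", "1/day"), 1.175,
               tolerance = 1e-4)
  expect_equal(convert_units(1, "gDW/L", "1e6cells/mL", 0.9e-9),
               1.1111, tolerance = 1e-4)
  for (u in list(c("gDW*h/L", "1e6cells*day/mL"), c("1/h", "1/day"),
                 c("gDW/L", "1e6cells/mL"))) {
    x <- 12.345
    back <- convert_units(convert_units(x, u[1], u[2]), u[2], u[1])
    expect_equal(back, x, tolerance = 1e-12)
  }
  expect_error(convert_units(1, "1/h", "gDW/L"), "unsupported")
})
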