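toy <- toy_as_generic_model()

test_that("growth-maximizing solve reproduces the closed-form optimum", {
  sol <- solve_fba(toy$model, toy$medium, xi = 0)
  expect_identical(sol$status, "optimal")
  expect_equal(unname(sol$exchanges["S"]), 0.5, tolerance = 1e-9)
  expect_equal(unname(sol$fluxes["resp"]), 0.45, tolerance = 1e-9)
  expect_equal(unname(sol$exchanges["W"]), -0.05, tolerance = 1e-9)
  expect_equal(sol$z, 17.0375 / 348, tolerance = 1e-9)  # 0.0489583 1/h
  expect_feasible_solution(toy, 0, sol)
})

test_that("xi beyond the medium depth yields an infeasible status, not an error", {
  sol <- solve_fba(toy$model, toy$medium, xi = 600)  # xi_m ~ 564.7
  expect_identical(sol$status, "infeasible")
  expect_true(is.na(sol$z))
})

test_that("a vanishing crowding budget with maintenance routed through costly reactions is infeasible", {
  p <- toy_params()
  ## budget so small that even the maintenance flux through respiration
  ## exceeds it, with fermentation also priced
  tm <- toy_as_generic_model(p, budget = 1e-9)
  tm$model$cost_fwd["gly"] <- 1
  sol <- solve_fba(tm$model, tm$medium, xi = 0)
  expect_identical(sol$status, "infeasible")
})

test_that("unbounded growth directions raise a hard error naming the culprit", {
  ## free lunch: a reaction creating E from nothing, cost-free and unbounded
  S <- matrix(c(1), 1, 1, dimnames = list("E", "magic"))
  mdl <- metabolic_model(S, budget = 1, biomass = c(E = 1),
                         external = "E", uptake_max = c(E = 0),
                         secretion = c(E = 0))
  expect_error(solve_fba(mdl, medium(), xi = 0), "unbounded")
})

test_that("cost minimization picks the cheap pathway among growth-equivalent optima", {
  ## two parallel routes S -> E with equal yield but different costs
  S <- matrix(c(-1, -1, 0,
                 5,  5, -0),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("S", "E"), c("cheap", "costly", "noop")))
  S <- S[, 1:2]
  mdl <- metabolic_model(S, cost_fwd = c(cheap = 1, costly = 3),
                         budget = 100, biomass = c(E = 10),
                         external = "S", uptake_max = c(S = 1),
                         secretion = c(S = 0))
  med <- medium(S = 10)
  sol <- solve_fba(mdl, med, xi = 0)
  expect_equal(unname(sol$fluxes["costly"]), 0, tolerance = 1e-9)
  expect_equal(unname(sol$fluxes["cheap"]), 1, tolerance = 1e-9)
  ## the one-argument entry point agrees
  z1 <- solve_fba(mdl, med, 0, lexicographic = FALSE)$z
  sol2 <- minimize_cost_at_optimum(mdl, med, 0, z1)
  expect_equal(sol2$cost, sol$cost, tolerance = 1e-9)
  expect_lte(sol2$cost, solve_fba(mdl, med, 0, lexicographic = FALSE)$cost + 1e-9)
  ## realized cost is the cost-weighted flux sum by definition
  expect_equal(sol$cost,
               sum(mdl$cost_fwd * sol$r_fwd + mdl$cost_rev * sol$r_rev))
})

test_that("validate_solution flags exactly the corrupted balances", {
  sol <- solve_fba(toy$model, toy$medium, xi = 10)
  expect_identical(nrow(validate_solution(toy$model, toy$medium, 10, sol)), 0L)
  bad <- sol
  bad$exchanges["S"] <- bad$exchanges["S"] + 1
  v <- validate_solution(toy$model, toy$medium, 10, bad)
  expect_true("balance" %in% v$constraint)
  expect_true("S" %in% v$id[v$constraint == "balance"])
  expect_false("W" %in% v$id[v$constraint == "balance"])
  ## a solution sitting exactly on the budget is legal (inclusive bound)
  sol0 <- solve_fba(toy$model, toy$medium, xi = 0)
  expect_equal(sol0$cost, toy$model$budget, tolerance = 1e-9)
  expect_identical(nrow(validate_solution(toy$model, toy$medium, 0, sol0)), 0L)
})

test_that("LP optimum equals brute-force vertex enumeration on small fixtures", {
  for (seed in 1:3) {
    fx <- generate_fixture("chain", n_reactions = 3, seed = seed)
    for (xi in c(0, 5, 20)) {
      sol <- solve_fba(fx$model, fx$medium, xi)
      if (sol$status != "optimal") next
      lp <- chemofba:::fba_lp(fx$model, fx$medium, xi)
      obj <- numeric(length(lp$ub)); obj[lp$iz] <- 1
      oracle <- enum_lp_max(obj, lp$A, lp$b, lp$sense, lp$ub)
      expect_equal(sol$z, oracle$objval, tolerance = 1e-8)
    }
  }
})

test_that("z*(xi) is non-increasing and feasible sets nest", {
  grid <- seq(0, 550, length.out = 50)
  z <- vapply(grid, function(x) solve_fba(toy$model, toy$medium, x)$z, 0)
  expect_true(all(diff(z) <= 1e-10))
  ## doubling medium concentrations never decreases the optimum
  med2 <- medium(S = 30)
  for (xi in c(0, 50, 200)) {
    expect_gte(solve_fba(toy$model, med2, xi)$z,
               solve_fba(toy$model, toy$medium, xi)$z - 1e-12)
  }
})
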