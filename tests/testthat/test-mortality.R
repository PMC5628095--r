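test_that("boundary mortality rates behave trivially", {
  inv <- small_inventory(n = 200)
  none <- mortality_model(0, 0, 0, mode = "stochastic", seed = 1)
  out <- apply_annual_mortality(inv, none, 1)
  expect_identical(out$inventory, inv)
  expect_equal(nrow(out$dead), 0L)
  # a rate of 1 is disallowed by the model contract
  expect_error(mortality_model(rate_street = 1), "rates")
  almost_all <- mortality_model(0.999999, 0.999999, 0.999999,
                                mode = "expected_value", seed = 1)
  out2 <- apply_annual_mortality(inv, almost_all, 1)
  expect_equal(sum(out2$inventory$alive), 0L)
  expect_true(all(out2$dead$death_year == 1L))
})

test_that("unknown land use labels fail naming the tree", {
  inv <- small_inventory(n = 10)
  inv$land_use[4] <- "plaza"
  expect_error(apply_annual_mortality(inv, mortality_model(), 1),
               paste0("tree_id ", inv$tree_id[4]))
})

test_that("stochastic thinning is an unbiased Bernoulli draw per tree", {
  inv <- uniform_inventory(10000, land_use = "street")
  deaths <- vapply(1:1000, function(s) {
    m <- mortality_model(mode = "stochastic", seed = s)
    nrow(apply_annual_mortality(inv, m, 1)$dead)
  }, numeric(1))
  # binomial oracle: mean within 3 standard errors of n*p
  n <- 10000; p <- 0.035
  se_mean <- sqrt(n * p * (1 - p)) / sqrt(1000)
  expect_lt(abs(mean(deaths) - n * p), 3 * se_mean)
  expect_lt(abs(sd(deaths) - sqrt(n * p * (1 - p))), 3)
})

test_that("expected-value selection kills exactly round(rate * alive) trees", {
  inv <- uniform_inventory(1234, land_use = "park")
  m <- mortality_model(mode = "expected_value", seed = 99)
  out <- apply_annual_mortality(inv, m, 5)
  expect_equal(nrow(out$dead), round(0.01 * 1234))
  expect_true(all(!out$inventory$alive[out$inventory$tree_id %in% out$dead$tree_id]))
  # dead trees are never resurrected nor re-killed
  out2 <- apply_annual_mortality(out$inventory, m, 6)
  expect_equal(length(intersect(out$dead$tree_id, out2$dead$tree_id)), 0L)
})

test_that("population half-life matches the closed form and a brute-force loop", {
  expect_identical(population_half_life(0.035), 20)
  expect_identical(population_half_life(0.02), 35)
  expect_identical(population_half_life(0.01), 69)
  expect_identical(population_half_life(0.5), 1)
  expect_identical(population_half_life(1), 1)
  expect_error(population_half_life(0), "rate")
  set.seed(314)
  rates <- runif(1000, 0.001, 0.5)
  brute <- vapply(rates, function(r) {
    surv <- 1; t <- 0
    while (surv > 0.5) { surv <- surv * (1 - r); t <- t + 1 }
    t
  }, numeric(1))
  expect_equal(population_half_life(rates), brute)
})

test_that("expected-value planting survival matches n(1-m)^t exactly", {
  for (rate in c(0.035, 0.02, 0.01)) {
    sc <- planting_scenario(n_trees = 100000, growth_horizon = 100,
                            mortality_rate = rate)
    traj <- run_planting_scenario(sc, ALLO, REG, mode = "expected_value")
    expect_equal(traj$alive_count, 100000 * (1 - rate)^(0:100),
                 tolerance = 1e-12)
    hl <- attr(traj, "half_life_years")
    expect_identical(hl, population_half_life(rate))
    expect_true(traj$is_half_life_year[traj$year == hl])
    # half-life is exactly the first year at or below 50% survival
    expect_lte(traj$alive_count[traj$year == hl], 50000)
    expect_gt(traj$alive_count[traj$year == hl - 1], 50000)
  }
})

test_that("zero-mortality planting keeps the cohort and grows carbon", {
  sc <- planting_scenario(n_trees = 1000, growth_horizon = 70,
                          mortality_rate = 0)
  traj <- run_planting_scenario(sc, ALLO, REG, mode = "expected_value")
  expect_true(all(traj$alive_count == 1000))
  expect_true(all(diff(traj$alive_carbon_ktC) > 0))
  expect_false(any(traj$is_half_life_year))
})

test_that("higher mortality gives a pointwise lower alive-carbon trajectory", {
  sc_hi <- planting_scenario(mortality_rate = 0.035)
  sc_lo <- planting_scenario(mortality_rate = 0.01)
  hi <- run_planting_scenario(sc_hi, ALLO, REG, mode = "expected_value")
  lo <- run_planting_scenario(sc_lo, ALLO, REG, mode = "expected_value")
  expect_true(all(hi$alive_carbon_ktC[-1] < lo$alive_carbon_ktC[-1]))
  expect_equal(hi$alive_carbon_ktC[1], lo$alive_carbon_ktC[1])
})

test_that("compensation analysis is pure arithmetic on its inputs", {
  # fabricate a minimal result: park flat (zero decline), street declining
  yearly <- expand.grid(year = 0:70, land_use = c("street", "mixed", "park"),
                        stringsAsFactors = FALSE)
  yearly$population <- 1000
  yearly$alive_ktC <- ifelse(yearly$land_use == "street",
                             100 - yearly$year, 100)
  yearly$dead_ktC <- 0
  fake <- structure(list(yearly = yearly,
                         mortality = mortality_model(mode = "expected_value")),
                    class = "lca_result")
  traj <- run_planting_scenario(planting_scenario(mortality_rate = 0.035),
                                ALLO, REG, mode = "expected_value")
  comp <- compensation_analysis(fake, traj)
  street <- comp[comp$land_use == "street", ]
  expect_equal(street$half_life_years, 20)
  expect_equal(street$alive_carbon_decline_ktC, 20)
  expect_equal(street$compensation_ratio,
               20 / traj$alive_carbon_ktC[traj$year == 20])
  park <- comp[comp$land_use == "park", ]
  expect_equal(park$compensation_ratio, 0)
  # the reference arithmetic: a 15.2 ktC loss against ~3.5 ktC of planting
  expect_gt(15.2 / 3.5, 4)
  # trajectories that do not span the half-life year are rejected
  short <- run_planting_scenario(planting_scenario(mortality_rate = 0.01,
                                                   growth_horizon = 50),
                                 ALLO, REG, mode = "expected_value")
  expect_error(compensation_analysis(fake, short), "half-life year")
})
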