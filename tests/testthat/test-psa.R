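test_that("degenerate PSA reproduces the deterministic base case exactly", {
  pop <- small_population(300, seed = 61)
  eqs <- read_risk_equations()
  params <- list(
    list(name = "management_cost", dist = "gamma", mean = 450, se = 0),
    list(name = "bmi_disutility", dist = "beta", mean = 0.006, se = 0),
    list(name = "hba1c_effect_12m", dist = "normal", mean = -0.84, sd = 0),
    list(name = "calibration_mi", dist = "lognormal", meanlog = 0, sdlog = 0)
  )
  spec <- psa_spec(n_samples = 3, parameters = params, seed = 4)
  res <- run_psa(spec, pop, eqs, n_years = 20)
  expect_equal(nrow(res$draws), 3)
  for (i in 1:3) {
    expect_equal(res$draws$delta_cost[i], res$base_case$incremental_cost)
    expect_equal(res$draws$delta_qaly[i], res$base_case$incremental_qaly)
  }
})

test_that("the requested number of PSA draws is produced and is seeded", {
  pop <- small_population(150, seed = 62)
  eqs <- read_risk_equations()
  spec <- psa_spec(n_samples = 8, seed = 10)
  res <- run_psa(spec, pop, eqs, n_years = 15)
  expect_equal(nrow(res$draws), 8)
  res2 <- run_psa(spec, pop, eqs, n_years = 15)
  expect_identical(res$draws, res2$draws)
  # a different seed gives a different draw sequence
  res3 <- run_psa(psa_spec(n_samples = 8, seed = 11), pop, eqs, n_years = 15)
  expect_false(identical(res$draws, res3$draws))
})

test_that("invalid hyperparameters fail before any simulation", {
  expect_error(psa_spec(parameters = list(
    list(name = "management_cost", dist = "gamma", mean = -5, se = 1))),
    "invalid gamma")
  expect_error(psa_spec(parameters = list(
    list(name = "bmi_disutility", dist = "beta", mean = 0.5, se = 0.9))),
    "beta se too large")
  expect_error(psa_spec(parameters = list(
    list(name = "x", dist = "cauchy", mean = 0))), "unknown distribution")
  expect_error(psa_spec(n_samples = 0), "at least 1")
})

test_that("expected NMB is the mean of per-draw NMBs (linearity)", {
  draws <- data.frame(delta_cost = c(100, -50, 20),
                      delta_qaly = c(0.01, 0.02, -0.005))
  nmbs <- 20000 * draws$delta_qaly - draws$delta_cost
  expect_equal(mean(nmbs),
               incremental_nmb(mean(draws$delta_cost),
                               mean(draws$delta_qaly), 20000))
  expect_equal(probability_cost_effective(draws, 20000), mean(nmbs > 0))
})

test_that("subgroup partitions are exhaustive and weight-consistent", {
  pop <- small_population(800, seed = 63)
  eqs <- read_risk_equations()
  sub <- subgroup_run(pop, "bmi_category", equations = eqs, n_years = 15,
                      seed = 12)
  strata <- sub[sub$stratum != "overall", ]
  expect_equal(sum(strata$n), nrow(pop))
  overall <- sub[sub$stratum == "overall", ]
  ok <- strata$n > 0
  expect_equal(
    sum(strata$incremental_cost[ok] * strata$n[ok]) / sum(strata$n[ok]),
    overall$incremental_cost, tolerance = 1e-9)
  expect_equal(
    sum(strata$incremental_qaly[ok] * strata$n[ok]) / sum(strata$n[ok]),
    overall$incremental_qaly, tolerance = 1e-9)

  # the half-open convention puts BMI exactly 30 in the 30-35 band
  pop2 <- pop
  pop2$bmi[1] <- 30
  g <- cut(pop2$bmi, c(-Inf, 28, 30, 35, 40, Inf),
           labels = c("<28", "28-30", "30-35", "35-40", ">=40"), right = FALSE)
  expect_equal(as.character(g[1]), "30-35")

  sub_imd <- subgroup_run(pop, "imd_quintile", equations = eqs, n_years = 10,
                          seed = 12)
  expect_equal(sum(sub_imd$stratum != "overall"), 5)

  sub_dur <- subgroup_run(pop, "diabetes_duration", equations = eqs,
                          n_years = 10, seed = 12)
  expect_setequal(sub_dur$stratum, c("<1y", "1-3y", "overall"))
})

test_that("a single-stratum grouping equals the whole-population run", {
  pop <- small_population(200, seed = 64)
  pop$diabetes_duration <- runif(nrow(pop), 0, 0.9)  # all < 1 year
  eqs <- read_risk_equations()
  sub <- subgroup_run(pop, "diabetes_duration", equations = eqs,
                      n_years = 10, seed = 13)
  lone <- sub[sub$stratum == "<1y", ]
  overall <- sub[sub$stratum == "overall", ]
  expect_equal(lone$incremental_cost, overall$incremental_cost)
  expect_equal(lone$incremental_qaly, overall$incremental_qaly)
  empty <- sub[sub$stratum == "1-3y", ]
  expect_equal(empty$n, 0)
  expect_true(is.na(empty$incremental_cost))
})
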