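test_that("generated marginals recover the specified moments within 3 SE", {
  n <- 10000
  pop <- generate_population(cohort_spec(n = n, seed = 7))
  spec <- cohort_spec(n = n)
  for (v in names(spec$continuous)) {
    m <- spec$continuous[[v]]
    se <- m$sd / sqrt(n)
    expect_lt(abs(mean(pop[[v]]) - m$mean), 3 * se)
    # SD of the sample SD is approx sd/sqrt(2n) for near-normal data
    expect_lt(abs(sd(pop[[v]]) - m$sd), 4 * m$sd / sqrt(2 * n))
  }
  expect_lt(abs(mean(pop$is_male) - 0.478),
            3 * sqrt(0.478 * 0.522 / n))
  expect_lt(abs(mean(pop$diabetes_duration < 1) - 0.545),
            3 * sqrt(0.545 * 0.455 / n))
  imd_freq <- tabulate(pop$imd_quintile, 5) / n
  for (k in 1:5) {
    p <- spec$imd_probs[k]
    expect_lt(abs(imd_freq[k] - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("eligibility invariants are enforced by truncation", {
  pop <- small_population(2000, seed = 3)
  expect_true(all(pop$age >= 18))
  expect_true(all(pop$bmi >= 25))
  expect_true(all(pop$diabetes_duration <= 3))
  expect_true(all(pop$hba1c > 0))
  expect_true(all(pop$imd_quintile %in% 1:5))
})

test_that("degenerate zero-SD spec yields identical individuals at the mean", {
  cont <- default_continuous_marginals()
  for (v in names(cont)) cont[[v]]$sd <- 0
  pop <- generate_population(cohort_spec(n = 20, continuous = cont, seed = 5))
  for (v in names(cont)) {
    expect_equal(pop[[v]], rep(cont[[v]]$mean, 20))
  }
})

test_that("generation is byte-identical under the same seed", {
  p1 <- generate_population(cohort_spec(n = 200, seed = 42))
  p2 <- generate_population(cohort_spec(n = 200, seed = 42))
  expect_identical(p1, p2)
  p3 <- generate_population(cohort_spec(n = 200, seed = 43))
  expect_false(identical(p1, p3))
})

test_that("requested correlation structure is approximately preserved", {
  pop <- generate_population(cohort_spec(n = 10000, seed = 9))
  expect_gt(cor(pop$weight, pop$bmi), 0.8)
  expect_lt(abs(cor(pop$bmi, pop$sbp) - 0.2), 0.06)
})

test_that("invalid specifications are rejected", {
  r <- default_correlation(names(default_continuous_marginals()))
  r[1, 2] <- r[2, 1] <- 2  # breaks PSD
  expect_error(cohort_spec(correlation = r), "positive semi-definite")
  cont <- default_continuous_marginals()
  cont$bmi$lower <- 80  # mean 34.6 outside [80, 70]
  expect_error(cohort_spec(n = 10, continuous = cont),
               "impossible truncation bounds")
})

test_that("stratified permuted blocks balance arms in every complete block", {
  trial <- generate_trial(small_spec(600, seed = 2), attrition_rate = 0,
                          seed = 4)
  stratum <- paste0(trial$is_male, trial$diabetes_duration < 1)
  for (s in unique(stratum)) {
    arm <- trial$arm[stratum == s]
    n_complete <- floor(length(arm) / 6)
    for (b in seq_len(n_complete)) {
      prefix <- arm[seq_len(6 * b)]
      expect_equal(sum(prefix == "DEW"), 3 * b)
    }
  }
})

test_that("attrition controls 12-month completeness", {
  t0 <- generate_trial(small_spec(300, seed = 1), attrition_rate = 0, seed = 1)
  expect_true(all(t0$completed_12m))
  expect_false(anyNA(t0$weight_12))

  n <- 577
  tr <- generate_trial(small_spec(n, seed = 6), attrition_rate = 0.31,
                       seed = 6)
  completers <- sum(tr$completed_12m)
  expect_lt(abs(completers - n * 0.69), 3 * sqrt(n * 0.31 * 0.69))
  expect_true(all(is.na(tr$weight_12[!tr$completed_12m])))
  expect_false(anyNA(tr$weight_12[tr$completed_12m]))
  expect_false(anyNA(tr$weight_0))
  expect_false(anyNA(tr$utility_0))
})

test_that("null effects leave arm means statistically indistinguishable", {
  null_eff <- effect_profile(hba1c_effect_12m = 0, weight_effect_12m = 0,
                             hba1c_effect_6m = 0, weight_effect_6m = 0)
  tr <- generate_trial(small_spec(4000, seed = 8), effects = null_eff,
                       attrition_rate = 0, seed = 8)
  chg <- tr$weight_12 - tr$weight_0
  d <- mean(chg[tr$arm == "DEW"]) - mean(chg[tr$arm == "DE"])
  se <- sqrt(var(chg[tr$arm == "DEW"]) / sum(tr$arm == "DEW") +
             var(chg[tr$arm == "DE"]) / sum(tr$arm == "DE"))
  expect_lt(abs(d), 3 * se)
})

test_that("utilities stay inside the EQ-5D index range", {
  tr <- generate_trial(small_spec(1000, seed = 12), seed = 12)
  u <- c(tr$utility_0, tr$utility_6, tr$utility_12)
  u <- u[!is.na(u)]
  expect_true(all(u >= -0.594 & u <= 1))
})

test_that("cohort tables round-trip through the delimited format", {
  pop <- small_population(50, seed = 20)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(pop, f, seed = 20)
  back <- read_cohort(f)
  expect_equal(back$bmi, pop$bmi, tolerance = 1e-8)
  expect_equal(nrow(back), 50)
})
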