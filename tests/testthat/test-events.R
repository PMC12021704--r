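state1 <- list(age = 60, hba1c = 54, bmi = 34, sbp = 134,
               chol_hdl_ratio = 3.8, male = 1, smoker = 0,
               diabetes_duration = 1, on_statin = FALSE,
               on_antihypertensive = FALSE)

test_that("annual probability follows the hazard closed forms", {
  # unit hazard: all coefficients zero, exponential, intercept 0
  eq <- risk_equation("death", "exponential", intercept = 0)
  expect_equal(annual_probability(eq, state1), 1 - exp(-1))

  # calibration multiplier scales the hazard exactly
  eq2 <- risk_equation("death", "exponential", intercept = 0,
                       calibration_multiplier = 0.5)
  expect_equal(annual_probability(eq2, state1), 1 - exp(-0.5))

  # statin RR 0.75 on an H = 0.02 hazard -> 1 - exp(-0.015)
  eq3 <- risk_equation("mi", "exponential", intercept = log(0.02),
                       treatment_rr = c(statin = 0.75))
  st <- state1
  st$on_statin <- TRUE
  expect_equal(annual_probability(eq3, st), 1 - exp(-0.015))
  expect_equal(annual_probability(eq3, state1), 1 - exp(-0.02))
})

test_that("linear-predictor coefficients act on the named covariates", {
  eq <- risk_equation("mi", "exponential", intercept = -5,
                      coefficients = c(hba1c = 0.02, male = 0.3))
  p1 <- annual_probability(eq, state1)
  expect_equal(p1, 1 - exp(-exp(-5 + 0.02 * 54 + 0.3)))
  st_hi <- state1; st_hi$hba1c <- 70
  expect_gt(annual_probability(eq, st_hi), p1)  # monotone in +ve coefficient
  eq_bad <- risk_equation("mi", "exponential", intercept = -5,
                          coefficients = c(nonexistent = 1))
  expect_error(annual_probability(eq_bad, state1), "nonexistent")
})

test_that("history flags feed subsequent hazards", {
  eq <- risk_equation("death", "exponential", intercept = -3,
                      coefficients = c(hist_mi = 1))
  hist0 <- matrix(FALSE, 1, 1, dimnames = list(NULL, "mi"))
  hist1 <- matrix(TRUE, 1, 1, dimnames = list(NULL, "mi"))
  expect_equal(annual_probability(eq, state1, hist1),
               1 - exp(-exp(-2)))
  expect_gt(annual_probability(eq, state1, hist1),
            annual_probability(eq, state1, hist0))
})

test_that("small-hazard limit: p matches H to first order", {
  for (h in c(1e-4, 1e-5, 1e-6)) {
    eq <- risk_equation("mi", "exponential", intercept = log(h))
    expect_lt(abs(annual_probability(eq, state1) - h), 1e-6)
  }
})

test_that("zero hazards survive to max_age and infinite death hazard kills at entry", {
  pop <- small_population(30, seed = 41)
  traj <- flat_trajectories(pop, 10)
  none <- list(death = risk_equation("death", "exponential",
                                     intercept = -Inf))
  res <- simulate_events(pop, none, traj, max_age = 200, seed = 1)
  expect_true(all(is.na(res$death_year)))
  expect_equal(res$years_alive, rep(10, 30))

  sure <- list(death = risk_equation("death", "exponential",
                                     intercept = 50))
  res2 <- simulate_events(pop, sure, traj, max_age = 200, seed = 1)
  expect_equal(res2$death_year, rep(1L, 30))
  expect_error(simulate_events(pop, list(), traj), "death")
})

test_that("constant annual death probability gives geometric survival", {
  n <- 10000
  pop <- small_population(n, seed = 42)
  pop$age <- rep(30, n)  # far from max_age so no censoring
  traj <- flat_trajectories(pop, 60)
  eqs <- list(death = const_death_eq(0.1))
  res <- simulate_events(pop, eqs, traj, max_age = 200, seed = 5)
  died <- !is.na(res$death_year)
  expect_gt(mean(died), 0.99)
  # geometric mean 1/0.1 = 10, sd sqrt(0.9)/0.1 = 9.49
  se <- sqrt(0.9) / 0.1 / sqrt(n)
  expect_lt(abs(mean(res$death_year[died]) - 10), 3 * se + 0.2)
})

test_that("events are unique first occurrences and never follow death", {
  pop <- small_population(500, seed = 43)
  eqs <- read_risk_equations()
  traj <- simulate_trajectories(pop, 30)
  res <- simulate_events(pop, eqs, traj, seed = 7)
  dead <- !is.na(res$death_year)
  for (oc in setdiff(colnames(res$events), "death")) {
    yr <- res$events[dead, oc]
    expect_true(all(is.na(yr) | yr <= res$death_year[dead]))
  }
  # common random numbers: identical runs reproduce exactly
  res2 <- simulate_events(pop, eqs, traj, seed = 7)
  expect_identical(res$events, res2$events)
})

test_that("incidence is monotone in the calibration multiplier under CRN", {
  pop <- small_population(1000, seed = 44)
  traj <- flat_trajectories(pop, 10)
  base <- risk_equation("mi", "exponential", intercept = log(0.02))
  eqs <- list(mi = base, death = const_death_eq(0.02))
  u <- event_uniforms(1000, 10, c("mi", "death"), 9)
  inc <- vapply(c(0.25, 0.5, 1, 2, 4), function(m) {
    eqs$mi$calibration_multiplier <- m
    r <- simulate_events(pop, eqs, traj, max_age = 200, uniforms = u)
    mean(!is.na(r$events[, "mi"]))
  }, 0)
  expect_true(all(diff(inc) >= 0))
})

test_that("calibration bisection hits reachable targets and rejects others", {
  pop <- small_population(5000, seed = 45)
  eq <- risk_equation("mi", "exponential", intercept = log(0.02))
  death <- const_death_eq(0.02)

  # fixed point: target equal to the uncalibrated incidence
  eqs <- list(mi = eq, death = death)
  traj <- flat_trajectories(pop, 10)
  ord <- c("mi", "death")
  u <- event_uniforms(5000, 10, ord, t2dcea:::child_seed(3, "calibration"))
  r0 <- simulate_events(pop, eqs, traj, max_age = 200, uniforms = u)
  inc0 <- mean(!is.na(r0$events[, "mi"]))
  cal <- calibrate(eq, pop, inc0, horizon = 10, tol = 0.002,
                   equations = list(death = death),
                   drift = c(hba1c = 0, bmi = 0, sbp = 0,
                             chol_hdl_ratio = 0), seed = 3)
  expect_lt(abs(cal$calibration_multiplier - 1), 0.15)
  expect_lt(abs(attr(cal, "achieved") - inc0), 0.002)

  # halved target is reachable and verified by re-simulation
  cal2 <- calibrate(eq, pop, inc0 / 2, horizon = 10, tol = 0.002,
                    equations = list(death = death),
                    drift = c(hba1c = 0, bmi = 0, sbp = 0,
                              chol_hdl_ratio = 0), seed = 3)
  eqs2 <- list(mi = cal2, death = death)
  r2 <- simulate_events(pop, eqs2, traj, max_age = 200, uniforms = u)
  expect_lt(abs(mean(!is.na(r2$events[, "mi"])) - inc0 / 2), 0.002)

  expect_error(calibrate(eq, pop, 0, horizon = 10), "\\(0, 1\\)")
  expect_error(calibrate(eq, pop[0, ], 0.1, horizon = 10), "non-empty")
  expect_error(
    calibrate(risk_equation("mi", "exponential", intercept = -60),
              pop[1:200, ], 0.99, horizon = 5, seed = 3),
    "unreachable")
})
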