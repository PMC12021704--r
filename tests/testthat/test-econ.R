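test_that("discounting follows the present-value closed form", {
  expect_equal(discount(100, 0, 0.035), 100)
  expect_equal(round(discount(100, 1, 0.035), 3), 96.618)
  expect_equal(discount(100, 2, 0), 100)
  expect_equal(discount(100, 10, 0.035), 100 / 1.035^10)
  expect_error(discount(100, -1), "non-negative")
  expect_error(discount(100, 1, rate = -1.5), "exceed -1")
})

test_that("remission rule hand-traces on stated trajectories", {
  # below 48 at year 1, rises to 49 at year 3: remission in years 1-2 only
  expect_equal(remission_status(c(54, 47, 47, 49, 45)),
               c(TRUE, TRUE, FALSE, FALSE))
  # exactly 48 at year 1: never in remission (strict threshold)
  expect_equal(remission_status(c(54, 48, 45, 45)), c(FALSE, FALSE, FALSE))
  # constant 45: remission in every simulated year
  expect_equal(remission_status(c(45, 45, 45, 45)), c(TRUE, TRUE, TRUE))
  # no re-entry after remission ends
  expect_equal(remission_status(c(54, 47, 49, 44)), c(TRUE, FALSE, FALSE))
})

test_that("accrual matches hand-computed costs and QALYs", {
  cat0 <- default_catalogue()
  cat0$discount_rate <- 0
  cat0$management_cost <- 0
  cat0$medication_cost <- 0
  cat0$bmi_disutility <- 0
  cat0$utility_age_slope <- 0
  cat0$utility_male <- 0
  cat0$utility_intercept <- 0.8

  pop <- small_population(1, seed = 51)
  pop$is_male <- FALSE
  traj <- flat_trajectories(pop, 2)
  traj$hba1c[] <- 60  # never in remission
  no_events <- list(events = matrix(NA_integer_, 1, 1,
                                    dimnames = list(NULL, "death")),
                    death_year = NA_integer_, years_alive = 2)
  acc <- accrue(pop, no_events, traj, cat0, intervention_cost = 0)
  expect_equal(acc$qaly, 1.6)  # utility 0.8 for 2 undiscounted years
  expect_equal(acc$cost, 0)

  # death in year 1: accrual stops afterwards
  died <- list(events = matrix(1L, 1, 1, dimnames = list(NULL, "death")),
               death_year = 1L, years_alive = 1)
  acc_d <- accrue(pop, died, traj, cat0)
  expect_equal(acc_d$qaly, 0.8)

  # a single MI in year 2 contributes its first-year cost discounted twice
  cat35 <- cat0
  cat35$discount_rate <- 0.035
  ev_mi <- list(events = matrix(c(2L, NA_integer_), 1, 2,
                                dimnames = list(NULL, c("mi", "death"))),
                death_year = NA_integer_, years_alive = 2)
  acc_mi <- accrue(pop, ev_mi, traj, cat35)
  expect_equal(acc_mi$cost, cat35$event_cost_first[["mi"]] / 1.035^2)
  # and its utility decrement applies from the event year
  expect_equal(acc_mi$qaly,
               0.8 / 1.035 + (0.8 - cat35$utility_decrement[["mi"]]) / 1.035^2)
})

test_that("medication costs are removed during remission years", {
  cat0 <- default_catalogue()
  cat0$discount_rate <- 0
  cat0$management_cost <- 0
  pop <- small_population(1, seed = 52)
  traj <- flat_trajectories(pop, 3)
  no_events <- list(events = matrix(NA_integer_, 1, 1,
                                    dimnames = list(NULL, "death")),
                    death_year = NA_integer_, years_alive = 3)
  traj$hba1c[] <- 45  # remission throughout
  remit <- accrue(pop, no_events, traj, cat0)
  traj$hba1c[] <- 60  # never in remission
  no_remit <- accrue(pop, no_events, traj, cat0)
  expect_equal(remit$cost, 0)
  expect_equal(no_remit$cost, 3 * cat0$medication_cost)
  expect_gte(no_remit$cost, remit$cost)  # removing remission never cuts cost
})

test_that("discounting never increases accrued totals", {
  pop <- small_population(200, seed = 53)
  eqs <- read_risk_equations()
  traj <- simulate_trajectories(pop, 20)
  ev <- simulate_events(pop, eqs, traj, seed = 2)
  cat0 <- default_catalogue(); cat0$discount_rate <- 0
  cat35 <- default_catalogue()
  a0 <- accrue(pop, ev, traj, cat0)
  a35 <- accrue(pop, ev, traj, cat35)
  expect_true(all(a35$cost <= a0$cost + 1e-9))
  expect_true(all(a35$qaly <= a0$qaly + 1e-9))
})

test_that("two-arm summary computes increments, dominance and exact NMB", {
  mk <- function(cost, qaly) list(cost = cost, qaly = qaly)
  r <- summarize_cea(mk(c(100, 120), c(1.0, 1.2)), mk(c(90, 100), c(0.9, 1.0)),
                     thresholds = c(13000, 20000))
  expect_equal(r$incremental_cost, 15)
  expect_equal(r$incremental_qaly, 0.15, tolerance = 1e-9)
  expect_equal(unname(r$nmb),
               c(13000 * r$incremental_qaly - 15,
                 20000 * r$incremental_qaly - 15))

  # published arithmetic: 81 / 0.0353 -> 2290 at 3 significant figures
  r2 <- summarize_cea(mk(81, 0.0353), mk(0, 0))
  expect_equal(signif(r2$icer, 3), 2290)
  expect_equal(unname(r2$nmb["lambda_20000"]), 625)

  r3 <- summarize_cea(mk(-26, 0.0353), mk(0, 0))
  expect_equal(r3$icer_label, "Dominant")
  r4 <- summarize_cea(mk(10, -0.01), mk(0, 0))
  expect_equal(r4$icer_label, "Dominated")
  r5 <- summarize_cea(mk(5, 1), mk(5, 1))
  expect_equal(r5$icer_label, "Undefined")
})

test_that("lifetime comparison is reproducible and responds to remission", {
  pop <- small_population(400, seed = 54)
  eqs <- read_risk_equations()
  r1 <- lifetime_cea(pop, eqs, n_years = 25, seed = 6)
  r2 <- lifetime_cea(pop, eqs, n_years = 25, seed = 6)
  expect_equal(r1$incremental_cost, r2$incremental_cost)
  expect_equal(r1$incremental_qaly, r2$incremental_qaly)
  expect_s3_class(r1, "cea_result")
  expect_output(print(r1), "Lifetime")
})
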