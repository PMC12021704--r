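#' Cost and utility catalogue for the lifetime model
#'
#' Per-outcome first-year and subsequent-year healthcare costs (GBP),
#' additive utility decrements, the annual diabetes management and
#' medication costs, age/sex-dependent baseline utility, a direct
#' BMI-related utility decrement, and the discount rate (3.5% per year,
#' the UK reference-case rate). Medication costs are removed during years
#' of diabetes remission. The shipped default catalogue is illustrative:
#' magnitudes follow the UK health-economics literature but are not the
#' confidential tariffs of any specific model.
#'
#' Baseline utility is `utility_intercept - utility_age_slope * (age - 60)
#' + utility_male * male - bmi_disutility * max(bmi - 25, 0)`, floored at
#' the EQ-5D index minimum of -0.594 after event decrements.
#'
#' @param path Optional YAML file with a `catalogue` section overriding
#'   the defaults.
#' @return An object of class `cost_utility_catalogue`.
#' @export
default_catalogue <- function(path = NULL) {
  cat_list <- list(
    event_cost_first = c(mi = 6000, stroke = 9500, chf = 4500, ihd = 3500,
                         amputation = 12000, blindness = 2500, ulcer = 2000,
                         renal_failure = 25000, death = 0),
    event_cost_subsequent = c(mi = 1500, stroke = 3000, chf = 1500,
                              ihd = 1000, amputation = 2500, blindness = 500,
                              ulcer = 500, renal_failure = 25000, death = 0),
    utility_decrement = c(mi = 0.055, stroke = 0.16, chf = 0.10, ihd = 0.09,
                          amputation = 0.28, blindness = 0.074, ulcer = 0.17,
                          renal_failure = 0.26, death = 0),
    management_cost = 450,
    medication_cost = 300,
    utility_intercept = 0.85,
    utility_age_slope = 0.0035,
    utility_male = 0.02,
    bmi_disutility = 0.006,
    discount_rate = 0.035
  )
  if (!is.null(path)) {
    over <- yaml::read_yaml(path)$catalogue
    for (nm in names(over)) {
      v <- over[[nm]]
      cat_list[[nm]] <- if (is.list(v)) unlist(v) else v
    }
  }
  validate_catalogue(cat_list)
}

validate_catalogue <- function(cat_list) {
  if (any(cat_list$event_cost_first < 0) ||
      any(cat_list$event_cost_subsequent < 0) ||
      cat_list$management_cost < 0 || cat_list$medication_cost < 0) {
    stop("catalogue costs must be non-negative")
  }
  if (any(cat_list$utility_decrement < 0)) {
    stop("utility decrements must be non-negative")
  }
  if (cat_list$discount_rate <= -1) stop("discount rate must exceed -1")
  structure(cat_list, class = "cost_utility_catalogue")
}

#' Present value of an amount accruing in a given year
#'
#' @param amount Amount (GBP or QALYs).
#' @param year Years from model entry; year 0 is undiscounted.
#' @param rate Annual discount rate (default 0.035).
#' @return `amount / (1 + rate)^year`.
#' @examples
#' discount(100, 1)  # 96.618...
#' @export
discount <- function(amount, year, rate = 0.035) {
  if (any(year < 0)) stop("year must be non-negative")
  if (rate <= -1) stop("discount rate must exceed -1")
  amount / (1 + rate)^year
}

#' Diabetes remission status along an HbA1c trajectory
#'
#' A simulated participant whose HbA1c is below 48 mmol/mol (6.5%) at 12
#' months (year 1) is in remission from year 1; remission ends
#' permanently at the first subsequent year in which HbA1c is at or above
#' 48 mmol/mol. Participants at exactly 48 at year 1 are never in
#' remission (strict threshold).
#'
#' @param hba1c Numeric vector or matrix of HbA1c by year (column 1 =
#'   year 0 baseline); matrices are persons by years.
#' @return Logical vector/matrix of the same shape excluding year 0:
#'   remission status in years `1..n`.
#' @examples
#' remission_status(c(54, 47, 47, 49, 45))  # TRUE TRUE FALSE FALSE
#' @export
remission_status <- function(hba1c) {
  if (is.null(dim(hba1c))) hba1c <- matrix(hba1c, nrow = 1)
  n_years <- ncol(hba1c) - 1
  if (n_years < 1) stop("trajectory must cover at least year 1")
  below <- hba1c[, -1, drop = FALSE] < 48
  # in remission while every year from 1 up to now has stayed below 48
  status <- if (ncol(below) == 1) below else t(apply(below, 1, cumprod)) == 1
  if (nrow(status) == 1 && nrow(hba1c) == 1) status <- drop(status)
  status
}

#' Accrue discounted lifetime costs and QALYs for a simulated cohort
#'
#' For every year a person is alive: costs are the annual diabetes
#' management cost, plus the medication cost (removed in remission
#' years), plus event costs (first-year cost in the event year,
#' subsequent-year cost in every later year); utility is the age/sex
#' baseline minus the BMI decrement minus the additive decrements of all
#' outcomes incurred so far, floored at -0.594. Both streams are
#' discounted; the per-person intervention cost is added once at year 0
#' undiscounted.
#'
#' @param population Data frame from [generate_population()].
#' @param events Result of [simulate_events()].
#' @param trajectories Result of [simulate_trajectories()] (same arm).
#' @param catalogue A [default_catalogue()].
#' @param intervention_cost Per-person programme cost (GBP) at entry.
#' @return A list with per-person vectors `cost` and `qaly` (discounted),
#'   and the remission matrix used.
#' @export
accrue <- function(population, events, trajectories, catalogue,
                   intervention_cost = 0) {
  n <- nrow(population)
  n_years <- ncol(trajectories$hba1c) - 1
  rate <- catalogue$discount_rate
  remit <- remission_status(trajectories$hba1c)
  if (is.null(dim(remit))) remit <- matrix(remit, nrow = n)
  outcomes <- colnames(events$events)
  cost <- rep(intervention_cost, n)
  qaly <- numeric(n)
  alive_years <- events$years_alive
  for (t in seq_len(n_years)) {
    alive <- alive_years >= t
    if (!any(alive)) break
    disc <- 1 / (1 + rate)^t
    med <- ifelse(remit[, t], 0, catalogue$medication_cost)
    yr_cost <- catalogue$management_cost + med
    util <- catalogue$utility_intercept -
      catalogue$utility_age_slope * (trajectories$age[, t + 1] - 60) +
      catalogue$utility_male * as.numeric(population$is_male) -
      catalogue$bmi_disutility * pmax(trajectories$bmi[, t + 1] - 25, 0)
    for (oc in setdiff(outcomes, "death")) {
      yr <- events$events[, oc]
      first <- !is.na(yr) & yr == t
      later <- !is.na(yr) & yr < t
      yr_cost <- yr_cost + first * catalogue$event_cost_first[[oc]] +
        later * catalogue$event_cost_subsequent[[oc]]
      util <- util - (first | later) * catalogue$utility_decrement[[oc]]
    }
    util <- pmax(util, -0.594)
    cost <- cost + alive * yr_cost * disc
    qaly <- qaly + alive * util * disc
  }
  list(cost = unname(cost), qaly = unname(qaly), remission = remit)
}

#' Summarise a two-arm lifetime comparison
#'
#' @param dew,de Accrual lists from [accrue()] for the intervention and
#'   comparator arms.
#' @param thresholds Willingness-to-pay thresholds (GBP/QALY).
#' @param label Scenario label.
#' @return An object of class `cea_result`: per-arm mean discounted costs
#'   and QALYs, increments, the ICER (or `"Dominant"`/`"Dominated"`), and
#'   the incremental net monetary benefit at each threshold.
#' @export
summarize_cea <- function(dew, de, thresholds = c(13000, 20000, 30000),
                          label = "base case") {
  if (!length(dew$cost) || !length(de$cost)) stop("both arms must be non-empty")
  dc <- mean(dew$cost) - mean(de$cost)
  dq <- mean(dew$qaly) - mean(de$qaly)
  nmb <- vapply(thresholds, function(l) incremental_nmb(dc, dq, l), 0)
  names(nmb) <- paste0("lambda_", thresholds)
  icer <- if (dq == 0) {
    NA_real_
  } else dc / dq
  icer_label <- if (dc < 0 && dq > 0) {
    "Dominant"
  } else if (dc > 0 && dq < 0) {
    "Dominated"
  } else if (dq == 0) {
    "Undefined"
  } else {
    format(round(icer), big.mark = "")
  }
  structure(list(
    label = label,
    cost_dew = mean(dew$cost), cost_de = mean(de$cost),
    qaly_dew = mean(dew$qaly), qaly_de = mean(de$qaly),
    incremental_cost = dc, incremental_qaly = dq,
    icer = icer, icer_label = icer_label, nmb = nmb,
    thresholds = thresholds, n = length(dew$cost)
  ), class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat("Lifetime cost-utility comparison:", x$label, "\n")
  cat(sprintf("  n = %d simulated individuals per arm\n", x$n))
  cat(sprintf("  Discounted cost  DEW %10.0f   DE %10.0f   increment %8.0f\n",
              x$cost_dew, x$cost_de, x$incremental_cost))
  cat(sprintf("  Discounted QALYs DEW %10.4f   DE %10.4f   increment %8.4f\n",
              x$qaly_dew, x$qaly_de, x$incremental_qaly))
  cat("  ICER:", x$icer_label,
      if (!x$icer_label %in% c("Dominant", "Dominated", "Undefined"))
        "GBP/QALY" else "", "\n")
  for (i in seq_along(x$thresholds)) {
    cat(sprintf("  NMB at %6d GBP/QALY: %8.0f\n", x$thresholds[i], x$nmb[i]))
  }
  invisible(x)
}

#' @export
summary.cea_result <- function(object, ...) {
  data.frame(
    label = object$label,
    cost_dew = object$cost_dew, cost_de = object$cost_de,
    qaly_dew = object$qaly_dew, qaly_de = object$qaly_de,
    incremental_cost = object$incremental_cost,
    incremental_qaly = object$incremental_qaly,
    icer = object$icer_label,
    nmb_20000 = unname(object$nmb[match(20000, object$thresholds)])
  )
}

#' Run the lifetime microsimulation for both arms
#'
#' Simulates the comparator and intervention arms on the same population
#' with common random numbers (identical event uniforms), so arm
#' differences reflect only the intervention-effect profile, the
#' remission medication offset and the intervention cost difference.
#'
#' @param population Data frame from [generate_population()].
#' @param equations Named list of [risk_equation()].
#' @param profile An [effect_profile()].
#' @param catalogue A [default_catalogue()].
#' @param dew_cost,de_cost Per-person programme costs (GBP).
#' @param n_years Simulated annual cycles (default 45, effectively
#'   lifetime for this population with `max_age` 100).
#' @param max_age Age at which simulation stops.
#' @param drift Annual risk-factor drift, see [default_drift()].
#' @param thresholds NMB thresholds.
#' @param seed Integer seed.
#' @param label Scenario label.
#' @return A `cea_result` with the per-arm accruals attached as
#'   attribute `"arms"`.
#' @export
lifetime_cea <- function(population, equations = read_risk_equations(),
                         profile = effect_profile(),
                         catalogue = default_catalogue(),
                         dew_cost = 325, de_cost = 158,
                         n_years = 45, max_age = 100,
                         drift = default_drift(),
                         thresholds = c(13000, 20000, 30000), seed = 1L,
                         label = "base case") {
  ord <- outcome_order(equations)
  u <- event_uniforms(nrow(population), n_years, ord, seed)
  run_arm <- function(arm, cost) {
    traj <- simulate_trajectories(population, n_years, drift = drift,
                                  profile = profile, arm = arm)
    ev <- simulate_events(population, equations, traj, max_age = max_age,
                          uniforms = u)
    accrue(population, ev, traj, catalogue, intervention_cost = cost)
  }
  de <- run_arm("DE", de_cost)
  dew <- run_arm("DEW", dew_cost)
  res <- summarize_cea(dew, de, thresholds, label = label)
  attr(res, "arms") <- list(dew = dew, de = de)
  res
}
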