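#' Intervention-effect profile with decay horizons
#'
#' Arm-level differences (DEW minus DE) in HbA1c and weight at 6 and 12
#' months, and the horizons over which the 12-month effects decay in the
#' lifetime model. Defaults are the trial's adjusted estimates: weight
#' -1.77 kg at 6 months and -1.38 kg at 12 months; HbA1c -1.83 mmol/mol at
#' 6 months and -0.84 mmol/mol at 12 months. The lifetime model assumes
#' the full 12-month effect at year 1, declining linearly (or
#' exponentially, see `decay_shape`) to exactly zero at the horizon: 5
#' years for HbA1c and 10 years for BMI. Weight effects are converted to
#' BMI units through height, imputed from the cohort's mean baseline
#' weight and BMI (`height = sqrt(weight / bmi)`, 1.68 m by default).
#'
#' @param hba1c_effect_12m,hba1c_effect_6m HbA1c differences (mmol/mol).
#' @param weight_effect_12m,weight_effect_6m Weight differences (kg).
#' @param height_m Height (m) used to convert kg to kg/m2.
#' @param hba1c_decay_horizon,bmi_decay_horizon Years after which the
#'   respective effect is exactly zero; must exceed 1.
#' @param decay_shape `"linear"` or `"exponential"` (exponential-to-zero:
#'   exponential decline rescaled to reach zero at the horizon).
#' @return An object of class `effect_profile` with the derived
#'   `bmi_effect_12m` (kg/m2).
#' @export
effect_profile <- function(hba1c_effect_12m = -0.84, weight_effect_12m = -1.38,
                           hba1c_effect_6m = -1.83, weight_effect_6m = -1.77,
                           height_m = sqrt(97.8 / 34.6),
                           hba1c_decay_horizon = 5, bmi_decay_horizon = 10,
                           decay_shape = c("linear", "exponential")) {
  if (hba1c_decay_horizon <= 1 || bmi_decay_horizon <= 1) {
    stop("decay horizons must exceed 1 year")
  }
  decay_shape <- match.arg(decay_shape)
  structure(list(
    hba1c_effect_12m = hba1c_effect_12m,
    hba1c_effect_6m = hba1c_effect_6m,
    weight_effect_12m = weight_effect_12m,
    weight_effect_6m = weight_effect_6m,
    bmi_effect_12m = weight_effect_12m / height_m^2,
    hba1c_decay_horizon = hba1c_decay_horizon,
    bmi_decay_horizon = bmi_decay_horizon,
    decay_shape = decay_shape
  ), class = "effect_profile")
}

#' Intervention effect remaining at a given time
#'
#' The full 12-month effect applies at `t = 1` year (and throughout the
#' first year); it then declines to exactly zero at the variable's decay
#' horizon and stays zero thereafter. Within the first year the effect
#' ramps in linearly from zero at baseline (`t = 0`), so that both arms
#' share the baseline state. The linear shape interpolates between
#' `(1, full)` and `(horizon, 0)`; the exponential shape declines at rate
#' `rate` but is shifted and rescaled so it also reaches exactly zero at
#' the horizon.
#'
#' @param profile An [effect_profile()].
#' @param variable `"hba1c"` or `"bmi"`.
#' @param t Time since model entry (years), non-negative; vectorised.
#' @param rate Decay rate for the exponential shape.
#' @return Effect size in the variable's units (mmol/mol or kg/m2).
#' @examples
#' effect_at(effect_profile(), "hba1c", 5)  # 0: horizon reached
#' @export
effect_at <- function(profile, variable, t, rate = 0.5) {
  stopifnot(inherits(profile, "effect_profile"))
  if (any(t < 0)) stop("t must be non-negative")
  full <- switch(variable,
    hba1c = profile$hba1c_effect_12m,
    bmi = profile$bmi_effect_12m,
    stop("unknown variable: ", variable)
  )
  horizon <- switch(variable,
    hba1c = profile$hba1c_decay_horizon,
    bmi = profile$bmi_decay_horizon
  )
  decay <- if (profile$decay_shape == "linear") {
    pmax(0, (horizon - t) / (horizon - 1))
  } else {
    raw <- (exp(-rate * (pmax(t, 1) - 1)) - exp(-rate * (horizon - 1))) /
      (1 - exp(-rate * (horizon - 1)))
    ifelse(t >= horizon, 0, pmax(0, raw))
  }
  frac <- ifelse(t <= 1, pmin(t, 1), pmin(1, decay))
  full * frac
}

#' Default annual risk-factor drifts
#'
#' Common secular trajectories applied to both arms: HbA1c rises by 0.5
#' mmol/mol per year (progressive beta-cell decline), BMI is flat, SBP and
#' the cholesterol:HDL ratio are flat. Override via the `drift` section of
#' the configuration.
#'
#' @return Named numeric vector of annual additive changes.
#' @export
default_drift <- function() {
  c(hba1c = 0.5, bmi = 0, sbp = 0, chol_hdl_ratio = 0)
}

#' Advance a cohort's risk-factor state by one annual cycle
#'
#' Applies the configured natural drift to every tracked risk factor, then
#' overwrites the arm effect as an offset from the common trajectory:
#' `value = common + effect_at(profile, variable, year)` for the
#' intervention arm, with the comparator following the common trajectory
#' exactly. Deterministic given the configuration.
#'
#' @param state A data frame (or list) with columns `hba1c`, `bmi`, `sbp`,
#'   `chol_hdl_ratio`, `smoker`, `age` and attribute-free numeric `year`.
#' @param drift Named vector of annual additive changes; must name every
#'   continuous variable it is asked to move.
#' @param profile An [effect_profile()] or `NULL` for no intervention.
#' @param arm `"DEW"` or `"DE"`.
#' @return The state advanced by one year (age incremented; `year`
#'   incremented; drifted values with the decayed arm effect applied).
#' @export
advance_year <- function(state, drift = default_drift(), profile = NULL,
                         arm = "DE") {
  vars <- c("hba1c", "bmi", "sbp", "chol_hdl_ratio")
  missing_drift <- setdiff(vars, names(drift))
  if (length(missing_drift)) {
    stop("drift configuration missing variable(s): ",
         paste(missing_drift, collapse = ", "))
  }
  year_next <- state$year + 1
  # last year's effect is removed before drifting and the newly decayed
  # effect re-applied, so effects decay rather than accumulate
  for (v in vars) {
    common <- state[[v]]
    if (!is.null(profile) && arm == "DEW" && v %in% c("hba1c", "bmi")) {
      common <- common - effect_at(profile, v, state$year)
    }
    common <- common + drift[[v]]
    eff <- if (!is.null(profile) && arm == "DEW" && v %in% c("hba1c", "bmi")) {
      effect_at(profile, v, year_next)
    } else 0
    state[[v]] <- common + eff
  }
  state$age <- state$age + 1
  state$year <- year_next
  state
}

#' Simulate full risk-factor trajectories for a cohort
#'
#' Builds per-person annual trajectories from baseline out to `n_years`,
#' applying drift and (for the intervention arm) the decaying effect
#' profile. Year 0 is baseline; the arm effect first applies at year 1.
#'
#' @param population Data frame from [generate_population()].
#' @param n_years Number of annual cycles.
#' @param drift Named drift vector, see [default_drift()].
#' @param profile An [effect_profile()] or `NULL`.
#' @param arm `"DEW"` or `"DE"`.
#' @return A list of matrices (`hba1c`, `bmi`, `sbp`, `chol_hdl_ratio`,
#'   `age`), each `nrow(population)` by `n_years + 1` (columns are years
#'   0..n_years).
#' @export
simulate_trajectories <- function(population, n_years, drift = default_drift(),
                                  profile = NULL, arm = "DE") {
  n <- nrow(population)
  base <- list(
    hba1c = population$hba1c,
    bmi = population$bmi,
    sbp = population$sbp,
    chol_hdl_ratio = population$total_chol / population$hdl,
    age = population$age
  )
  out <- lapply(base, function(v) {
    m <- matrix(NA_real_, n, n_years + 1)
    m[, 1] <- v
    m
  })
  is_dew <- !is.null(profile) && arm == "DEW"
  for (t in seq_len(n_years)) {
    for (v in c("hba1c", "bmi", "sbp", "chol_hdl_ratio")) {
      common <- base[[v]] + t * drift[[v]]
      eff <- if (is_dew && v %in% c("hba1c", "bmi")) {
        effect_at(profile, v, t)
      } else 0
      out[[v]][, t + 1] <- common + eff
    }
    out$age[, t + 1] <- base$age + t
  }
  out
}

#' Export trajectories as a person-year table
#'
#' @param traj Result of [simulate_trajectories()].
#' @param ids Person identifiers.
#' @return A long data frame with one row per person-year, for audit.
#' @export
trajectory_table <- function(traj, ids = seq_len(nrow(traj$hba1c))) {
  n <- nrow(traj$hba1c)
  yrs <- ncol(traj$hba1c) - 1
  data.frame(
    id = rep(ids, times = yrs + 1),
    year = rep(0:yrs, each = n),
    hba1c = as.vector(traj$hba1c),
    bmi = as.vector(traj$bmi),
    sbp = as.vector(traj$sbp),
    chol_hdl_ratio = as.vector(traj$chol_hdl_ratio),
    age = as.vector(traj$age)
  )
}
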