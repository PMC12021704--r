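#' Probabilistic sensitivity analysis specification
#'
#' Parameter uncertainty is propagated by sampling each uncertain
#' parameter from a distribution matched to its support, following
#' standard health-economics conventions: normal for effect sizes,
#' gamma for costs, beta for probabilities/utility quantities, lognormal
#' for relative risks and hazard multipliers. Draws are independent
#' across parameters.
#'
#' Each parameter is a list with `name`, `dist` (`"normal"`,
#' `"lognormal"`, `"beta"`, `"gamma"`) and hyperparameters (`mean`/`sd`
#' for normal; `meanlog`/`sdlog` for lognormal; `mean`/`se` for beta and
#' gamma, converted by moment matching). Recognised names:
#' `hba1c_effect_12m`, `weight_effect_12m` (effect profile);
#' `management_cost`, `medication_cost`, `bmi_disutility` (catalogue);
#' `calibration_<outcome>` (multiplies the outcome's calibration
#' multiplier).
#'
#' @param n_samples Number of PSA draws (default 2000).
#' @param parameters List of parameter definitions (see Details).
#' @param thresholds CEAC thresholds (GBP/QALY).
#' @param seed Integer seed.
#' @return An object of class `psa_spec`.
#' @export
psa_spec <- function(n_samples = 2000, parameters = default_psa_parameters(),
                     thresholds = c(13000, 20000, 30000), seed = 1L) {
  if (n_samples < 1) stop("n_samples must be at least 1")
  for (p in parameters) validate_psa_parameter(p)
  structure(list(n_samples = as.integer(n_samples), parameters = parameters,
                 thresholds = thresholds, seed = as.integer(seed)),
            class = "psa_spec")
}

#' @rdname psa_spec
#' @export
default_psa_parameters <- function() {
  list(
    list(name = "hba1c_effect_12m", dist = "normal", mean = -0.84, sd = 1.10),
    list(name = "weight_effect_12m", dist = "normal", mean = -1.38, sd = 0.60),
    list(name = "management_cost", dist = "gamma", mean = 450, se = 45),
    list(name = "medication_cost", dist = "gamma", mean = 300, se = 30),
    list(name = "bmi_disutility", dist = "beta", mean = 0.006, se = 0.0015),
    list(name = "calibration_mi", dist = "lognormal", meanlog = 0, sdlog = 0.15),
    list(name = "calibration_stroke", dist = "lognormal", meanlog = 0,
         sdlog = 0.15)
  )
}

validate_psa_parameter <- function(p) {
  if (is.null(p$name) || is.null(p$dist)) {
    stop("each PSA parameter needs a name and a dist")
  }
  switch(p$dist,
    normal = if (is.null(p$mean) || is.null(p$sd) || p$sd < 0) {
      stop("invalid normal hyperparameters for ", p$name)
    },
    lognormal = if (is.null(p$meanlog) || is.null(p$sdlog) || p$sdlog < 0) {
      stop("invalid lognormal hyperparameters for ", p$name)
    },
    gamma = if (is.null(p$mean) || is.null(p$se) || p$mean <= 0 || p$se < 0) {
      stop("invalid gamma hyperparameters for ", p$name)
    },
    beta = {
      if (is.null(p$mean) || is.null(p$se) || p$mean <= 0 || p$mean >= 1 ||
          p$se < 0) {
        stop("invalid beta hyperparameters for ", p$name)
      }
      if (p$se > 0 && p$se^2 >= p$mean * (1 - p$mean)) {
        stop("beta se too large for mean, parameter ", p$name)
      }
    },
    stop("unknown distribution '", p$dist, "' for ", p$name)
  )
  invisible(TRUE)
}

sample_psa_parameter <- function(p, n) {
  switch(p$dist,
    normal = rnorm(n, p$mean, p$sd),
    lognormal = rlnorm(n, p$meanlog, p$sdlog),
    gamma = if (p$se == 0) rep(p$mean, n) else {
      shape <- (p$mean / p$se)^2
      rgamma(n, shape = shape, rate = shape / p$mean)
    },
    beta = if (p$se == 0) rep(p$mean, n) else {
      nu <- p$mean * (1 - p$mean) / p$se^2 - 1
      rbeta(n, p$mean * nu, (1 - p$mean) * nu)
    }
  )
}

apply_psa_draw <- function(draw, profile, catalogue, equations) {
  for (nm in names(draw)) {
    v <- draw[[nm]]
    if (nm %in% c("hba1c_effect_12m", "weight_effect_12m")) {
      args <- list(hba1c_effect_12m = profile$hba1c_effect_12m,
                   weight_effect_12m = profile$weight_effect_12m,
                   hba1c_effect_6m = profile$hba1c_effect_6m,
                   weight_effect_6m = profile$weight_effect_6m,
                   hba1c_decay_horizon = profile$hba1c_decay_horizon,
                   bmi_decay_horizon = profile$bmi_decay_horizon,
                   decay_shape = profile$decay_shape)
      args[[nm]] <- v
      profile <- do.call(effect_profile, args)
    } else if (nm %in% names(unclass(catalogue)) &&
               !is.null(catalogue[[nm]]) && length(catalogue[[nm]]) == 1) {
      catalogue[[nm]] <- v
    } else if (startsWith(nm, "calibration_")) {
      oc <- sub("^calibration_", "", nm)
      if (!is.null(equations[[oc]])) {
        equations[[oc]]$calibration_multiplier <-
          equations[[oc]]$calibration_multiplier * v
      }
    } else {
      stop("PSA parameter '", nm, "' does not map to a model quantity")
    }
  }
  list(profile = profile, catalogue = catalogue, equations = equations)
}

#' Run the probabilistic sensitivity analysis
#'
#' For each of `spec$n_samples` draws, parameter values are sampled,
#' substituted into the effect profile, catalogue and risk equations, and
#' both arms are re-run on the same population with the same event
#' uniforms (common random numbers across arms and draws), recording the
#' incremental cost and QALYs. Fully reproducible from the spec seed.
#'
#' @param spec A [psa_spec()].
#' @param population Data frame from [generate_population()].
#' @param equations,profile,catalogue Base-case model inputs.
#' @param dew_cost,de_cost Programme costs (GBP).
#' @param n_years,max_age,drift Simulation settings as in
#'   [lifetime_cea()].
#' @return An object of class `psa_result`: `draws` (data frame of
#'   `delta_cost`, `delta_qaly`), `ceac`, expected NMB per threshold, and
#'   the base-case `cea_result`.
#' @export
run_psa <- function(spec, population, equations = read_risk_equations(),
                    profile = effect_profile(),
                    catalogue = default_catalogue(),
                    dew_cost = 325, de_cost = 158, n_years = 45,
                    max_age = 100, drift = default_drift()) {
  stopifnot(inherits(spec, "psa_spec"))
  for (p in spec$parameters) validate_psa_parameter(p)
  nm <- vapply(spec$parameters, `[[`, "", "name")
  samples <- with_seed(child_seed(spec$seed, "psa"), {
    out <- lapply(spec$parameters, sample_psa_parameter, n = spec$n_samples)
    names(out) <- nm
    as.data.frame(out)
  })
  base <- lifetime_cea(population, equations, profile, catalogue,
                       dew_cost, de_cost, n_years, max_age, drift,
                       thresholds = spec$thresholds, seed = spec$seed)
  draws <- matrix(NA_real_, spec$n_samples, 2,
                  dimnames = list(NULL, c("delta_cost", "delta_qaly")))
  for (i in seq_len(spec$n_samples)) {
    mod <- apply_psa_draw(as.list(samples[i, , drop = FALSE]),
                          profile, catalogue, equations)
    res <- lifetime_cea(population, mod$equations, mod$profile,
                        mod$catalogue, dew_cost, de_cost, n_years, max_age,
                        drift, thresholds = spec$thresholds, seed = spec$seed)
    draws[i, ] <- c(res$incremental_cost, res$incremental_qaly)
  }
  draws <- as.data.frame(draws)
  cc <- ceac(draws, spec$thresholds)
  enmb <- vapply(spec$thresholds, function(l) {
    mean(incremental_nmb(draws$delta_cost, draws$delta_qaly, l))
  }, 0)
  structure(list(draws = draws, ceac = cc,
                 expected_nmb = stats::setNames(enmb,
                   paste0("lambda_", spec$thresholds)),
                 thresholds = spec$thresholds, base_case = base,
                 samples = samples),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat("Probabilistic sensitivity analysis:", nrow(x$draws), "draws\n")
  cat(sprintf("  Mean incremental cost: %8.0f   mean incremental QALYs: %.4f\n",
              mean(x$draws$delta_cost), mean(x$draws$delta_qaly)))
  for (i in seq_along(x$thresholds)) {
    cat(sprintf("  At %6d GBP/QALY: P(cost-effective) %.2f, expected NMB %8.0f\n",
                x$thresholds[i], x$ceac$probability[i], x$expected_nmb[i]))
  }
  invisible(x)
}

#' @export
plot.psa_result <- function(x, ...) {
  graphics::plot(x$draws$delta_qaly, x$draws$delta_cost,
                 xlab = "Incremental QALYs", ylab = "Incremental cost (GBP)",
                 main = "Cost-effectiveness plane", pch = 16,
                 col = grDevices::adjustcolor("steelblue", 0.5), ...)
  graphics::abline(h = 0, v = 0, lty = 3)
  invisible(x)
}

#' Probability that the intervention is cost-effective
#'
#' @param draws Data frame with `delta_cost`, `delta_qaly`.
#' @param threshold Willingness-to-pay (GBP/QALY).
#' @return Fraction of draws with `threshold*delta_qaly - delta_cost > 0`.
#' @export
probability_cost_effective <- function(draws, threshold) {
  if (nrow(draws) < 1) stop("at least one draw is required")
  mean(incremental_nmb(draws$delta_cost, draws$delta_qaly, threshold) > 0)
}

#' Subgroup lifetime cost-effectiveness
#'
#' Runs the two-arm lifetime simulation once on the full population with
#' common random numbers, then summarises incremental costs and QALYs
#' within strata of diabetes duration (under 1 year vs 1-3 years), BMI
#' category (under 28, 28-30, 30-35, 35-40, 40 and over kg/m2; bands are
#' half-open `[lower, upper)`) or IMD quintile. Partitioning a single
#' common-random-number run keeps the size-weighted subgroup increments
#' exactly consistent with the whole-population increments.
#'
#' @param population Data frame from [generate_population()].
#' @param grouping `"diabetes_duration"`, `"bmi_category"` or
#'   `"imd_quintile"`.
#' @param ... Passed to [lifetime_cea()].
#' @return A data frame with one row per stratum (empty strata reported
#'   with `NA` results) plus an `overall` row.
#' @export
subgroup_run <- function(population,
                         grouping = c("diabetes_duration", "bmi_category",
                                      "imd_quintile"), ...) {
  grouping <- match.arg(grouping)
  g <- switch(grouping,
    diabetes_duration = factor(ifelse(population$diabetes_duration < 1,
                                      "<1y", "1-3y"),
                               levels = c("<1y", "1-3y")),
    bmi_category = cut(population$bmi, c(-Inf, 28, 30, 35, 40, Inf),
                       labels = c("<28", "28-30", "30-35", "35-40", ">=40"),
                       right = FALSE),
    imd_quintile = factor(population$imd_quintile, levels = 1:5)
  )
  res <- lifetime_cea(population, ...)
  arms <- attr(res, "arms")
  strata <- levels(g)
  rows <- lapply(c(strata, "overall"), function(s) {
    idx <- if (s == "overall") rep(TRUE, nrow(population)) else g == s
    if (!any(idx)) {
      return(data.frame(stratum = s, n = 0, incremental_cost = NA_real_,
                        incremental_qaly = NA_real_, icer = NA_real_))
    }
    dc <- mean(arms$dew$cost[idx]) - mean(arms$de$cost[idx])
    dq <- mean(arms$dew$qaly[idx]) - mean(arms$de$qaly[idx])
    data.frame(stratum = s, n = sum(idx), incremental_cost = dc,
               incremental_qaly = dq,
               icer = if (dq != 0) dc / dq else NA_real_)
  })
  out <- do.call(rbind, rows)
  attr(out, "grouping") <- grouping
  out
}
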