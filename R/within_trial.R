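#' QALYs over 12 months by the trapezoidal rule
#'
#' Area under the linear interpolant of the EQ-5D utility index measured
#' at 0, 6 and 12 months, expressed in years (so constant utility `u`
#' yields `u` QALYs).
#'
#' @param utilities Length-3 vector (or 3-column matrix, persons by
#'   visits) of utilities at 0, 6, 12 months.
#' @param months Measurement times in months (default `c(0, 6, 12)`).
#' @return QALYs accrued over the measurement window.
#' @examples
#' qaly_auc(c(1.0, 0.5, 0.5))  # 0.625
#' @export
qaly_auc <- function(utilities, months = c(0, 6, 12)) {
  if (is.null(dim(utilities))) utilities <- matrix(utilities, nrow = 1)
  if (ncol(utilities) != length(months)) {
    stop("utilities and months must align")
  }
  if (anyNA(utilities)) {
    stop("missing utility values: impute or drop before computing QALYs")
  }
  yrs <- months / 12
  auc <- numeric(nrow(utilities))
  for (i in seq_len(length(months) - 1)) {
    auc <- auc + (yrs[i + 1] - yrs[i]) *
      (utilities[, i] + utilities[, i + 1]) / 2
  }
  if (length(auc) == 1) auc <- unname(auc[1])
  auc
}

#' Incremental net monetary benefit
#'
#' @param delta_cost Incremental cost (GBP), intervention minus
#'   comparator.
#' @param delta_qaly Incremental QALYs.
#' @param threshold Willingness-to-pay (GBP per QALY).
#' @return `threshold * delta_qaly - delta_cost` (GBP).
#' @examples
#' incremental_nmb(81, 0.0353, 20000)  # 625
#' @export
incremental_nmb <- function(delta_cost, delta_qaly, threshold) {
  threshold * delta_qaly - delta_cost
}

#' Cost-effectiveness acceptability curve from bootstrap draws
#'
#' @param draws Data frame or matrix with columns `delta_cost` and
#'   `delta_qaly`, one row per bootstrap (or PSA) draw.
#' @param thresholds Vector of willingness-to-pay thresholds.
#' @return An object of class `ceac`: data frame of `threshold` and
#'   `probability` (fraction of draws with positive NMB).
#' @export
ceac <- function(draws, thresholds = c(13000, 20000, 30000)) {
  draws <- as.data.frame(draws)
  if (nrow(draws) < 1) stop("at least one draw is required")
  prob <- vapply(thresholds, function(l) {
    mean(incremental_nmb(draws$delta_cost, draws$delta_qaly, l) > 0)
  }, 0)
  structure(data.frame(threshold = thresholds, probability = prob),
            class = c("ceac", "data.frame"))
}

#' @export
plot.ceac <- function(x, ...) {
  graphics::plot(x$threshold, x$probability, type = "b", ylim = c(0, 1),
                 xlab = "Willingness to pay (GBP/QALY)",
                 ylab = "P(cost-effective)",
                 main = "Cost-effectiveness acceptability curve", ...)
  graphics::abline(h = 0.5, lty = 3)
  invisible(x)
}

#' Incremental cost per unit of outcome improvement
#'
#' Outcome improvements (HbA1c or weight decreases) are counted positive,
#' so `delta_outcome` is comparator-minus-intervention for
#' lower-is-better outcomes. A negative incremental cost together with an
#' improvement is flagged dominant; a zero outcome difference leaves the
#' ratio undefined.
#'
#' @param delta_cost Incremental cost (GBP).
#' @param delta_outcome Outcome improvement (positive = intervention
#'   better).
#' @return List with `ratio`, `dominant`, `defined`.
#' @examples
#' cost_per_unit(100, 2)   # 50 GBP per unit
#' cost_per_unit(-232, 1)  # dominant
#' @export
cost_per_unit <- function(delta_cost, delta_outcome) {
  if (delta_outcome == 0) {
    return(list(ratio = NA_real_, dominant = FALSE, defined = FALSE))
  }
  list(ratio = delta_cost / delta_outcome,
       dominant = delta_cost < 0 && delta_outcome > 0,
       defined = TRUE)
}

#' Within-trial cost-utility analysis
#'
#' Twelve-month cost-utility comparison of the two arms from an NHS/PSS
#' perspective on a trial-record table: per-arm mean total costs
#' (healthcare use plus the per-person programme cost) and QALYs
#' ([qaly_auc()]), their increments, net monetary benefit at each
#' threshold, incremental cost per mmol/mol HbA1c and per kg weight
#' reduction, and a CEAC from a nonparametric person-level bootstrap
#' (paired resampling within arm). Complete-case analysis by default; the
#' `mean_impute` switch replaces missing 12-month outcomes by the arm
#' mean before analysis.
#'
#' @param trial Data frame from [generate_trial()] (or the same layout).
#' @param dew_cost,de_cost Per-person programme costs added to each arm.
#' @param thresholds NMB/CEAC thresholds (GBP/QALY).
#' @param n_boot Bootstrap replicates (default 5000).
#' @param seed Seed for the bootstrap.
#' @param mean_impute Impute missing 12-month outcomes by arm means
#'   instead of dropping incomplete cases.
#' @return An object of class `within_trial_cea`.
#' @export
within_trial_cea <- function(trial, dew_cost = 325, de_cost = 158,
                             thresholds = c(13000, 20000, 30000),
                             n_boot = 5000, seed = 1L,
                             mean_impute = FALSE) {
  needed <- c("arm", "utility_0", "utility_6", "utility_12", "weight_0",
              "weight_12", "hba1c_0", "hba1c_12", "healthcare_cost_0to6",
              "cost_6to12")
  miss <- setdiff(needed, names(trial))
  if (length(miss)) stop("trial table missing columns: ",
                         paste(miss, collapse = ", "))
  if (mean_impute) {
    for (v in c("utility_12", "weight_12", "hba1c_12")) {
      for (a in unique(trial$arm)) {
        idx <- trial$arm == a & is.na(trial[[v]])
        trial[[v]][idx] <- mean(trial[[v]][trial$arm == a], na.rm = TRUE)
      }
    }
  } else {
    trial <- trial[stats::complete.cases(
      trial[, c("utility_12", "weight_12", "hba1c_12")]), ]
  }
  trial$total_cost <- trial$healthcare_cost_0to6 + trial$cost_6to12 +
    ifelse(trial$arm == "DEW", dew_cost, de_cost)
  trial$qaly <- qaly_auc(as.matrix(trial[, c("utility_0", "utility_6",
                                             "utility_12")]))
  arm_stats <- function(d) {
    c(cost = mean(d$total_cost), qaly = mean(d$qaly),
      hba1c_chg = mean(d$hba1c_12 - d$hba1c_0),
      weight_chg = mean(d$weight_12 - d$weight_0))
  }
  dew <- trial[trial$arm == "DEW", ]
  de <- trial[trial$arm == "DE", ]
  s1 <- arm_stats(dew); s0 <- arm_stats(de)
  dc <- s1[["cost"]] - s0[["cost"]]
  dq <- s1[["qaly"]] - s0[["qaly"]]
  # improvements counted positive: comparator change minus intervention
  hba1c_impr <- s0[["hba1c_chg"]] - s1[["hba1c_chg"]]
  weight_impr <- s0[["weight_chg"]] - s1[["weight_chg"]]
  boot <- with_seed(child_seed(seed, "bootstrap"), {
    t(replicate(n_boot, {
      b1 <- dew[sample.int(nrow(dew), replace = TRUE), ]
      b0 <- de[sample.int(nrow(de), replace = TRUE), ]
      c(delta_cost = mean(b1$total_cost) - mean(b0$total_cost),
        delta_qaly = mean(b1$qaly) - mean(b0$qaly))
    }))
  })
  boot <- as.data.frame(boot)
  structure(list(
    n_dew = nrow(dew), n_de = nrow(de),
    cost_dew = s1[["cost"]], cost_de = s0[["cost"]],
    qaly_dew = s1[["qaly"]], qaly_de = s0[["qaly"]],
    incremental_cost = dc, incremental_qaly = dq,
    nmb = stats::setNames(
      vapply(thresholds, function(l) incremental_nmb(dc, dq, l), 0),
      paste0("lambda_", thresholds)),
    cost_per_mmolmol = cost_per_unit(dc, hba1c_impr),
    cost_per_kg = cost_per_unit(dc, weight_impr),
    ceac = ceac(boot, thresholds),
    bootstrap = boot, thresholds = thresholds
  ), class = "within_trial_cea")
}

#' @export
print.within_trial_cea <- function(x, ...) {
  cat("Within-trial (12-month) cost-utility analysis\n")
  cat(sprintf("  Complete cases: DEW %d, DE %d\n", x$n_dew, x$n_de))
  cat(sprintf("  Mean cost  DEW %8.0f   DE %8.0f   increment %8.0f\n",
              x$cost_dew, x$cost_de, x$incremental_cost))
  cat(sprintf("  Mean QALYs DEW %8.4f   DE %8.4f   increment %8.4f\n",
              x$qaly_dew, x$qaly_de, x$incremental_qaly))
  for (i in seq_along(x$thresholds)) {
    cat(sprintf("  NMB at %6d: %8.0f   P(cost-effective): %.2f\n",
                x$thresholds[i], x$nmb[i], x$ceac$probability[i]))
  }
  if (x$cost_per_mmolmol$dominant) {
    cat("  Cost per mmol/mol HbA1c reduction: dominant (cost-saving)\n")
  } else if (x$cost_per_mmolmol$defined) {
    cat(sprintf("  Cost per mmol/mol HbA1c reduction: %.0f\n",
                x$cost_per_mmolmol$ratio))
  }
  if (x$cost_per_kg$dominant) {
    cat("  Cost per kg weight reduction: dominant (cost-saving)\n")
  } else if (x$cost_per_kg$defined) {
    cat(sprintf("  Cost per kg weight reduction: %.0f\n", x$cost_per_kg$ratio))
  }
  invisible(x)
}

#' @export
summary.within_trial_cea <- function(object, ...) {
  data.frame(
    arm = c("DEW", "DE"),
    n = c(object$n_dew, object$n_de),
    mean_cost = c(object$cost_dew, object$cost_de),
    mean_qaly = c(object$qaly_dew, object$qaly_de)
  )
}
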