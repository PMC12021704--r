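#' Parametric annual-hazard risk equation
#'
#' One complication or death hazard, in the style of diabetes outcome
#' models: a log-linear predictor over risk-factor covariates wrapped in
#' one of four parametric forms, an overall calibration multiplier, and
#' multiplicative relative-risk modifiers for statin and antihypertensive
#' treatment. The annual hazard is
#' `H = calibration * prod(treatment RRs) * base_hazard`, converted to a
#' probability by `p = 1 - exp(-H)`.
#'
#' Forms (`d` = diabetes duration, `a` = current age, `lp` = intercept
#' plus coefficient-weighted covariates):
#' \describe{
#'   \item{exponential}{constant hazard `H = exp(lp)`}
#'   \item{weibull}{duration-dependent integrated annual hazard
#'     `H = exp(lp) * ((d+1)^shape - d^shape)`}
#'   \item{gompertz}{age-dependent integrated annual hazard
#'     `H = exp(lp) * (exp(shape*(a+1)) - exp(shape*a)) / shape`}
#'   \item{logistic}{annual probability `plogis(lp)`, back-converted to a
#'     hazard}
#' }
#'
#' The exact published coefficient values of proprietary outcome models
#' are not redistributed; the package ships an illustrative, clearly
#' synthetic parameter file and users supply their own coefficients for
#' substantive work.
#'
#' @param outcome One of `"mi"`, `"stroke"`, `"chf"`, `"ihd"`,
#'   `"amputation"`, `"blindness"`, `"ulcer"`, `"renal_failure"`,
#'   `"death"`.
#' @param form `"exponential"`, `"weibull"`, `"gompertz"` or `"logistic"`.
#' @param intercept Linear-predictor intercept.
#' @param coefficients Named numeric vector mapping covariate names to
#'   values. Recognised covariates: `hba1c`, `bmi`, `sbp`,
#'   `chol_hdl_ratio`, `age`, `male`, `smoker`, `diabetes_duration`, and
#'   post-event history flags `hist_<outcome>`.
#' @param shape Shape parameter for the weibull/gompertz forms.
#' @param calibration_multiplier Positive scalar scaling the hazard
#'   (default 1); set by [calibrate()].
#' @param treatment_rr Named vector of relative risks in `(0, 1]` applied
#'   when the person is on the treatment: names among `statin`,
#'   `antihypertensive`.
#' @return An object of class `risk_equation`.
#' @export
risk_equation <- function(outcome, form = "exponential", intercept = -Inf,
                          coefficients = numeric(), shape = 1,
                          calibration_multiplier = 1,
                          treatment_rr = c(statin = 1, antihypertensive = 1)) {
  outcomes <- c("mi", "stroke", "chf", "ihd", "amputation", "blindness",
                "ulcer", "renal_failure", "death")
  if (!outcome %in% outcomes) stop("unknown outcome: ", outcome)
  if (!form %in% c("exponential", "weibull", "gompertz", "logistic")) {
    stop("unknown form: ", form)
  }
  if (calibration_multiplier <= 0) stop("calibration_multiplier must be positive")
  if (any(treatment_rr <= 0) || any(treatment_rr > 1)) {
    stop("treatment RRs must lie in (0, 1]")
  }
  structure(list(outcome = outcome, form = form, intercept = intercept,
                 coefficients = coefficients, shape = shape,
                 calibration_multiplier = calibration_multiplier,
                 treatment_rr = treatment_rr),
            class = "risk_equation")
}

# Covariate matrix for a cohort at one cycle: columns named as the
# recognised covariates; `history` is a logical matrix of past events.
covariate_values <- function(names, state, history) {
  n <- length(state$age)
  sapply(names, function(nm) {
    if (nm %in% names(state)) {
      as.numeric(state[[nm]])
    } else if (startsWith(nm, "hist_")) {
      ev <- sub("^hist_", "", nm)
      if (!ev %in% colnames(history)) stop("missing covariate: ", nm)
      as.numeric(history[, ev])
    } else {
      stop("missing covariate: ", nm)
    }
  }, simplify = TRUE)
}

#' Annual event probability for each person in a cohort state
#'
#' @param eq A [risk_equation()].
#' @param state List/data frame with the current `age`, `hba1c`, `bmi`,
#'   `sbp`, `chol_hdl_ratio`, `male`, `smoker`, `diabetes_duration`,
#'   `on_statin`, `on_antihypertensive` for every person.
#' @param history Logical matrix (persons by outcomes) of events incurred
#'   in earlier cycles; feeds `hist_*` covariates.
#' @return Vector of annual probabilities in `[0, 1]`.
#' @examples
#' eq <- risk_equation("death", "exponential", intercept = 0)
#' st <- list(age = 60, hba1c = 54, bmi = 34, sbp = 134,
#'            chol_hdl_ratio = 3.8, male = 1, smoker = 0,
#'            diabetes_duration = 1, on_statin = FALSE,
#'            on_antihypertensive = FALSE)
#' annual_probability(eq, st)  # 1 - exp(-1)
#' @export
annual_probability <- function(eq, state, history = NULL) {
  stopifnot(inherits(eq, "risk_equation"))
  n <- length(state$age)
  if (is.null(history)) {
    history <- matrix(FALSE, n, 0)
  }
  lp <- rep(eq$intercept, n)
  if (length(eq$coefficients)) {
    x <- covariate_values(names(eq$coefficients), state, history)
    if (is.null(dim(x))) x <- matrix(x, nrow = n)
    lp <- lp + drop(x %*% eq$coefficients)
  }
  base_h <- switch(eq$form,
    exponential = exp(lp),
    weibull = {
      d <- pmax(state$diabetes_duration, 0)
      exp(lp) * ((d + 1)^eq$shape - d^eq$shape)
    },
    gompertz = {
      a <- state$age
      exp(lp) * (exp(eq$shape * (a + 1)) - exp(eq$shape * a)) / eq$shape
    },
    logistic = -log1p(-pmin(plogis(lp), 1 - 1e-12))
  )
  rr <- rep(1, n)
  if ("statin" %in% names(eq$treatment_rr)) {
    rr <- rr * ifelse(as.logical(state$on_statin), eq$treatment_rr[["statin"]], 1)
  }
  if ("antihypertensive" %in% names(eq$treatment_rr)) {
    rr <- rr * ifelse(as.logical(state$on_antihypertensive),
                      eq$treatment_rr[["antihypertensive"]], 1)
  }
  h <- eq$calibration_multiplier * rr * base_h
  pmin(pmax(1 - exp(-h), 0), 1)
}

#' Read risk equations from a parameter file
#'
#' The file is plain-text YAML: a list of blocks with `outcome`, `form`,
#' `intercept`, named `coefficients`, optional `shape`,
#' `calibration_multiplier` and `treatment_rr`. The shipped
#' `risk_equations_synthetic.yaml` is illustrative only.
#'
#' @param path Path to the YAML parameter file.
#' @return Named list of [risk_equation()] objects keyed by outcome.
#' @export
read_risk_equations <- function(path = system.file(
  "extdata", "risk_equations_synthetic.yaml", package = "t2dcea")) {
  if (!file.exists(path)) stop("risk-equation file not found: ", path)
  raw <- yaml::read_yaml(path)
  eqs <- lapply(raw$equations, function(b) {
    risk_equation(
      outcome = b$outcome,
      form = b$form %||% "exponential",
      intercept = b$intercept %||% -Inf,
      coefficients = unlist(b$coefficients) %||% numeric(),
      shape = b$shape %||% 1,
      calibration_multiplier = b$calibration_multiplier %||% 1,
      treatment_rr = unlist(b$treatment_rr) %||%
        c(statin = 1, antihypertensive = 1)
    )
  })
  names(eqs) <- vapply(eqs, `[[`, "", "outcome")
  eqs
}

# Fixed cycle order for event draws: alphabetical with death evaluated
# last, so a run is exactly reproducible.
outcome_order <- function(equations) {
  nm <- names(equations)
  c(sort(setdiff(nm, "death")), intersect("death", nm))
}

#' Simulate event histories for a cohort
#'
#' Annual loop from model entry to death or `max_age`: the risk-factor
#' state advances along the supplied trajectories, each outcome equation
#' is evaluated in a fixed order (alphabetical, death last), and events
#' are drawn by comparing pre-drawn uniforms with the annual probability.
#' Each outcome occurs at most once (first occurrence); the history flags
#' of earlier events feed subsequent hazards through `hist_*` covariates.
#'
#' With `uniforms` supplied (persons x years x outcomes array) the same
#' random numbers are reused across arms or calibration iterations
#' (common random numbers), which makes incidence monotone in hazard
#' scaling and sharply reduces comparison variance.
#'
#' @param population Data frame from [generate_population()].
#' @param equations Named list of [risk_equation()] covering `"death"`.
#' @param trajectories Result of [simulate_trajectories()] for this arm.
#' @param max_age Simulation stops at this age (default 100).
#' @param seed Seed used when `uniforms` is not supplied.
#' @param uniforms Optional pre-drawn array from [event_uniforms()].
#' @return A list: `events` (persons x outcomes matrix of first-occurrence
#'   years, `NA` if never), `death_year` (`NA` if alive at `max_age`),
#'   `years_alive` (completed years lived in the model, capped at
#'   `max_age - entry age`).
#' @export
simulate_events <- function(population, equations, trajectories,
                            max_age = 100, seed = 1L, uniforms = NULL) {
  if (!"death" %in% names(equations)) stop("equations must cover death")
  n <- nrow(population)
  n_years <- ncol(trajectories$hba1c) - 1
  ord <- outcome_order(equations)
  if (is.null(uniforms)) {
    uniforms <- event_uniforms(n, n_years, ord, seed)
  }
  events <- matrix(NA_integer_, n, length(ord), dimnames = list(NULL, ord))
  hist <- matrix(FALSE, n, length(ord), dimnames = list(NULL, ord))
  alive <- rep(TRUE, n)
  death_year <- rep(NA_integer_, n)
  for (t in seq_len(n_years)) {
    at_risk <- alive & (population$age + t <= max_age)
    if (!any(at_risk)) break
    state <- list(
      age = trajectories$age[, t + 1],
      hba1c = trajectories$hba1c[, t + 1],
      bmi = trajectories$bmi[, t + 1],
      sbp = trajectories$sbp[, t + 1],
      chol_hdl_ratio = trajectories$chol_hdl_ratio[, t + 1],
      male = as.numeric(population$is_male),
      smoker = as.numeric(population$smoker),
      diabetes_duration = population$diabetes_duration + t,
      on_statin = population$on_statin,
      on_antihypertensive = population$on_antihypertensive
    )
    for (oc in ord) {
      p <- annual_probability(equations[[oc]], state, hist)
      new_event <- at_risk & is.na(events[, oc]) & (uniforms[, t, oc] < p)
      events[new_event, oc] <- t
      if (oc == "death") {
        death_year[new_event] <- t
        alive[new_event] <- FALSE
      }
    }
    hist[] <- !is.na(events)
  }
  entry_cap <- pmin(n_years, pmax(0, max_age - population$age))
  years_alive <- ifelse(is.na(death_year), entry_cap, death_year)
  list(events = events, death_year = death_year, years_alive = years_alive)
}

#' Pre-draw the uniform deviates for an event simulation
#'
#' @param n Persons.
#' @param n_years Annual cycles.
#' @param outcomes Character vector of outcome names (draw order).
#' @param seed Integer seed.
#' @return A persons x years x outcomes array of uniforms.
#' @export
event_uniforms <- function(n, n_years, outcomes, seed = 1L) {
  with_seed(child_seed(seed, "events"), {
    array(runif(n * n_years * length(outcomes)),
          dim = c(n, n_years, length(outcomes)),
          dimnames = list(NULL, NULL, outcomes))
  })
}

#' Calibrate a risk equation to a target cumulative incidence
#'
#' Bisection on the log of the calibration multiplier until the simulated
#' cumulative incidence of the equation's outcome over `horizon` years in
#' `cohort` matches `target_cum_incidence` within `tol`. The same uniform
#' deviates are reused in every iteration (common random numbers), which
#' makes simulated incidence monotone non-decreasing in the multiplier and
#' guarantees bisection converges to the crossing point.
#'
#' @param eq A [risk_equation()] to calibrate.
#' @param cohort Data frame from [generate_population()].
#' @param target_cum_incidence Target proportion in (0, 1).
#' @param horizon Years over which incidence is accumulated.
#' @param tol Absolute tolerance on the incidence (default 0.002).
#' @param equations Optional full equation list (death competing risk
#'   included during calibration when supplied).
#' @param drift,seed Trajectory drift and RNG seed.
#' @param bounds Multiplier search bounds (default `c(1e-4, 1e4)`).
#' @param max_iter Bisection iteration cap.
#' @return The calibrated [risk_equation()] with its
#'   `calibration_multiplier` set; the achieved incidence is attached as
#'   attribute `achieved`.
#' @export
calibrate <- function(eq, cohort, target_cum_incidence, horizon = 10,
                      tol = 0.002, equations = NULL,
                      drift = default_drift(), seed = 1L,
                      bounds = c(1e-4, 1e4), max_iter = 60) {
  if (target_cum_incidence <= 0 || target_cum_incidence >= 1) {
    stop("target cumulative incidence must lie in (0, 1)")
  }
  if (nrow(cohort) == 0) stop("cohort must be non-empty")
  traj <- simulate_trajectories(cohort, horizon, drift = drift)
  eqs <- if (is.null(equations)) list() else equations
  eqs[[eq$outcome]] <- eq
  if (!"death" %in% names(eqs)) {
    eqs$death <- risk_equation("death", "exponential", intercept = -Inf)
  }
  ord <- outcome_order(eqs)
  u <- event_uniforms(nrow(cohort), horizon, ord, child_seed(seed, "calibration"))
  incidence_at <- function(mult) {
    eqs[[eq$outcome]]$calibration_multiplier <- mult
    res <- simulate_events(cohort, eqs, traj, max_age = 200, uniforms = u)
    mean(!is.na(res$events[, eq$outcome]))
  }
  lo <- bounds[1]; hi <- bounds[2]
  inc_lo <- incidence_at(lo); inc_hi <- incidence_at(hi)
  if (target_cum_incidence < inc_lo - tol || target_cum_incidence > inc_hi + tol) {
    stop("target incidence ", target_cum_incidence,
         " unreachable within multiplier bounds [", bounds[1], ", ",
         bounds[2], "] (achievable range ", signif(inc_lo, 3), "-",
         signif(inc_hi, 3), ")")
  }
  mid <- eq$calibration_multiplier
  for (i in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)  # bisection on the log scale
    inc <- incidence_at(mid)
    if (abs(inc - target_cum_incidence) <= tol) break
    if (inc < target_cum_incidence) lo <- mid else hi <- mid
  }
  eq$calibration_multiplier <- mid
  attr(eq, "achieved") <- incidence_at(mid)
  eq
}
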