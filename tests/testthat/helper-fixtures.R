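# Small shared fixtures, built in code at test time.

small_spec <- function(n = 500, seed = 11) cohort_spec(n = n, seed = seed)

small_population <- function(n = 500, seed = 11) {
  generate_population(small_spec(n, seed))
}

# single constant-hazard death equation: annual p = 1 - exp(-exp(intercept))
const_death_eq <- function(p_annual) {
  risk_equation("death", "exponential", intercept = log(-log(1 - p_annual)))
}

flat_trajectories <- function(population, n_years) {
  simulate_trajectories(population, n_years,
                        drift = c(hba1c = 0, bmi = 0, sbp = 0,
                                  chol_hdl_ratio = 0))
}
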