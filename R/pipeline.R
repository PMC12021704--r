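#' Run the full analysis pipeline
#'
#' End-to-end seeded run: synthetic cohort generation, synthetic trial and
#' within-trial cost-utility analysis, lifetime two-arm microsimulation
#' under each costing scenario, probabilistic sensitivity analysis, and
#' subgroup summaries. Writes delimited report tables and a
#' machine-readable JSON manifest (inputs, seed, configuration digest,
#' package version) to `out_dir`. A single global seed fans out to fixed
#' per-stage child seeds so partial re-runs reproduce exactly.
#'
#' @param config Path to a YAML configuration file, or a configuration
#'   list as returned by [read_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Global integer seed (overrides the config's seed).
#' @return Invisibly, a list with the in-memory results: `within_trial`,
#'   `lifetime` (one `cea_result` per scenario), `psa`, `subgroups`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = read_config(), out_dir = tempfile("t2dcea_"),
                         seed = NULL) {
  if (is.character(config)) config <- read_config(config)
  seed <- as.integer(seed %||% config$seed %||% 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  digest <- config_digest(config)
  meta <- c(seed = seed, config_digest = digest)

  eq_path <- config$risk_equation_file %||%
    system.file("extdata", "risk_equations_synthetic.yaml", package = "t2dcea")
  if (!file.exists(eq_path)) {
    stop("risk-equation file not found: ", eq_path)
  }
  equations <- read_risk_equations(eq_path)

  spec <- cohort_spec_from_config(config$cohort %||% list())
  spec$seed <- child_seed(seed, "population")
  profile <- do.call(effect_profile, config$effects %||% list())
  catalogue <- default_catalogue()
  for (nmv in names(config$catalogue %||% list())) {
    v <- config$catalogue[[nmv]]
    catalogue[[nmv]] <- if (is.list(v)) unlist(v) else v
  }
  drift <- unlist(config$drift %||% as.list(default_drift()))
  n_years <- config$n_years %||% 45

  # stage 1: cohort
  population <- tryCatch(generate_population(spec),
                         error = function(e) stop("cohort stage: ",
                                                  conditionMessage(e)))
  write_cohort(population, file.path(out_dir, "population.tsv"), seed = seed)

  # stage 2: synthetic trial + within-trial CEA
  trial <- generate_trial(spec, profile,
                          attrition_rate = config$attrition %||% 0.31,
                          seed = seed)
  write_cohort(trial, file.path(out_dir, "trial.tsv"), seed = seed)
  costs <- cost_scenarios()
  wt <- tryCatch(
    within_trial_cea(trial,
                     dew_cost = costs$dew_cost[1],
                     de_cost = costs$de_cost[costs$scenario == "mixed"],
                     n_boot = config$n_boot %||% 5000, seed = seed),
    error = function(e) stop("within-trial stage: ", conditionMessage(e)))
  write_table_with_header(summary(wt), file.path(out_dir, "within_trial.tsv"),
                          meta)
  write_table_with_header(wt$ceac, file.path(out_dir, "within_trial_ceac.tsv"),
                          meta)

  # stage 3: lifetime microsimulation per costing scenario
  lifetime <- lapply(seq_len(nrow(costs)), function(i) {
    tryCatch(
      lifetime_cea(population, equations, profile, catalogue,
                   dew_cost = costs$dew_cost[i], de_cost = costs$de_cost[i],
                   n_years = n_years, drift = drift, seed = seed,
                   label = costs$scenario[i]),
      error = function(e) stop("lifetime stage (", costs$scenario[i], "): ",
                               conditionMessage(e)))
  })
  names(lifetime) <- costs$scenario
  lt_table <- do.call(rbind, lapply(lifetime, summary))
  write_table_with_header(lt_table, file.path(out_dir, "lifetime.tsv"), meta)

  # stage 4: PSA on the base (mixed) scenario
  pspec <- psa_spec(n_samples = config$psa$n_samples %||% 2000, seed = seed)
  psa <- tryCatch(
    run_psa(pspec, population, equations, profile, catalogue,
            dew_cost = costs$dew_cost[1],
            de_cost = costs$de_cost[costs$scenario == "mixed"],
            n_years = n_years, drift = drift),
    error = function(e) stop("PSA stage: ", conditionMessage(e)))
  write_table_with_header(psa$draws, file.path(out_dir, "psa_draws.tsv"), meta)
  write_table_with_header(psa$ceac, file.path(out_dir, "psa_ceac.tsv"), meta)

  # stage 5: subgroups
  subgroups <- lapply(c("diabetes_duration", "bmi_category", "imd_quintile"),
    function(gv) {
      subgroup_run(population, gv, equations = equations, profile = profile,
                   catalogue = catalogue, dew_cost = costs$dew_cost[1],
                   de_cost = costs$de_cost[costs$scenario == "mixed"],
                   n_years = n_years, drift = drift, seed = seed)
    })
  names(subgroups) <- c("diabetes_duration", "bmi_category", "imd_quintile")
  sub_table <- do.call(rbind, lapply(names(subgroups), function(nmv) {
    cbind(grouping = nmv, subgroups[[nmv]])
  }))
  write_table_with_header(sub_table, file.path(out_dir, "subgroups.tsv"), meta)

  manifest <- list(
    package = "t2dcea",
    version = as.character(utils::packageVersion("t2dcea")),
    seed = seed,
    config_digest = digest,
    n_population = nrow(population),
    n_trial = nrow(trial),
    n_years = n_years,
    psa_samples = pspec$n_samples,
    risk_equation_file = eq_path,
    outputs = list.files(out_dir)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(within_trial = wt, lifetime = lifetime, psa = psa,
                 subgroups = subgroups, manifest = manifest,
                 out_dir = out_dir))
}
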