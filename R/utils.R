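#' @keywords internal
#' @import stats
#' @importFrom utils write.table read.delim packageVersion
"_PACKAGE"

# Quantile function of a normal truncated to [lower, upper].
# Used for correlation-preserving marginal transforms in the cohort generator.
qtruncnorm <- function(p, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  if (any(sd < 0)) stop("sd must be non-negative")
  if (any(lower >= upper)) stop("impossible truncation bounds: lower >= upper")
  if (all(sd == 0)) return(rep_len(mean, length(p)))
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  if (any(phi - plo < 1e-12)) {
    stop("impossible truncation bounds: no probability mass in [lower, upper]")
  }
  qnorm(plo + p * (phi - plo), mean, sd)
}

# Mean and sd of a normal(mu, sigma) truncated to [lower, upper]
# (standard closed forms).
truncnorm_moments <- function(mu, sigma, lower = -Inf, upper = Inf) {
  a <- (lower - mu) / sigma
  b <- (upper - mu) / sigma
  z <- pnorm(b) - pnorm(a)
  da <- dnorm(a); db <- dnorm(b)
  ada <- ifelse(is.finite(a), a * da, 0)
  bdb <- ifelse(is.finite(b), b * db, 0)
  m <- mu + sigma * (da - db) / z
  v <- sigma^2 * (1 + (ada - bdb) / z - ((da - db) / z)^2)
  c(mean = m, sd = sqrt(pmax(v, 0)))
}

# Underlying (mu, sigma) such that the truncated normal on [lower, upper]
# has the requested mean and sd: the marginal moments a user specifies are
# then recovered by the generated sample despite eligibility truncation.
truncnorm_params <- function(mean, sd, lower = -Inf, upper = Inf) {
  if (mean < lower || mean > upper) {
    stop("impossible truncation bounds: target mean outside [lower, upper]")
  }
  if (sd == 0 || (!is.finite(lower) && !is.finite(upper))) {
    return(c(mu = mean, sigma = sd))
  }
  obj <- function(par) {
    mo <- truncnorm_moments(par[1], exp(par[2]), lower, upper)
    (mo[["mean"]] - mean)^2 + (mo[["sd"]] - sd)^2
  }
  fit <- optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
  mo <- truncnorm_moments(fit$par[1], exp(fit$par[2]), lower, upper)
  if (abs(mo[["mean"]] - mean) > 0.02 * sd || abs(mo[["sd"]] - sd) > 0.05 * sd) {
    stop("impossible truncation bounds: cannot match mean ", mean, " sd ", sd,
         " on [", lower, ", ", upper, "]")
  }
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# Fan a single global seed out to per-stage child seeds so that partial
# re-runs of a pipeline stage reproduce exactly. Offsets are fixed and
# documented; result kept below 2^31 - 1.
child_seed <- function(seed, stage) {
  stages <- c(
    population = 11L, trial = 23L, trajectories = 37L, events = 53L,
    calibration = 71L, psa = 97L, bootstrap = 113L, pipeline = 131L
  )
  off <- stages[[stage]]
  if (is.null(off)) stop("unknown seed stage: ", stage)
  as.integer((as.numeric(seed) * 151 + off) %% 2147483629)
}

# Evaluate code under a local RNG state so library internals never disturb
# the caller's random stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

#' Read a model configuration file
#'
#' Configuration files are plain-text YAML key-value documents. The package
#' ships a complete default configuration covering the cohort specification,
#' intervention-effect profile, risk-factor drifts, risk-equation file,
#' cost/utility catalogue, costing scenarios and PSA settings.
#'
#' @param path Path to a YAML configuration file. The default reads the
#'   configuration shipped with the package.
#' @return A named list.
#' @export
read_config <- function(path = system.file("extdata", "default_config.yaml",
                                           package = "t2dcea")) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  yaml::read_yaml(path)
}

# Stable digest of a configuration for run manifests: configs are small, so
# a simple FNV-1a over the serialized text is adequate and dependency-free.
config_digest <- function(config) {
  txt <- yaml::as.yaml(config)
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

write_table_with_header <- function(df, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in names(meta)) writeLines(sprintf("# %s: %s", m, meta[[m]]), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}
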