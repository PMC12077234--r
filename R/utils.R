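#' Sampler configuration for the Bayesian models
#'
#' All model-fitting functions in the package take a `sampler_config` list.
#' Defaults follow common practice for these conditionally conjugate
#' hierarchies: 4 chains, 1000 adaptation/warmup iterations and 1000
#' retained iterations per chain. Every chain gets its own deterministic
#' RNG seed derived from `seed`, so fits are exactly reproducible.
#'
#' @param chains number of MCMC chains.
#' @param warmup iterations discarded as adaptation + burn-in per chain.
#' @param samples retained iterations per chain.
#' @param seed integer seed; chain seeds are `seed + 0:(chains-1)`.
#' @param rhat_limit convergence gate for hyperparameters; a warning is
#'   raised when any monitored hyperparameter exceeds it.
#' @return a list with class `"sampler_config"`.
#' @export
sampler_config <- function(chains = 4L, warmup = 1000L, samples = 1000L,
                           seed = 1L, rhat_limit = 1.01) {
  stopifnot(chains >= 1, warmup >= 0, samples >= 2, is.finite(seed))
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 samples = as.integer(samples), seed = as.integer(seed),
                 rhat_limit = rhat_limit),
            class = "sampler_config")
}

jags_inits <- function(config, inits = NULL) {
  lapply(seq_len(config$chains), function(k) {
    c(list(.RNG.name = "base::Mersenne-Twister",
           .RNG.seed = (config$seed + k - 1L) %% .Machine$integer.max),
      inits)
  })
}

#' Run a JAGS model and return draws plus a fit report
#'
#' Thin wrapper used by every model in the package: compiles the model,
#' runs adaptation/burn-in, samples the monitored nodes and computes
#' split-Rhat for each monitored scalar.
#'
#' @param model_string JAGS model code.
#' @param data named list of data.
#' @param monitor character vector of node names to monitor.
#' @param config a [sampler_config()].
#' @return list with `draws` (matrix, iterations x parameters, chains
#'   stacked), `mcmc` (the coda `mcmc.list`), `rhat` (named vector) and
#'   `report` (list with rhat range, seed, dimensions).
#' @keywords internal
run_jags <- function(model_string, data, monitor, config = sampler_config(),
                     inits = NULL) {
  # a short adaptation is enough for the slice/conjugate samplers these
  # models use; warmup below provides the actual burn-in
  jm <- rjags::jags.model(textConnection(model_string), data = data,
                          inits = jags_inits(config, inits),
                          n.chains = config$chains, quiet = TRUE,
                          n.adapt = max(100L, min(300L, config$warmup)))
  if (config$warmup > 0) update(jm, config$warmup, progress.bar = "none")
  mc <- rjags::coda.samples(jm, monitor, n.iter = config$samples,
                            progress.bar = "none")
  draws <- do.call(rbind, lapply(mc, as.matrix))
  rhat <- apply_split_rhat(mc)
  report <- list(seed = config$seed, chains = config$chains,
                 warmup = config$warmup, samples = config$samples,
                 rhat_min = suppressWarnings(min(rhat, na.rm = TRUE)),
                 rhat_max = suppressWarnings(max(rhat, na.rm = TRUE)))
  list(draws = draws, mcmc = mc, rhat = rhat, report = report)
}

#' Split-Rhat convergence diagnostic
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, the standard guard against within-chain trends. Returns `NA` for
#' parameters with (numerically) zero variance.
#'
#' @param x a coda `mcmc.list` or a list of draw matrices (iteration x
#'   parameter) of equal dimensions.
#' @return named numeric vector, one entry per parameter.
#' @export
apply_split_rhat <- function(x) {
  mats <- lapply(x, as.matrix)
  p <- ncol(mats[[1]])
  out <- vapply(seq_len(p), function(j) {
    ch <- lapply(mats, function(m) m[, j])
    split_rhat_one(ch)
  }, numeric(1))
  names(out) <- colnames(mats[[1]])
  out
}

split_rhat_one <- function(chains) {
  half <- function(v) {
    n <- length(v) %/% 2L
    list(v[seq_len(n)], v[seq_len(n) + (length(v) - n)])
  }
  sub <- unlist(lapply(chains, half), recursive = FALSE)
  m <- length(sub)
  n <- length(sub[[1]])
  means <- vapply(sub, mean, numeric(1))
  vars <- vapply(sub, stats::var, numeric(1))
  w <- mean(vars)
  b <- n * stats::var(means)
  if (!is.finite(w) || w <= 1e-300) return(NA_real_)
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Equal-tailed 89% posterior interval
#'
#' @param x numeric vector of posterior draws.
#' @param prob interval mass (default 0.89, the interval reported
#'   throughout the package).
#' @return numeric vector `c(low, high)`.
#' @export
pi89 <- function(x, prob = 0.89) {
  a <- (1 - prob) / 2
  unname(stats::quantile(x, c(a, 1 - a), names = FALSE))
}

#' Summarise posterior draws into an estimate table
#'
#' @param draws matrix of draws (iterations x parameters).
#' @param unit_ids labels for the columns (defaults to column names).
#' @param rhat optional named vector of Rhat values to attach.
#' @return data.frame with columns `unit_id`, `mean`, `sd`, `pi89_low`,
#'   `pi89_high` and `rhat`.
#' @export
posterior_summary <- function(draws, unit_ids = colnames(draws), rhat = NULL) {
  draws <- as.matrix(draws)
  qs <- apply(draws, 2, pi89)
  out <- data.frame(
    unit_id = unit_ids,
    mean = colMeans(draws),
    sd = apply(draws, 2, stats::sd),
    pi89_low = qs[1, ],
    pi89_high = qs[2, ],
    rhat = if (is.null(rhat)) NA_real_ else unname(rhat[colnames(draws)]),
    stringsAsFactors = FALSE, row.names = NULL)
  out
}

# deterministic md5 hash of an R object via canonical JSON (base R only)
config_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f), add = TRUE)
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}

# seed scoping helper: run expr under a seed without disturbing the caller
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
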