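#' @useDynLib vocnet, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

dyadic_model_code <- "
model {
  for (k in 1:N) {
    y[k] ~ dnorm(a_dyad[dyad[k]] + a_rec[r1[k]] + a_rec[r2[k]], tau)
  }
  for (d in 1:D) { a_dyad[d] ~ dnorm(abar, tau_dyad) }
  for (r in 1:R) { a_rec[r] ~ dnorm(0, tau_rec) }
  abar ~ dnorm(0, 4)            # normal(0, 0.5)
  # T(0.001,) is a numerical floor (~0.05% prior mass) guarding against
  # degenerate zero-variance data
  sigma ~ dexp(2) T(0.001,)
  sigma_dyad ~ dexp(2) T(0.001,)
  sigma_rec ~ dexp(2) T(0.001,)
  tau <- pow(sigma, -2)
  tau_dyad <- pow(sigma_dyad, -2)
  tau_rec <- pow(sigma_rec, -2)
}"

within_model_code <- "
model {
  for (k in 1:N) {
    y[k] ~ dnorm(a_ind[ind[k]] + a_same_rec * same[k] + a_rec_pair[rp[k]]
                 + a_call[c1[k]] + a_call[c2[k]], tau)
  }
  for (i in 1:I) { a_ind[i] ~ dnorm(abar, tau_ind) }
  for (p in 1:P) { a_rec_pair[p] ~ dnorm(0, tau_rp) }
  for (c in 1:C) { a_call[c] ~ dnorm(0, tau_call) }
  abar ~ dnorm(0, 16)           # normal(0, 0.25)
  a_same_rec ~ dnorm(0, 4)      # normal(0, 0.5)
  sigma ~ dexp(5) T(0.001,)
  sigma_ind ~ dexp(3) T(0.001,)
  sigma_rec_pair ~ dexp(3) T(0.001,)
  sigma_call ~ dexp(3) T(0.001,)
  tau <- pow(sigma, -2)
  tau_ind <- pow(sigma_ind, -2)
  tau_rp <- pow(sigma_rec_pair, -2)
  tau_call <- pow(sigma_call, -2)
}"

standardize_guard <- function(y, standardize) {
  if (!standardize) return(list(y = y, center = 0, scale = 1))
  s <- stats::sd(y)
  if (!is.finite(s) || s < 1e-12) s <- 1
  m <- mean(y)
  list(y = (y - m) / s, center = m, scale = s)
}

check_distances <- function(obs) {
  bad <- which(!is.finite(obs$distance))
  if (length(bad))
    stop("non-finite distances in rows: ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "")
  invisible(obs)
}

rhat_gate <- function(rhat, limit, what) {
  bad <- rhat[!is.na(rhat) & rhat > limit]
  if (length(bad))
    warning(what, ": Rhat above ", limit, " for ",
            paste(names(bad), collapse = ", "),
            " (max ", round(max(bad), 3), "); inspect convergence")
  invisible(rhat)
}

#' Fit the dyadic acoustic-distance model
#'
#' Decomposes between-individual acoustic distances into a per-dyad offset
#' (the dyad's average acoustic distance — the similarity measure carried
#' into later models), per-recording offsets controlling for repeated
#' comparison of recordings, and residual noise:
#' \deqn{y \sim \mathrm{normal}(\mu, \sigma), \quad
#'       \mu = \alpha_{dyad} + \alpha_{rec[i]} + \alpha_{rec[j]}}
#' with \eqn{\alpha_{dyad} \sim \mathrm{normal}(\bar\alpha, \sigma_{dyad})},
#' \eqn{\bar\alpha \sim \mathrm{normal}(0, 0.5)},
#' \eqn{\alpha_{rec} \sim \mathrm{normal}(0, \sigma_{rec})} and
#' \eqn{\sigma, \sigma_{dyad}, \sigma_{rec} \sim \mathrm{exponential}(2)}.
#' Both recordings of a cross-recording pair contribute their offset
#' additively.
#'
#' Distances are z-scored before fitting so the priors are weakly
#' informative on the model scale; the transform is stored and inverted on
#' export, so all reported estimates are on the input scale. A warning is
#' raised when any hyperparameter's split-Rhat exceeds the configured gate.
#'
#' @param observations distance table from
#'   [between_individual_distances()] (or [simulate_dyadic_distances()]).
#' @param config a [sampler_config()].
#' @param standardize z-score distances before fitting (default TRUE;
#'   skipped automatically when the distances are constant).
#' @return object of class `dyadic_fit`: list with `dyads` (per-dyad
#'   posterior-estimate table on the input scale), `hyper` (hyperparameter
#'   table, input scale), `draws` (per-dyad posterior draw matrix, input
#'   scale), `scale`, and `report`.
#' @export
fit_dyadic_model <- function(observations, config = sampler_config(),
                             standardize = TRUE) {
  check_distances(observations)
  dyad <- factor(observations$dyad_id)
  if (nlevels(dyad) < 2) stop("need at least 2 dyads")
  recs <- factor(c(observations$rec_i, observations$rec_j))
  r1 <- as.integer(recs[seq_len(nrow(observations))])
  r2 <- as.integer(recs[nrow(observations) + seq_len(nrow(observations))])
  z <- standardize_guard(observations$distance, standardize)
  fit <- run_jags(dyadic_model_code,
                  data = list(y = z$y, N = nrow(observations),
                              D = nlevels(dyad), R = nlevels(recs),
                              dyad = as.integer(dyad), r1 = r1, r2 = r2),
                  monitor = c("a_dyad", "abar", "sigma", "sigma_dyad",
                              "sigma_rec"),
                  config = config)
  hy_names <- c("abar", "sigma", "sigma_dyad", "sigma_rec")
  rhat_gate(fit$rhat[hy_names], config$rhat_limit, "dyadic model")
  a_cols <- match(sprintf("a_dyad[%d]", seq_len(nlevels(dyad))),
                  colnames(fit$draws))
  # back-transform: location parameters recover the centre, scales do not
  dyad_draws <- z$center + z$scale * fit$draws[, a_cols, drop = FALSE]
  colnames(dyad_draws) <- levels(dyad)
  hyper_draws <- fit$draws[, hy_names]
  hyper_draws[, "abar"] <- z$center + z$scale * hyper_draws[, "abar"]
  hyper_draws[, c("sigma", "sigma_dyad", "sigma_rec")] <-
    z$scale * hyper_draws[, c("sigma", "sigma_dyad", "sigma_rec")]
  structure(list(
    dyads = posterior_summary(dyad_draws,
                              rhat = stats::setNames(fit$rhat[a_cols],
                                                     levels(dyad))),
    hyper = posterior_summary(hyper_draws, unit_ids = hy_names,
                              rhat = fit$rhat[hy_names]),
    draws = dyad_draws,
    hyper_draws = hyper_draws,
    scale = z[c("center", "scale")],
    report = c(fit$report, list(model = "dyadic", n_obs = nrow(observations),
                                n_dyads = nlevels(dyad),
                                n_recordings = nlevels(recs)))),
    class = "dyadic_fit")
}

#' Fit the within-individual diversity model
#'
#' Decomposes within-individual acoustic distances into a per-individual
#' offset (the individual's average distance between its own calls — the
#' contact-call diversity measure), a same-recording offset, recording-pair
#' offsets and per-call offsets:
#' \deqn{\mu = \alpha_{ind} + \alpha_{same\,rec} + \alpha_{rec\,pair}
#'       + \alpha_{call_i} + \alpha_{call_j}}
#' with \eqn{\alpha_{ind} \sim \mathrm{normal}(\bar\alpha, \sigma_{ind})},
#' \eqn{\bar\alpha \sim \mathrm{normal}(0, 0.25)},
#' \eqn{\sigma \sim \mathrm{exponential}(5)} and the group-level SDs
#' \eqn{\sigma_{ind}, \sigma_{rec\,pair}, \sigma_{call} \sim
#' \mathrm{exponential}(3)}. The same-recording offset is a single scalar
#' applied when both calls come from one recording (prior normal(0, 0.5)).
#'
#' @param observations distance table from
#'   [within_individual_distances()] (or [simulate_within_distances()]).
#' @inheritParams fit_dyadic_model
#' @return object of class `within_fit`: `individuals` (per-individual
#'   diversity estimates, input scale), `hyper`, `draws`, `scale`,
#'   `report`.
#' @export
fit_within_model <- function(observations, config = sampler_config(),
                             standardize = TRUE) {
  check_distances(observations)
  ind <- factor(observations$id_i)
  if (nlevels(ind) < 2) stop("need at least 2 individuals")
  calls <- factor(c(observations$call_i, observations$call_j))
  c1 <- as.integer(calls[seq_len(nrow(observations))])
  c2 <- as.integer(calls[nrow(observations) + seq_len(nrow(observations))])
  rp <- factor(paste(pmin(observations$rec_i, observations$rec_j),
                     pmax(observations$rec_i, observations$rec_j)))
  z <- standardize_guard(observations$distance, standardize)
  fit <- run_jags(within_model_code,
                  data = list(y = z$y, N = nrow(observations),
                              I = nlevels(ind), P = nlevels(rp),
                              C = nlevels(calls),
                              ind = as.integer(ind),
                              same = as.numeric(observations$same_recording),
                              rp = as.integer(rp), c1 = c1, c2 = c2),
                  monitor = c("a_ind", "abar", "a_same_rec", "sigma",
                              "sigma_ind", "sigma_rec_pair", "sigma_call"),
                  config = config)
  hy_names <- c("abar", "a_same_rec", "sigma", "sigma_ind", "sigma_rec_pair",
                "sigma_call")
  rhat_gate(fit$rhat[hy_names], config$rhat_limit, "within-individual model")
  a_cols <- match(sprintf("a_ind[%d]", seq_len(nlevels(ind))),
                  colnames(fit$draws))
  ind_draws <- z$center + z$scale * fit$draws[, a_cols, drop = FALSE]
  colnames(ind_draws) <- levels(ind)
  hyper_draws <- fit$draws[, hy_names]
  hyper_draws[, "abar"] <- z$center + z$scale * hyper_draws[, "abar"]
  sc <- setdiff(hy_names, "abar")
  hyper_draws[, sc] <- z$scale * hyper_draws[, sc]
  structure(list(
    individuals = posterior_summary(ind_draws,
                                    rhat = stats::setNames(fit$rhat[a_cols],
                                                           levels(ind))),
    hyper = posterior_summary(hyper_draws, unit_ids = hy_names,
                              rhat = fit$rhat[hy_names]),
    draws = ind_draws,
    hyper_draws = hyper_draws,
    scale = z[c("center", "scale")],
    report = c(fit$report, list(model = "within",
                                n_obs = nrow(observations),
                                n_individuals = nlevels(ind),
                                n_calls = nlevels(calls)))),
    class = "within_fit")
}

#' Export posterior summaries from a distance-model fit
#'
#' One row per dyad or individual with the posterior mean, SD and 89%
#' equal-tailed interval on the input scale — the mean and SD are the
#' measurement-error inputs to the second-stage effect models.
#'
#' @param fit a `dyadic_fit` or `within_fit`.
#' @return data.frame with columns `unit_id`, `unit_type`, `mean`, `sd`,
#'   `pi89_low`, `pi89_high`, `rhat`.
#' @export
export_summaries <- function(fit) {
  if (inherits(fit, "dyadic_fit")) {
    out <- fit$dyads
    out$unit_type <- "dyad"
  } else if (inherits(fit, "within_fit")) {
    out <- fit$individuals
    out$unit_type <- "individual"
  } else stop("fit must be a dyadic_fit or within_fit")
  out[c("unit_id", "unit_type", "mean", "sd", "pi89_low", "pi89_high",
        "rhat")]
}

#' @export
print.dyadic_fit <- function(x, ...) {
  cat(sprintf("<dyadic_fit: %d dyads, %d obs | Rhat %.3f-%.3f>\n",
              x$report$n_dyads, x$report$n_obs, x$report$rhat_min,
              x$report$rhat_max))
  print(x$hyper, digits = 3)
  invisible(x)
}

#' @export
print.within_fit <- function(x, ...) {
  cat(sprintf("<within_fit: %d individuals, %d obs | Rhat %.3f-%.3f>\n",
              x$report$n_individuals, x$report$n_obs, x$report$rhat_min,
              x$report$rhat_max))
  print(x$hyper, digits = 3)
  invisible(x)
}

#' Draw from the priors of the distance models
#'
#' Samples the hyperparameter priors exactly as specified in the model
#' code, for prior-predictive checking (e.g. the exponential(2) scale
#' priors of the dyadic model have prior mean 0.5).
#'
#' @param model `"dyadic"` or `"within"`.
#' @param n number of draws.
#' @param seed integer seed.
#' @return data.frame of prior draws.
#' @export
prior_draws <- function(model = c("dyadic", "within"), n = 1000, seed = 1L) {
  model <- match.arg(model)
  with_seed(seed, {
    if (model == "dyadic") {
      data.frame(abar = stats::rnorm(n, 0, 0.5),
                 sigma = stats::rexp(n, 2),
                 sigma_dyad = stats::rexp(n, 2),
                 sigma_rec = stats::rexp(n, 2))
    } else {
      data.frame(abar = stats::rnorm(n, 0, 0.25),
                 a_same_rec = stats::rnorm(n, 0, 0.5),
                 sigma = stats::rexp(n, 5),
                 sigma_ind = stats::rexp(n, 3),
                 sigma_rec_pair = stats::rexp(n, 3),
                 sigma_call = stats::rexp(n, 3))
    }
  })
}
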