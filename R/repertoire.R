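#' Shannon entropy of a vocal repertoire
#'
#' \eqn{H = -\sum_i p_i \log p_i} over the call types an individual
#' produced, where \eqn{p_i} is the proportion of the repertoire made up by
#' type \eqn{i}. Zero-count types contribute 0 (the \eqn{p \log p \to 0}
#' limit). Natural logarithm by default; `H` is 0 for a single-type
#' repertoire and at most `log(k)` for `k` observed types.
#'
#' @param counts non-negative integer vector of per-type call counts (or a
#'   matrix/data.frame with one row per individual).
#' @param base logarithm base (default `exp(1)`).
#' @return entropy (scalar, or one value per row).
#' @export
repertoire_entropy <- function(counts, base = exp(1)) {
  if (is.matrix(counts) || is.data.frame(counts)) {
    return(apply(as.matrix(counts), 1, repertoire_entropy, base = base))
  }
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total == 0) stop("all counts are zero: entropy undefined")
  p <- counts[counts > 0] / total
  -sum(p * log(p, base = base))
}

#' Per-individual repertoire count table
#'
#' Tabulates calls per individual and call type, dropping individuals with
#' fewer than `min_calls` vocalizations (low totals produce unstable
#' entropy and composition estimates). Rare types can be excluded for the
#' composition model via `drop_types`; the minimum-call filter is applied
#' on the full total before any types are dropped.
#'
#' @param calls data.frame with `individual_id` and `call_type`.
#' @param min_calls minimum vocalizations to retain an individual
#'   (default 30).
#' @param drop_types call types to exclude after filtering (default none;
#'   use `c("frill", "other_tonal")` for the composition model, where these
#'   types are too rare to model reliably).
#' @return data.frame with `individual_id`, one column per retained call
#'   type and `total` (count over retained types). Attribute `"dropped"`
#'   lists excluded individuals.
#' @export
build_repertoire_table <- function(calls, min_calls = 30,
                                   drop_types = NULL) {
  labels <- call_type_labels()
  bad <- setdiff(unique(calls$call_type), labels)
  if (length(bad))
    stop("unknown call type labels: ", paste(bad, collapse = ", "))
  if (!nrow(calls)) {
    warning("empty call table")
    out <- data.frame(individual_id = character(), stringsAsFactors = FALSE)
    for (l in labels) out[[l]] <- integer()
    out$total <- integer()
    attr(out, "dropped") <- character()
    return(out)
  }
  tab <- table(factor(calls$individual_id),
               factor(calls$call_type, levels = labels))
  full_total <- rowSums(tab)
  keep <- full_total >= min_calls
  dropped <- rownames(tab)[!keep]
  if (length(dropped))
    message(length(dropped), " individuals with < ", min_calls,
            " vocalizations excluded")
  tab <- tab[keep, , drop = FALSE]
  if (!is.null(drop_types)) {
    miss <- setdiff(drop_types, labels)
    if (length(miss)) stop("unknown drop types: ", paste(miss, collapse = ", "))
    tab <- tab[, setdiff(labels, drop_types), drop = FALSE]
  }
  out <- data.frame(individual_id = rownames(tab),
                    as.data.frame.matrix(tab),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$total <- rowSums(tab)
  attr(out, "dropped") <- dropped
  out
}

# Posterior sampler for the Dirichlet-multinomial composition model, with
# the per-individual Dirichlet draw integrated out analytically:
#   log P(x_i) = log Gamma(theta) - log Gamma(n_i + theta)
#     + sum_k [log Gamma(x_ik + theta*pi_ik) - log Gamma(theta*pi_ik)]
# up to the multinomial coefficient (constant in the parameters).
# Component-wise adaptive random-walk Metropolis on unconstrained scales:
# alpha via its gamma representation (g_k ~ Gamma(a0_k, 1) on the log
# scale, alpha = g / sum(g), which is exactly the dirichlet(a0) prior),
# theta on the log scale with its exponential(0.2) prior, and B / delta
# with their normal(0, 0.5) priors. Proposal scales adapt towards 44%
# acceptance during warmup and are frozen for the retained draws.
dirmult_mcmc <- function(x, X, female, a0, config) {
  I <- nrow(x); K <- ncol(x); J <- ncol(X)
  n <- rowSums(x)
  const_n <- function(theta) sum(lgamma(theta) - lgamma(n + theta))
  loglik <- function(w, B, delta, lt) {
    if (lt > 50) return(-Inf)
    g <- exp(w - max(w))
    alpha <- g / sum(g)
    theta <- exp(lt)
    lp <- matrix(log(alpha), I, K, byrow = TRUE) + X %*% t(B) +
      outer(female, delta)
    lp <- lp - apply(lp, 1, max)
    s <- exp(lp)
    pi <- s / rowSums(s)
    ll <- const_n(theta) + sum(lgamma(x + theta * pi) - lgamma(theta * pi))
    if (!is.finite(ll)) return(-Inf)
    ll
  }
  logprior <- function(w, B, delta, lt) {
    # log-gamma(a0) density for w (unnormalised) gives alpha ~ dirichlet(a0)
    sum(a0 * w - exp(w)) - 2 * sum(B^2) - 2 * sum(delta^2) +
      lt - 0.2 * exp(lt)
  }
  n_par <- K + K * J + K + 1
  run_chain <- function(chain) {
    set.seed((config$seed + chain - 1L) %% .Machine$integer.max)
    w <- log(colSums(x) + 0.5) - log(sum(x))
    B <- matrix(0, K, J)
    delta <- rep(0, K)
    lt <- log(5)
    scales <- rep(0.2, n_par)
    acc <- rep(0, n_par)
    post <- loglik(w, B, delta, lt) + logprior(w, B, delta, lt)
    n_iter <- config$warmup + config$samples
    draws <- matrix(NA_real_, config$samples, K + K * J + K + 1)
    pi_sum <- matrix(0, I, K)
    get_par <- function(p) {
      if (p <= K) w[p]
      else if (p <= K + K * J) B[p - K]
      else if (p <= 2 * K + K * J) delta[p - K - K * J]
      else lt
    }
    set_par <- function(p, v) {
      if (p <= K) w[p] <<- v
      else if (p <= K + K * J) B[p - K] <<- v
      else if (p <= 2 * K + K * J) delta[p - K - K * J] <<- v
      else lt <<- v
    }
    for (it in seq_len(n_iter)) {
      for (p in seq_len(n_par)) {
        old <- get_par(p)
        set_par(p, old + rnorm(1, 0, scales[p]))
        cand <- loglik(w, B, delta, lt) + logprior(w, B, delta, lt)
        if (is.finite(cand) && log(runif(1)) < cand - post) {
          post <- cand
          acc[p] <- acc[p] + 1
        } else {
          set_par(p, old)
        }
      }
      if (it <= config$warmup && it %% 25 == 0) {
        rate <- acc / 25
        scales <- scales * exp((rate - 0.44))
        acc[] <- 0
      }
      if (it > config$warmup) {
        g <- exp(w - max(w)); alpha <- g / sum(g)
        lp <- matrix(log(alpha), I, K, byrow = TRUE) + X %*% t(B) +
          outer(female, delta)
        lp <- lp - apply(lp, 1, max)
        s <- exp(lp)
        pim <- s / rowSums(s)
        pi_sum <- pi_sum + pim
        draws[it - config$warmup, ] <- c(alpha, B, delta, exp(lt))
      }
    }
    colnames(draws) <- c(sprintf("alpha[%d]", 1:K),
                         sprintf("B[%d,%d]", rep(1:K, J), rep(1:J, each = K)),
                         sprintf("delta[%d]", 1:K), "theta")
    list(draws = draws, pi_mean = pi_sum / config$samples)
  }
  chains <- with_seed(config$seed, lapply(seq_len(config$chains), run_chain))
  draw_mats <- lapply(chains, `[[`, "draws")
  list(draws = do.call(rbind, draw_mats),
       rhat = apply_split_rhat(draw_mats),
       pi_mean = Reduce(`+`, lapply(chains, `[[`, "pi_mean")) /
         length(chains),
       report = list(seed = config$seed, chains = config$chains,
                     warmup = config$warmup, samples = config$samples))
}

#' Fit the Dirichlet-multinomial repertoire-composition model
#'
#' Per-individual call-type counts are multinomial with probabilities drawn
#' from a Dirichlet centred on individual-specific expected proportions:
#' \deqn{x_i \sim \mathrm{multinomial}(p_i),\;
#'       p_i \sim \mathrm{dirichlet}(\pi_i \theta),\;
#'       \pi_{ik} = s_{ik}/\textstyle\sum_k s_{ik},\;
#'       s_{ik} = \exp(\log \alpha_k + \beta_k A_i + \delta_k F_i)}
#' where \eqn{\theta} controls how far individuals stray from their
#' expected proportions, \eqn{\alpha} is the baseline composition simplex,
#' \eqn{\beta} are per-type effects of standardised continuous covariates
#' and \eqn{\delta} per-type female offsets. Priors:
#' \eqn{\theta \sim \mathrm{exponential}(0.2)},
#' \eqn{\alpha \sim \mathrm{dirichlet}(5, 0.5, \ldots, 0.5)} (the first,
#' contact, type dominates real repertoires) and
#' \eqn{\beta, \delta \sim \mathrm{normal}(0, 0.5)}.
#'
#' Because the softmax is invariant to adding a constant to all per-type
#' log-effects, \eqn{\beta} and \eqn{\delta} are reported both raw and
#' sum-to-zero-centred (`beta_centered`, `delta_centered`); the centred
#' versions are the identifiable contrasts.
#'
#' @param counts repertoire table from [build_repertoire_table()] (with
#'   `drop_types` applied as desired). Types with zero total count are
#'   dropped with a warning before fitting.
#' @param covariates data.frame with `individual_id`, optional continuous
#'   covariate columns (named in `continuous`) and an optional `sex`
#'   column with levels F/M.
#' @param continuous names of continuous covariate columns (z-scored
#'   internally).
#' @param config a [sampler_config()].
#' @return object of class `dirmult_fit`: `alpha` (posterior table),
#'   `beta`, `beta_centered`, `delta`, `delta_centered`, `theta`, `pi`
#'   (per-individual fitted proportions, posterior means), `draws`,
#'   `types`, `report`.
#' @export
fit_dirichlet_multinomial <- function(counts, covariates = NULL,
                                      continuous = character(),
                                      config = sampler_config()) {
  type_cols <- setdiff(names(counts), c("individual_id", "total"))
  x <- as.matrix(counts[type_cols])
  zero <- colSums(x) == 0
  if (any(zero)) {
    warning("call types with zero total count dropped: ",
            paste(type_cols[zero], collapse = ", "))
    x <- x[, !zero, drop = FALSE]
    type_cols <- type_cols[!zero]
  }
  I <- nrow(x); K <- ncol(x)
  if (I < 10) stop("need at least 10 individuals for the composition model")
  female <- rep(0, I)
  X <- matrix(0, I, max(1, length(continuous)))
  J <- length(continuous)
  if (!is.null(covariates)) {
    m <- match(counts$individual_id, covariates$individual_id)
    if (anyNA(m)) stop("covariates missing for some individuals")
    if ("sex" %in% names(covariates)) {
      sx <- covariates$sex[m]
      if (length(unique(sx[sx %in% c("F", "M")])) < 2 && any(sx %in% c("F", "M")))
        stop("sex column is constant")
      female <- as.numeric(sx == "F")
      female[is.na(female)] <- 0
    }
    if (J > 0) {
      X <- as.matrix(as.data.frame(lapply(covariates[m, continuous,
                                                     drop = FALSE],
                                          function(v) as.numeric(scale(v)))))
    }
  }
  if (J == 0) { X <- matrix(0, I, 1); Jfit <- 1 } else Jfit <- J
  a0 <- c(5, rep(0.5, K - 1))
  fit <- dirmult_mcmc(x, X, female, a0, config)
  cn <- function(nm) match(nm, colnames(fit$draws))
  alpha_d <- fit$draws[, cn(sprintf("alpha[%d]", seq_len(K))), drop = FALSE]
  colnames(alpha_d) <- type_cols
  theta_d <- fit$draws[, "theta", drop = FALSE]
  delta_d <- fit$draws[, cn(sprintf("delta[%d]", seq_len(K))), drop = FALSE]
  colnames(delta_d) <- type_cols
  beta_list <- lapply(seq_len(J), function(j) {
    d <- fit$draws[, cn(sprintf("B[%d,%d]", seq_len(K), j)), drop = FALSE]
    colnames(d) <- type_cols
    d
  })
  names(beta_list) <- continuous
  center <- function(d) d - rowMeans(d)
  pi_mean <- fit$pi_mean
  dimnames(pi_mean) <- list(counts$individual_id, type_cols)
  hyper_rhat <- fit$rhat[c(sprintf("alpha[%d]", seq_len(K)), "theta")]
  rhat_gate(hyper_rhat, config$rhat_limit, "dirichlet-multinomial model")
  structure(list(
    alpha = posterior_summary(alpha_d),
    beta = lapply(beta_list, posterior_summary),
    beta_centered = lapply(beta_list, function(d) posterior_summary(center(d))),
    delta = posterior_summary(delta_d),
    delta_centered = posterior_summary(center(delta_d)),
    theta = posterior_summary(theta_d, unit_ids = "theta"),
    pi = pi_mean,
    draws = list(alpha = alpha_d, beta = beta_list, delta = delta_d,
                 theta = theta_d[, 1]),
    types = type_cols,
    sex_modelled = any(female > 0),
    report = c(fit$report,
               list(rhat_min = suppressWarnings(min(hyper_rhat,
                                                    na.rm = TRUE)),
                    rhat_max = suppressWarnings(max(hyper_rhat,
                                                    na.rm = TRUE)),
                    model = "dirichlet_multinomial",
                    n_individuals = I, n_types = K))),
    class = "dirmult_fit")
}

#' @export
print.dirmult_fit <- function(x, ...) {
  cat(sprintf("<dirmult_fit: %d individuals, %d call types | Rhat max %.3f>\n",
              x$report$n_individuals, x$report$n_types, x$report$rhat_max))
  print(x$alpha, digits = 3)
  invisible(x)
}

#' Sex contrast on repertoire composition
#'
#' Posterior of the female-minus-male difference in expected call-type
#' proportions at the covariate mean: per draw, the female composition is
#' `softmax(log alpha + delta)` and the male composition `alpha`; the
#' contrast is their difference per type. Contrasts sum to zero across
#' types (both compositions are simplexes).
#'
#' @param fit a [fit_dirichlet_multinomial()] result fitted with a `sex`
#'   covariate.
#' @return posterior-estimate data.frame, one row per call type.
#' @export
sex_contrast <- function(fit) {
  if (!inherits(fit, "dirmult_fit")) stop("fit must be a dirmult_fit")
  if (!isTRUE(fit$sex_modelled))
    stop("model was fitted without sex variation")
  la <- log(fit$draws$alpha)
  lf <- la + fit$draws$delta
  piF <- exp(lf) / rowSums(exp(lf))
  piM <- exp(la) / rowSums(exp(la))
  contrast <- piF - piM
  colnames(contrast) <- fit$types
  posterior_summary(contrast)
}
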