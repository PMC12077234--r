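#' Directed acyclic graphs for effect adjustment
#'
#' A DAG is stored as a node vector plus an edge data.frame
#' (`from`, `to`). Construction validates acyclicity.
#'
#' @param nodes character vector of variable names.
#' @param edges data.frame with columns `from`, `to`.
#' @return object of class `effect_dag`.
#' @export
effect_dag <- function(nodes, edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges)) {
    stopifnot(all(c("from", "to") %in% names(edges)))
    nodes <- unique(c(nodes, edges$from, edges$to))
  }
  dag <- structure(list(nodes = nodes, edges = edges), class = "effect_dag")
  if (!dag_is_acyclic(dag)) stop("graph is cyclic: not a DAG")
  dag
}

dag_parents <- function(dag, node) {
  unique(dag$edges$from[dag$edges$to == node])
}

dag_children <- function(dag, node) {
  unique(dag$edges$to[dag$edges$from == node])
}

dag_reachable <- function(dag, from, direction = c("down", "up")) {
  direction <- match.arg(direction)
  step <- if (direction == "down") dag_children else dag_parents
  seen <- character()
  frontier <- from
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(lapply(frontier, step, dag = dag))), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

dag_is_acyclic <- function(dag) {
  for (v in dag$nodes) {
    if (v %in% dag_reachable(dag, v, "down")) return(FALSE)
  }
  TRUE
}

#' Read DAGs from a JSON file
#'
#' The package ships its default causal diagrams (for call similarity,
#' call diversity and information content) in
#' `inst/extdata/dags.json`; `default_dags()` loads them.
#'
#' @param path JSON file: an object mapping DAG names to
#'   `{nodes: [...], edges: [{from, to}, ...]}`.
#' @return named list of [effect_dag()] objects.
#' @export
dags_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(d) {
    edges <- as.data.frame(d$edges, stringsAsFactors = FALSE)
    effect_dag(d$nodes, edges)
  })
}

#' @rdname dags_from_json
#' @export
default_dags <- function() {
  dags_from_json(system.file("extdata", "dags.json", package = "vocnet"))
}

#' Back-door adjustment set for a total or direct effect
#'
#' For the *total* effect of `exposure` on `outcome` the adjustment set
#' closes all back-door paths by conditioning on the exposure's parents
#' (always a valid back-door set when all confounders are observed, as in
#' these diagrams). For the *direct* effect the set additionally contains
#' every mediator — nodes lying on a directed path from exposure to
#' outcome — so the indirect paths are blocked too.
#'
#' @param exposure,outcome variable names present in `dag`.
#' @param dag an [effect_dag()].
#' @param kind `"total"` or `"direct"`.
#' @return character vector of adjustment variables (possibly empty).
#' @export
build_adjustment <- function(exposure, outcome, dag,
                             kind = c("total", "direct")) {
  kind <- match.arg(kind)
  if (!exposure %in% dag$nodes) stop("exposure not in DAG: ", exposure)
  if (!outcome %in% dag$nodes) stop("outcome not in DAG: ", outcome)
  adj <- setdiff(dag_parents(dag, exposure), outcome)
  if (kind == "direct") {
    mediators <- intersect(dag_reachable(dag, exposure, "down"),
                           dag_reachable(dag, outcome, "up"))
    adj <- union(adj, setdiff(mediators, c(exposure, outcome)))
  }
  sort(adj)
}

#' Model formula for an effect specification
#'
#' @param outcome,exposure variable names.
#' @param adjustment character vector of adjustment variables.
#' @return a `formula` `outcome ~ exposure + adjustment...`.
#' @export
effect_formula <- function(outcome, exposure, adjustment = character()) {
  stats::as.formula(paste(outcome, "~",
                          paste(c(exposure, adjustment), collapse = " + ")),
                    env = globalenv())
}

#' Registry of effect models
#'
#' The shipped registry resolves each planned model into an outcome, an
#' exposure, the adjustment covariates and the causal-effect kind. Its
#' single-letter abbreviations collide in the source material (e.g. `S`
#' is both similarity and sex), so every entry stores full variable names
#' and a note documenting the reading.
#'
#' @param path optional JSON path; defaults to the shipped registry.
#' @return data.frame with columns `outcome`, `exposure`, `kind`,
#'   `adjustment` (comma-separated), `note`.
#' @export
model_registry <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "model_registry.json", package = "vocnet")
  as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE),
                stringsAsFactors = FALSE)
}

me_individual_code <- "
model {
  for (i in 1:N) {
    obs[i] ~ dnorm(latent[i], obs_tau[i])
    latent[i] ~ dnorm(mu[i], tau)
    mu[i] <- a + inprod(X[i, ], b[])
  }
  a ~ dnorm(a_mean, a_tau)
  for (j in 1:J) { b[j] ~ dnorm(0, 4) }   # normal(0, 0.5)
  sigma ~ dexp(2) T(0.001,)
  tau <- pow(sigma, -2)
}"

me_dyadic_code <- "
model {
  for (i in 1:N) {
    obs[i] ~ dnorm(latent[i], obs_tau[i])
    latent[i] ~ dnorm(mu[i], tau)
    mu[i] <- a + inprod(X[i, ], b[]) + u[m1[i]] + u[m2[i]]
  }
  for (k in 1:M) { u[k] ~ dnorm(0, tau_id) }
  a ~ dnorm(a_mean, a_tau)
  for (j in 1:J) { b[j] ~ dnorm(0, 4) }
  sigma ~ dexp(2) T(0.001,)
  sigma_id ~ dexp(2) T(0.001,)
  tau <- pow(sigma, -2)
  tau_id <- pow(sigma_id, -2)
}"

info_sqrt_code <- "
model {
  for (i in 1:N) {
    y[i] ~ dnorm(mu[i], tau)
    mu[i] <- a + inprod(X[ind[i], ], b[]) + u[ind[i]]
  }
  for (k in 1:M) { u[k] ~ dnorm(0, tau_ind) }
  a ~ dnorm(0, 1)
  for (j in 1:J) { b[j] ~ dnorm(0, 4) }
  sigma ~ dexp(2) T(0.001,)
  sigma_ind ~ dexp(2) T(0.001,)
  tau <- pow(sigma, -2)
  tau_ind <- pow(sigma_ind, -2)
}"

info_pois_code <- "
model {
  for (i in 1:N) {
    y[i] ~ dpois(lambda[i])
    log(lambda[i]) <- a + inprod(X[ind[i], ], b[]) + u[ind[i]]
  }
  for (k in 1:M) { u[k] ~ dnorm(0, tau_ind) }
  a ~ dnorm(0, 1)
  for (j in 1:J) { b[j] ~ dnorm(0, 4) }
  sigma_ind ~ dexp(2) T(0.001,)
  tau_ind <- pow(sigma_ind, -2)
}"

build_design <- function(predictors, vars, id_col) {
  miss <- setdiff(vars, names(predictors))
  if (length(miss))
    stop("predictor table lacks variables: ", paste(miss, collapse = ", "))
  for (v in vars) {
    if (all(is.na(predictors[[v]])))
      stop("predictor entirely missing: ", v)
  }
  keep <- stats::complete.cases(predictors[vars])
  predictors <- predictors[keep, , drop = FALSE]
  X <- as.matrix(as.data.frame(lapply(predictors[vars], function(v) {
    v <- as.numeric(v)
    # standardize continuous predictors; leave binaries as-is
    if (length(unique(v)) > 2) {
      s <- stats::sd(v)
      if (s > 0) v <- (v - mean(v)) / s
    }
    v
  })))
  colnames(X) <- vars
  list(X = X, ids = predictors[[id_col]], keep = keep)
}

slope_summary <- function(fit, vars, extra = character(), y_scale = NULL) {
  b_cols <- if (length(vars) == 1 && "b" %in% colnames(fit$draws))
    match("b", colnames(fit$draws))
  else match(sprintf("b[%d]", seq_along(vars)), colnames(fit$draws))
  draws <- fit$draws[, b_cols, drop = FALSE]
  colnames(draws) <- vars
  if (!is.null(y_scale)) draws <- draws * y_scale$scale
  rh <- stats::setNames(fit$rhat[b_cols], vars)
  out <- posterior_summary(draws, rhat = rh)
  names(out)[1] <- "term"
  extra_rows <- lapply(extra, function(p) {
    d <- fit$draws[, p, drop = FALSE]
    if (!is.null(y_scale)) {
      d <- if (p == "a") y_scale$center + y_scale$scale * d
      else y_scale$scale * d
    }
    r <- posterior_summary(d, unit_ids = p, rhat = fit$rhat[p])
    names(r)[1] <- "term"
    r
  })
  rbind(out, do.call(rbind, extra_rows))
}

#' Second-stage effect model for individual-level outcomes
#'
#' Regresses a measured outcome (the exported posterior mean and SD of a
#' first-stage quantity such as contact-call diversity or repertoire
#' entropy) on standardised predictors, propagating the measurement
#' uncertainty: the observed mean is normal around a latent true value
#' with the exported SD, and the latent values follow the linear model
#' with residual SD `sigma`. Complete cases on the model's variables are
#' used.
#'
#' @param outcomes data.frame with `unit_id`, `est_mean`, `est_sd`.
#' @param predictors data.frame with `unit_id` (or `id`) plus predictor
#'   columns.
#' @param exposure name of the exposure variable.
#' @param adjustment character vector of adjustment covariates.
#' @param config a [sampler_config()].
#' @param intercept_prior `c(mean, sd)` for the intercept, on the fitting
#'   scale; default `c(0, 0.5)` (use `c(1, 1)` with
#'   `standardize = FALSE` for repertoire-entropy outcomes, whose natural
#'   scale already matches that prior).
#' @param standardize z-score the outcome before fitting so the priors are
#'   weakly informative on the model scale (default TRUE); slopes and
#'   scale parameters are back-transformed to the input scale on export.
#' @return object of class `effect_fit`: `slopes` (posterior table with
#'   one row per predictor plus `sigma`), `draws`, `report`.
#' @export
fit_individual_effect_model <- function(outcomes, predictors, exposure,
                                        adjustment = character(),
                                        config = sampler_config(),
                                        intercept_prior = c(0, 0.5),
                                        standardize = TRUE) {
  id_col <- if ("unit_id" %in% names(predictors)) "unit_id" else "id"
  vars <- c(exposure, adjustment)
  m <- merge(outcomes, predictors, by.x = "unit_id", by.y = id_col)
  des <- build_design(m, vars, "unit_id")
  m <- m[des$keep, , drop = FALSE]
  if (nrow(m) < length(vars) + 2) stop("too few complete cases")
  z <- standardize_guard(m$est_mean, standardize)
  obs_sd <- pmax(m$est_sd, 1e-6) / z$scale
  fit <- run_jags(me_individual_code,
                  data = list(obs = z$y, obs_tau = obs_sd^-2,
                              X = des$X, N = nrow(m), J = ncol(des$X),
                              a_mean = intercept_prior[1],
                              a_tau = intercept_prior[2]^-2),
                  monitor = c("a", "b", "sigma"), config = config)
  rhat_gate(fit$rhat[c("a", "sigma",
                       grep("^b\\[", names(fit$rhat), value = TRUE))],
            config$rhat_limit, "individual effect model")
  structure(list(slopes = slope_summary(fit, vars, extra = c("a", "sigma"),
                                        y_scale = z),
                 draws = fit$draws,
                 y_scale = z[c("center", "scale")],
                 report = c(fit$report,
                            list(model = "individual_effect", n = nrow(m),
                                 exposure = exposure,
                                 adjustment = adjustment))),
            class = "effect_fit")
}

#' Second-stage effect model for dyadic outcomes
#'
#' As [fit_individual_effect_model()], for dyad-level outcomes (e.g. the
#' per-dyad acoustic distance), with multi-membership varying intercepts:
#' each dyad's latent outcome includes the random effects of both member
#' individuals, so non-independence of dyads sharing an individual is
#' absorbed.
#'
#' @param outcomes data.frame with `dyad_id`, `id_i`, `id_j`, `est_mean`,
#'   `est_sd`.
#' @param predictors data.frame with `dyad_id` plus dyadic predictor
#'   columns (edge weights, relatedness, normalised nest distance...).
#' @inheritParams fit_individual_effect_model
#' @return object of class `effect_fit` with an additional `sigma_id` row
#'   in `slopes`.
#' @export
fit_dyadic_effect_model <- function(outcomes, predictors, exposure,
                                    adjustment = character(),
                                    config = sampler_config(),
                                    intercept_prior = c(0, 0.5),
                                    standardize = TRUE) {
  vars <- c(exposure, adjustment)
  m <- merge(outcomes, predictors, by = "dyad_id")
  known <- stats::complete.cases(m[c("id_i", "id_j", "est_mean", "est_sd")])
  if (any(!known)) {
    message(sum(!known), " dyads with unknown members or missing estimates ",
            "dropped")
    m <- m[known, , drop = FALSE]
  }
  des <- build_design(m, vars, "dyad_id")
  m <- m[des$keep, , drop = FALSE]
  if (nrow(m) < length(vars) + 2) stop("too few complete cases")
  members <- factor(c(m$id_i, m$id_j))
  m1 <- as.integer(members[seq_len(nrow(m))])
  m2 <- as.integer(members[nrow(m) + seq_len(nrow(m))])
  z <- standardize_guard(m$est_mean, standardize)
  obs_sd <- pmax(m$est_sd, 1e-6) / z$scale
  fit <- run_jags(me_dyadic_code,
                  data = list(obs = z$y, obs_tau = obs_sd^-2,
                              X = des$X, N = nrow(m), J = ncol(des$X),
                              M = nlevels(members), m1 = m1, m2 = m2,
                              a_mean = intercept_prior[1],
                              a_tau = intercept_prior[2]^-2),
                  monitor = c("a", "b", "sigma", "sigma_id"), config = config)
  rhat_gate(fit$rhat[c("a", "sigma", "sigma_id",
                       grep("^b\\[", names(fit$rhat), value = TRUE))],
            config$rhat_limit, "dyadic effect model")
  structure(list(slopes = slope_summary(fit, vars,
                                        extra = c("a", "sigma", "sigma_id"),
                                        y_scale = z),
                 draws = fit$draws,
                 y_scale = z[c("center", "scale")],
                 report = c(fit$report,
                            list(model = "dyadic_effect", n = nrow(m),
                                 exposure = exposure,
                                 adjustment = adjustment))),
            class = "effect_fit")
}

#' Information-content model on amplitude-modulation peak counts
#'
#' Hierarchical model of per-call peak counts with individual varying
#' intercepts and individual-level predictors. Default likelihood is a
#' normal on square-root-transformed counts (a variance-stabilising choice
#' for low counts); a Poisson log-link alternative is available via
#' `likelihood = "poisson"`. The between-individual SD `sigma_ind` is
#' reported alongside the slopes.
#'
#' @param counts data.frame with `call_id`, `individual_id`, `count`.
#' @param predictors data.frame with `id` plus predictor columns.
#' @param exposure,adjustment predictor names.
#' @param likelihood `"sqrt_normal"` (default) or `"poisson"`.
#' @inheritParams fit_individual_effect_model
#' @return object of class `effect_fit`; `slopes` contains the predictor
#'   slopes, the intercept and `sigma_ind` (plus `sigma` for the normal
#'   likelihood).
#' @export
fit_information_model <- function(counts, predictors, exposure,
                                  adjustment = character(),
                                  likelihood = c("sqrt_normal", "poisson"),
                                  config = sampler_config()) {
  likelihood <- match.arg(likelihood)
  if (any(counts$count < 0)) stop("counts must be non-negative")
  vars <- c(exposure, adjustment)
  id_col <- if ("id" %in% names(predictors)) "id" else "unit_id"
  des <- build_design(predictors, vars, id_col)
  keep_ids <- des$ids
  cc <- counts[counts$individual_id %in% keep_ids, , drop = FALSE]
  ind <- factor(cc$individual_id, levels = keep_ids)
  data <- list(X = des$X, N = nrow(cc), J = ncol(des$X),
               M = length(keep_ids), ind = as.integer(ind))
  inits <- NULL
  y_scale <- NULL
  if (likelihood == "sqrt_normal") {
    # centre so the intercept prior sits on the data; the offset is added
    # back to the reported intercept
    ybar <- mean(sqrt(cc$count))
    data$y <- sqrt(cc$count) - ybar
    y_scale <- list(center = ybar, scale = 1)
    code <- info_sqrt_code
    monitor <- c("a", "b", "sigma", "sigma_ind")
    extra <- c("a", "sigma", "sigma_ind")
    # neutral start: with near-constant counts the intercept and the
    # varying intercepts are jointly ridge-constrained, and chains started
    # from diffuse prior draws can freeze off-centre
    inits <- list(a = 0, b = rep(0, ncol(des$X)),
                  u = rep(0, length(keep_ids)), sigma = 0.5,
                  sigma_ind = 0.2)
  } else {
    data$y <- cc$count
    code <- info_pois_code
    monitor <- c("a", "b", "sigma_ind")
    extra <- c("a", "sigma_ind")
    # start the log-link chain at a sane point; random draws from the
    # diffuse priors can push lambda into under/overflow
    inits <- list(a = log(mean(cc$count) + 0.5), b = rep(0, ncol(des$X)),
                  u = rep(0, length(keep_ids)), sigma_ind = 0.2)
  }
  fit <- run_jags(code, data = data, monitor = monitor, config = config,
                  inits = inits)
  rhat_gate(fit$rhat[extra], config$rhat_limit, "information model")
  structure(list(slopes = slope_summary(fit, vars, extra = extra,
                                        y_scale = y_scale),
                 draws = fit$draws,
                 report = c(fit$report,
                            list(model = paste0("information_", likelihood),
                                 n_calls = nrow(cc),
                                 n_individuals = length(keep_ids),
                                 exposure = exposure))),
            class = "effect_fit")
}

#' @export
print.effect_fit <- function(x, ...) {
  cat(sprintf("<effect_fit '%s': n=%s, exposure=%s>\n", x$report$model,
              x$report$n %||% x$report$n_calls, x$report$exposure))
  print(x$slopes, digits = 3)
  invisible(x)
}
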