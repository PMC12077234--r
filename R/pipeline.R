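#' End-to-end pipeline configuration
#'
#' Bundles the stage configurations, sampler settings and thresholds for a
#' full synthetic-data run. Defaults are sized for a desk-scale replicate
#' of the analysis: a 60-bird colony, 25 survey sessions, about 40 calls
#' per bird. Every source of randomness derives deterministically from
#' `seed`, so two runs with the same config produce identical outputs.
#'
#' @param seed master seed; stage seeds are derived from it.
#' @param population a [population_config()].
#' @param observations an [observation_config()].
#' @param calls a [call_config()].
#' @param sampler a [sampler_config()] used by every model fit (the
#'   pipeline default uses 2 chains of 500+500 iterations to keep a full
#'   run in the minutes range; raise for production inference).
#' @param min_calls repertoire inclusion threshold (vocalizations per
#'   individual).
#' @param min_height prominence threshold for amplitude-modulation peaks.
#' @param max_pairs_per_dyad cap on between-individual call pairs per dyad.
#' @param max_pairs_per_individual cap on within-individual call pairs.
#' @param tolerance_effect optional acoustic displacement along
#'   affiliative edges passed to the call generator (`dyad_effect`);
#'   positive values make close affiliates sound more different.
#' @param stages character vector of stages to run, in order.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            population = population_config(n_individuals = 60,
                                                           n_trees = 12),
                            observations = observation_config(n_sessions = 25),
                            calls = call_config(mean_calls = 40,
                                                calls_size = 3),
                            sampler = sampler_config(chains = 2L,
                                                     warmup = 500L,
                                                     samples = 500L),
                            min_calls = 30, min_height = 30,
                            max_pairs_per_dyad = 2,
                            max_pairs_per_individual = 60,
                            tolerance_effect = NULL,
                            stages = c("simulate", "networks", "distances",
                                       "fit-dyadic", "fit-diversity",
                                       "fit-information", "fit-repertoire",
                                       "fit-effects")) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

stage_seed <- function(config, k) (config$seed * 1000L + k) %% 2147483647L

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Simulates a population with its social observations and calls, builds
#' the five network layers and the multiplex, computes DTW acoustic
#' distances, fits the dyadic-similarity and within-individual-diversity
#' models, propagates their posterior summaries into the second-stage
#' effect models (similarity vs tolerance edge, diversity vs chamber size /
#' age / sex, entropy vs tree size, information content vs degree), and
#' fits the Dirichlet-multinomial composition model with a sex contrast.
#' All artifacts are written as delimited text under `out_dir`, plus a
#' machine-readable `report.json` with seeds, the config hash and
#' convergence ranges.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list(config_hash = config_hash(unclass(config)[
    setdiff(names(config), "sampler")]))
  report <- list(seed = config$seed, config_hash = res$config_hash,
                 stages = list())
  run_stage <- function(name, expr) {
    if (!any(startsWith(config$stages, name)) &&
        !name %in% config$stages) return(NULL)
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # simulate ----------------------------------------------------------
  if ("simulate" %in% config$stages) {
    res$pop <- run_stage("simulate",
                         simulate_population(config$population,
                                             stage_seed(config, 1)))
    res$obs <- run_stage("simulate",
                         simulate_social_observations(res$pop$individuals,
                                                      config$observations,
                                                      stage_seed(config, 2)))
    res$relatedness <- run_stage("simulate",
                                 simulate_relatedness(res$pop$individuals,
                                                      stage_seed(config, 3)))
    d <- file.path(out_dir, "inputs")
    dir.create(d, showWarnings = FALSE)
    write_tsv(res$pop$individuals, file.path(d, "individuals.tsv"))
    write_tsv(res$pop$nest_sites, file.path(d, "nest_sites.tsv"))
    write_tsv(res$obs$sightings, file.path(d, "sightings.tsv"))
    write_tsv(res$obs$interactions, file.path(d, "interactions.tsv"))
  }

  # networks ----------------------------------------------------------
  if ("networks" %in% config$stages) {
    res$layers <- run_stage("networks", {
      ind <- res$pop$individuals
      list(foraging = foraging_layer(res$obs$sightings),
           mate = binary_layer(res$obs$interactions, "mate", ind),
           affiliative = binary_layer(res$obs$interactions, "affiliative",
                                      ind),
           aggression = binary_layer(res$obs$interactions, "aggression", ind),
           nest_distance = nest_distance_layer(ind, res$pop$nest_sites))
    })
    res$multiplex <- multiplex_network(res$layers$foraging, res$layers$mate,
                                       res$layers$aggression,
                                       res$layers$affiliative)
    res$metrics <- node_metrics(res$layers$foraging, res$multiplex,
                                res$pop$individuals)
    d <- file.path(out_dir, "networks")
    dir.create(d, showWarnings = FALSE)
    for (nm in names(res$layers))
      write_layer(res$layers[[nm]], file.path(d, paste0(nm, ".tsv")))
    write_tsv(res$metrics, file.path(d, "node_metrics.tsv"))
    report$stages$networks <- list(
      n_nodes = vapply(res$layers, function(l) length(l$nodes), 0L),
      n_edges = vapply(res$layers, function(l) nrow(l$edges), 0L))
  }

  # calls + distances --------------------------------------------------
  if ("distances" %in% config$stages) {
    res$callsim <- run_stage("distances", {
      ccfg <- config$calls
      if (!is.null(config$tolerance_effect))
        ccfg$dyad_effect <- list(layer = res$layers$affiliative,
                                 effect = config$tolerance_effect)
      simulate_calls(res$pop$individuals, ccfg, stage_seed(config, 4))
    })
    res$between <- run_stage("distances",
      between_individual_distances(res$callsim$calls,
                                   max_pairs_per_dyad =
                                     config$max_pairs_per_dyad,
                                   seed = stage_seed(config, 5)))
    res$within <- run_stage("distances",
      within_individual_distances(res$callsim$calls,
                                  max_pairs_per_individual =
                                    config$max_pairs_per_individual,
                                  seed = stage_seed(config, 6)))
    d <- file.path(out_dir, "distances")
    dir.create(d, showWarnings = FALSE)
    write_tsv(res$between, file.path(d, "between.tsv"))
    write_tsv(res$within, file.path(d, "within.tsv"))
    write_tsv(res$callsim$calls[setdiff(names(res$callsim$calls), "f0")],
              file.path(out_dir, "inputs", "calls.tsv"))
    report$stages$distances <- list(n_between = nrow(res$between),
                                    n_within = nrow(res$within))
  }

  # first-stage acoustic models ----------------------------------------
  sam <- config$sampler
  d <- file.path(out_dir, "posteriors")
  dir.create(d, showWarnings = FALSE)
  if ("fit-dyadic" %in% config$stages) {
    cfg1 <- sam; cfg1$seed <- stage_seed(config, 7)
    res$dyadic_fit <- run_stage("fit-dyadic",
                                fit_dyadic_model(res$between, cfg1))
    write_tsv(export_summaries(res$dyadic_fit),
              file.path(d, "dyadic_summary.tsv"))
    write_tsv(res$dyadic_fit$hyper, file.path(d, "dyadic_hyper.tsv"))
    report$stages$dyadic <- res$dyadic_fit$report[c("rhat_min", "rhat_max",
                                                    "n_dyads", "n_obs")]
  }
  if ("fit-diversity" %in% config$stages) {
    cfg2 <- sam; cfg2$seed <- stage_seed(config, 8)
    res$within_fit <- run_stage("fit-diversity",
                                fit_within_model(res$within, cfg2))
    write_tsv(export_summaries(res$within_fit),
              file.path(d, "within_summary.tsv"))
    write_tsv(res$within_fit$hyper, file.path(d, "within_hyper.tsv"))
    report$stages$within <- res$within_fit$report[c("rhat_min", "rhat_max",
                                                    "n_individuals", "n_obs")]
  }

  # information content -------------------------------------------------
  if ("fit-information" %in% config$stages) {
    res$peaks <- run_stage("fit-information", {
      contact <- res$callsim$calls[res$callsim$calls$call_type == "contact", ]
      data.frame(call_id = contact$call_id,
                 individual_id = contact$individual_id,
                 count = vapply(contact$f0, count_am_peaks, 0L,
                                min_height = config$min_height),
                 stringsAsFactors = FALSE)
    })
    write_tsv(res$peaks, file.path(out_dir, "distances", "peak_counts.tsv"))
  }

  # repertoire ----------------------------------------------------------
  if ("fit-repertoire" %in% config$stages) {
    d <- file.path(out_dir, "repertoire")
    dir.create(d, showWarnings = FALSE)
    res$repertoire <- run_stage("fit-repertoire", {
      full <- build_repertoire_table(res$callsim$calls,
                                     min_calls = config$min_calls)
      comp <- build_repertoire_table(res$callsim$calls,
                                     min_calls = config$min_calls,
                                     drop_types = c("frill", "other_tonal"))
      ent <- data.frame(
        individual_id = full$individual_id,
        entropy = repertoire_entropy(full[setdiff(names(full),
                                                  c("individual_id",
                                                    "total"))]),
        stringsAsFactors = FALSE)
      covs <- res$pop$individuals[c("id", "sex", "age")]
      names(covs)[1] <- "individual_id"
      cfg3 <- sam; cfg3$seed <- stage_seed(config, 9)
      dm <- fit_dirichlet_multinomial(comp, covs, continuous = "age",
                                      config = cfg3)
      list(full = full, comp = comp, entropy = ent, dm = dm,
           contrast = if (isTRUE(dm$sex_modelled)) sex_contrast(dm) else NULL)
    })
    write_tsv(res$repertoire$full, file.path(d, "repertoire_counts.tsv"))
    write_tsv(res$repertoire$entropy, file.path(d, "entropy.tsv"))
    write_tsv(res$repertoire$dm$alpha, file.path(d, "alpha.tsv"))
    write_tsv(res$repertoire$dm$theta, file.path(d, "theta.tsv"))
    if (!is.null(res$repertoire$contrast))
      write_tsv(res$repertoire$contrast, file.path(d, "sex_contrast.tsv"))
    report$stages$repertoire <- list(
      n_individuals = nrow(res$repertoire$full),
      rhat_max = res$repertoire$dm$report$rhat_max)
  }

  # second-stage effect models ------------------------------------------
  if ("fit-effects" %in% config$stages) {
    d <- file.path(out_dir, "effects")
    dir.create(d, showWarnings = FALSE)
    res$effects <- run_stage("fit-effects",
                             fit_pipeline_effects(res, config))
    write_tsv(res$effects, file.path(d, "effect_table.tsv"))
    report$stages$effects <- list(n_models = length(unique(
      paste(res$effects$outcome, res$effects$exposure))))
  }

  report$completed <- TRUE
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(res)
}

# second-stage models the pipeline runs, mirroring the shipped registry
fit_pipeline_effects <- function(res, config) {
  sam <- config$sampler
  rows <- list()
  add_row <- function(fit, outcome, exposure, kind) {
    sl <- fit$slopes[fit$slopes$term == exposure, ]
    data.frame(outcome = outcome, exposure = exposure, kind = kind,
               mean = sl$mean, pi89_low = sl$pi89_low,
               pi89_high = sl$pi89_high,
               n = fit$report$n %||% fit$report$n_calls,
               stringsAsFactors = FALSE)
  }

  # dyadic: similarity ~ tolerance (+ mate, relatedness, foraging, nest)
  dy <- export_summaries(res$dyadic_fit)
  names(dy)[match(c("unit_id", "mean", "sd"), names(dy))] <-
    c("dyad_id", "est_mean", "est_sd")
  idmap <- unique(res$between[c("dyad_id", "id_i", "id_j")])
  dy <- merge(dy, idmap, by = "dyad_id")
  rel <- res$relatedness
  dpred <- data.frame(
    dyad_id = dy$dyad_id,
    tolerance = edge_weight(res$layers$affiliative, dy$id_i, dy$id_j),
    mate = edge_weight(res$layers$mate, dy$id_i, dy$id_j),
    foraging = edge_weight(res$layers$foraging, dy$id_i, dy$id_j),
    nest_distance = edge_weight(res$layers$nest_distance, dy$id_i, dy$id_j,
                                default = NA),
    relatedness = rel[cbind(dy$id_i, dy$id_j)],
    stringsAsFactors = FALSE)
  cfgd <- sam; cfgd$seed <- stage_seed(config, 10)
  fit_tol <- fit_dyadic_effect_model(
    dy, dpred, exposure = "tolerance",
    adjustment = c("mate", "relatedness", "foraging"),
    config = cfgd)
  rows$tolerance <- add_row(fit_tol, "similarity", "tolerance", "direct")

  # individual-level: diversity ~ chamber size / age / sex
  div <- export_summaries(res$within_fit)
  names(div)[match(c("mean", "sd"), names(div))] <- c("est_mean", "est_sd")
  covs <- merge(res$metrics, res$pop$individuals[c("id", "sex", "age")],
                by = "id")
  covs$sex_female <- as.numeric(covs$sex == "F")
  covs$sex_female[covs$sex == "unknown"] <- NA
  names(covs)[names(covs) == "id"] <- "unit_id"
  specs <- list(
    list(exposure = "chamber_size", adjustment = c("age", "sex_female"),
         kind = "total"),
    list(exposure = "age", adjustment = c("degree", "chamber_size",
                                          "sex_female"), kind = "direct"),
    list(exposure = "sex_female",
         adjustment = c("degree", "age", "chamber_size", "tree_size"),
         kind = "direct"))
  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    cfgk <- sam; cfgk$seed <- stage_seed(config, 10 + k)
    fit <- fit_individual_effect_model(div, covs, exposure = sp$exposure,
                                       adjustment = sp$adjustment,
                                       config = cfgk)
    rows[[paste0("div_", sp$exposure)]] <-
      add_row(fit, "diversity", sp$exposure, sp$kind)
  }

  # repertoire entropy ~ tree size (computed outcome: negligible est_sd)
  if (!is.null(res$repertoire)) {
    ent <- res$repertoire$entropy
    eout <- data.frame(unit_id = ent$individual_id, est_mean = ent$entropy,
                       est_sd = 1e-6, stringsAsFactors = FALSE)
    cfge <- sam; cfge$seed <- stage_seed(config, 14)
    fit_ent <- fit_individual_effect_model(
      eout, covs, exposure = "tree_size",
      adjustment = c("degree", "age", "sex_female", "chamber_size"),
      config = cfge, intercept_prior = c(1, 1), standardize = FALSE)
    rows$entropy <- add_row(fit_ent, "repertoire_entropy", "tree_size",
                            "direct")
  }

  # information content ~ degree (+ age, tree size)
  if (!is.null(res$peaks)) {
    cfgi <- sam; cfgi$seed <- stage_seed(config, 15)
    names(covs)[names(covs) == "unit_id"] <- "id"
    fit_inf <- fit_information_model(res$peaks, covs, exposure = "degree",
                                     adjustment = c("age", "tree_size"),
                                     config = cfgi)
    rows$information <- add_row(fit_inf, "information", "degree", "total")
  }

  # sex contrast on the contact-call proportion, from the composition model
  if (!is.null(res$repertoire$contrast)) {
    ct <- res$repertoire$contrast
    ct_contact <- ct[ct$unit_id == "contact", ]
    rows$contrast <- data.frame(outcome = "contact_proportion",
                                exposure = "sex_female", kind = "contrast",
                                mean = ct_contact$mean,
                                pi89_low = ct_contact$pi89_low,
                                pi89_high = ct_contact$pi89_high,
                                n = res$repertoire$dm$report$n_individuals,
                                stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarise a completed pipeline run
#'
#' Reads a pipeline output directory and returns a human-readable summary:
#' the effect table (one row per fitted effect, with 89% intervals), the
#' convergence report and headline counts. Incomplete runs produce a
#' partial report with the gaps flagged.
#'
#' @param artifact_dir directory written by [run_pipeline()].
#' @return list with `report`, `effects` (data.frame or NULL) and
#'   `messages`; printed compactly.
#' @export
pipeline_report <- function(artifact_dir) {
  msgs <- character()
  rep_file <- file.path(artifact_dir, "report.json")
  report <- if (file.exists(rep_file)) {
    jsonlite::read_json(rep_file, simplifyVector = TRUE)
  } else {
    msgs <- c(msgs, "report.json missing: incomplete run")
    NULL
  }
  eff_file <- file.path(artifact_dir, "effects", "effect_table.tsv")
  effects <- if (file.exists(eff_file)) {
    utils::read.table(eff_file, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  } else {
    msgs <- c(msgs, "no effects fitted")
    NULL
  }
  structure(list(report = report, effects = effects, messages = msgs),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report\n")
  if (!is.null(x$report))
    cat("  seed:", x$report$seed, "| config:",
        substr(x$report$config_hash, 1, 8), "\n")
  if (!is.null(x$effects)) {
    cat("  fitted effects:\n")
    print(x$effects, digits = 3)
  }
  for (m in x$messages) cat("  [!]", m, "\n")
  invisible(x)
}

#' Forest plot of fitted effects
#'
#' Dot-and-interval plot of the effect table produced by the pipeline
#' (posterior mean and 89% interval per exposure).
#'
#' @param effects effect table (data.frame with `outcome`, `exposure`,
#'   `mean`, `pi89_low`, `pi89_high`).
#' @param file optional path; when given, a PNG is written there.
#' @return invisibly, `effects`.
#' @export
plot_effects <- function(effects, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 200 + 60 * nrow(effects),
                   res = 120)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  lab <- paste(effects$outcome, "~", effects$exposure)
  n <- nrow(effects)
  old <- graphics::par(mar = c(4, 14, 1, 1))
  on.exit(graphics::par(old), add = TRUE)
  graphics::plot(effects$mean, seq_len(n),
                 xlim = range(c(effects$pi89_low, effects$pi89_high, 0)),
                 ylim = c(0.5, n + 0.5), yaxt = "n", pch = 16,
                 xlab = "standardised effect (89% interval)", ylab = "")
  graphics::segments(effects$pi89_low, seq_len(n), effects$pi89_high,
                     seq_len(n))
  graphics::abline(v = 0, lty = 2, col = "grey50")
  graphics::axis(2, at = seq_len(n), labels = lab, las = 1, cex.axis = 0.8)
  invisible(effects)
}
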