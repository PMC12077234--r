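# Shared configuration for the analysis scripts. Source()d by each
# numbered driver; everything derives from one master seed so the whole
# workflow is reproducible end to end.

library(vocnet)

MASTER_SEED <- 20211031L   # season start of the second field period
RESULTS_DIR <- "results"

# Study conditions for the synthetic colony: 60 marked individuals in a
# dozen nesting trees, 25 survey sessions, ~40 classified calls per bird.
# The generator plants two effects whose recovery the later scripts check:
# affiliated dyads are pushed apart in acoustic space, and females carry a
# -0.5 log-proportion deficit on the contact call.
analysis_config <- pipeline_config(
  seed = MASTER_SEED,
  population = population_config(n_individuals = 60, n_trees = 12),
  observations = observation_config(n_sessions = 25),
  calls = call_config(mean_calls = 40, calls_size = 3,
                      delta_sex = c(-0.5, rep(0, 10))),
  sampler = sampler_config(chains = 2L, warmup = 600L, samples = 600L,
                           seed = MASTER_SEED),
  tolerance_effect = 1.5)

dir.create(RESULTS_DIR, showWarnings = FALSE)

save_table <- function(df, name) {
  path <- file.path(RESULTS_DIR, name)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  message("wrote ", path)
  invisible(path)
}
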