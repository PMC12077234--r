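#!/usr/bin/env Rscript
# Simulate the synthetic colony: individuals with nest assignments,
# foraging sightings, dyadic interactions, relatedness, and classified
# calls with F0 traces. Writes the six input tables under results/inputs/.

source("analysis/00_config.R")
cfg <- analysis_config

pop <- simulate_population(cfg$population, seed = MASTER_SEED + 1L)
obs <- simulate_social_observations(pop$individuals, cfg$observations,
                                    seed = MASTER_SEED + 2L)
rel <- simulate_relatedness(pop$individuals, seed = MASTER_SEED + 3L)

# the affiliative layer is needed now so the call generator can displace
# affiliated dyads in acoustic space
aff <- binary_layer(obs$interactions, "affiliative", pop$individuals)
ccfg <- cfg$calls
ccfg$dyad_effect <- list(layer = aff, effect = cfg$tolerance_effect)
calls <- simulate_calls(pop$individuals, ccfg, seed = MASTER_SEED + 4L)

write_input_tables(list(individuals = pop$individuals,
                        nest_sites = pop$nest_sites,
                        sightings = obs$sightings,
                        interactions = obs$interactions,
                        calls = calls$calls,
                        relatedness = rel,
                        truth = calls$truth),
                   file.path(RESULTS_DIR, "inputs"))

gs <- group_sizes(pop$individuals)
message(sprintf(paste0(
  "simulated %d individuals (%d nesting), %d sightings, %d interactions, ",
  "%d calls; chamber sizes %d-%d, tree sizes %d-%d"),
  nrow(pop$individuals), sum(!is.na(pop$individuals$entry_id)),
  nrow(obs$sightings), nrow(obs$interactions), nrow(calls$calls),
  min(gs$chamber_size, na.rm = TRUE), max(gs$chamber_size, na.rm = TRUE),
  min(gs$tree_size, na.rm = TRUE), max(gs$tree_size, na.rm = TRUE)))
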