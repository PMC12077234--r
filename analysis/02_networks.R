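#!/usr/bin/env Rscript
# Build the five social-network layers and the multiplex from the
# simulated observation tables; compute the node metrics used as
# predictors downstream.

source("analysis/00_config.R")
ind <- read.table(file.path(RESULTS_DIR, "inputs", "individuals.tsv"),
                  header = TRUE, sep = "\t", stringsAsFactors = FALSE)
ns <- read.table(file.path(RESULTS_DIR, "inputs", "nest_sites.tsv"),
                 header = TRUE, sep = "\t", stringsAsFactors = FALSE)
sg <- read.table(file.path(RESULTS_DIR, "inputs", "sightings.tsv"),
                 header = TRUE, sep = "\t", stringsAsFactors = FALSE)
iv <- read.table(file.path(RESULTS_DIR, "inputs", "interactions.tsv"),
                 header = TRUE, sep = "\t", stringsAsFactors = FALSE)

layers <- list(foraging = foraging_layer(sg),
               mate = binary_layer(iv, "mate", ind),
               affiliative = binary_layer(iv, "affiliative", ind),
               aggression = binary_layer(iv, "aggression", ind),
               nest_distance = nest_distance_layer(ind, ns))
for (nm in names(layers)) {
  print(layers[[nm]])
  write_layer(layers[[nm]], file.path(RESULTS_DIR, paste0(nm, ".tsv")))
}

mp <- multiplex_network(layers$foraging, layers$mate, layers$aggression,
                        layers$affiliative)
metrics <- node_metrics(layers$foraging, mp, ind)
save_table(metrics, "node_metrics.tsv")

message(sprintf(
  "foraging degree 0-%d; versatility 0-%d; %d of %d individuals nest-assigned",
  max(metrics$degree, na.rm = TRUE), max(metrics$versatility, na.rm = TRUE),
  sum(!is.na(metrics$chamber_size)), nrow(metrics)))
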