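test_that("simulated populations respect nesting caps and are deterministic", {
  cfg <- population_config(n_individuals = 100)
  pop <- simulate_population(cfg, seed = 7)
  sizes <- table(pop$individuals$entry_id)
  expect_true(all(sizes >= 1 & sizes <= 4))
  tree_sizes <- table(pop$individuals$tree_id)
  expect_true(all(tree_sizes >= 1 & tree_sizes <= 20))
  # entries of one tree share coordinates up to survey jitter
  ns <- pop$nest_sites
  for (tr in unique(ns$tree_id)) {
    xs <- ns$x[ns$tree_id == tr]
    expect_lt(diff(range(xs)), 10)
  }
  # determinism
  pop2 <- simulate_population(cfg, seed = 7)
  expect_identical(pop, pop2)
  pop3 <- simulate_population(population_config(n_individuals = 200), seed = 7)
  pop4 <- simulate_population(population_config(n_individuals = 200), seed = 7)
  expect_identical(pop3, pop4)
  # degenerate single-individual population
  tiny <- simulate_population(population_config(n_individuals = 1, n_trees = 1,
                                                prop_unassigned = 0),
                              seed = 1)
  expect_equal(nrow(tiny$individuals), 1)
  expect_equal(unname(table(tiny$individuals$tree_id)[1]), 1)
})

test_that("infeasible population configs are rejected", {
  expect_error(population_config(n_individuals = 500, n_trees = 2,
                                 max_tree_size = 20),
               "infeasible")
  expect_error(population_config(n_individuals = 0), "n_individuals")
  expect_error(population_config(chamber_size_probs = c(1, 1)), "weights")
})

test_that("allopreening concentrates within shared nest entries", {
  pop <- simulate_population(population_config(n_individuals = 80), seed = 3)
  obs <- simulate_social_observations(
    pop$individuals, observation_config(mate_fidelity = 0.95), seed = 3)
  ap <- obs$interactions[obs$interactions$type == "allopreen", ]
  expect_gt(nrow(ap), 20)
  # brute-force join of events against entry assignments
  entry <- setNames(pop$individuals$entry_id, pop$individuals$id)
  shared <- mapply(function(a, b) {
    !is.na(entry[a]) && !is.na(entry[b]) && entry[a] == entry[b]
  }, ap$id_a, ap$id_b)
  expect_gt(mean(shared), 0.9)
})

test_that("observation edge cases behave as specified", {
  pop <- simulate_population(population_config(n_individuals = 20), seed = 2)
  # zero aggression rate leaves the aggression table empty
  obs <- simulate_social_observations(
    pop$individuals, observation_config(rate_aggression = 0), seed = 2)
  expect_equal(sum(obs$interactions$type == "aggression"), 0)
  # zero sessions warn, not fail
  expect_warning(
    empty <- simulate_social_observations(pop$individuals,
                                          observation_config(n_sessions = 0),
                                          seed = 2),
    "zero sessions")
  expect_equal(nrow(empty$sightings), 0)
  expect_equal(nrow(empty$interactions), 0)
  # determinism
  o1 <- simulate_social_observations(pop$individuals, observation_config(),
                                     seed = 9)
  o2 <- simulate_social_observations(pop$individuals, observation_config(),
                                     seed = 9)
  expect_identical(o1, o2)
})

test_that("relatedness matrices are symmetric with configured kin structure", {
  pop <- simulate_population(population_config(n_individuals = 50), seed = 4)
  kin <- data.frame(id_a = "ind001", id_b = "ind002")
  m <- simulate_relatedness(pop$individuals, seed = 4, kin_pairs = kin)
  expect_identical(m, t(m))
  expect_true(all(m[upper.tri(m)] >= 0 & m[upper.tri(m)] <= 1))
  expect_gte(m["ind001", "ind002"], 0.35)
  expect_lte(m["ind001", "ind002"], 0.65)
  # unrelated population: small mean away from the kin pair
  m2 <- simulate_relatedness(pop$individuals, seed = 5)
  expect_lt(mean(m2[upper.tri(m2)]), 0.05)
})

test_that("call-type counts follow the configured composition", {
  pop <- simulate_population(population_config(n_individuals = 30), seed = 6)
  # beta = 0, very large theta: empirical proportions approach alpha
  cfg <- call_config(mean_calls = 400, calls_size = 1e6, theta = 1e6)
  cs <- simulate_calls(pop$individuals, cfg, seed = 6)
  emp <- table(factor(cs$calls$call_type, levels = call_type_labels()))
  emp <- as.numeric(emp) / sum(emp)
  expect_lt(max(abs(emp - cfg$alpha)), 0.02)
  expect_equal(length(unique(cs$calls$call_type)), 11)
  # determinism
  cs2 <- simulate_calls(pop$individuals, cfg, seed = 6)
  expect_identical(cs$calls, cs2$calls)
  # a non-simplex alpha is rejected
  expect_error(call_config(alpha = rep(1, 11)), "simplex")
})

test_that("a configured female contact-call deficit shows in the counts", {
  pop <- simulate_population(population_config(n_individuals = 60,
                                               prop_unknown_sex = 0),
                             seed = 8)
  cfg <- call_config(mean_calls = 50, theta = 50,
                     delta_sex = c(-0.3, rep(0, 10)))
  hits <- 0
  for (r in 1:20) {
    cs <- simulate_calls(pop$individuals, cfg, seed = 800 + r)
    calls <- merge(cs$calls, pop$individuals[c("id", "sex")],
                   by.x = "individual_id", by.y = "id")
    share <- tapply(calls$call_type == "contact", calls$sex, mean)
    if (share[["F"]] < share[["M"]]) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("input tables round-trip through the text format", {
  pop <- simulate_population(population_config(n_individuals = 12,
                                               n_trees = 4), seed = 5)
  obs <- simulate_social_observations(pop$individuals,
                                      observation_config(n_sessions = 5),
                                      seed = 5)
  cs <- simulate_calls(pop$individuals, call_config(mean_calls = 4), seed = 5)
  rel <- simulate_relatedness(pop$individuals, seed = 5)
  dir <- withr::local_tempdir()
  write_input_tables(list(individuals = pop$individuals,
                          nest_sites = pop$nest_sites,
                          sightings = obs$sightings,
                          interactions = obs$interactions,
                          calls = cs$calls, relatedness = rel,
                          truth = cs$truth), dir)
  back <- read_calls(dir)
  expect_equal(back$call_id, cs$calls$call_id)
  i <- which.max(lengths(cs$calls$f0))
  expect_equal(back$f0[[i]], cs$calls$f0[[i]], tolerance = 1e-4)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(gt$theta, cs$truth$theta)
})
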