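test_that("back-door adjustment handles mediation and confounding", {
  chain <- effect_dag(c("X", "M", "Y"),
                      data.frame(from = c("X", "M"), to = c("M", "Y")))
  expect_equal(build_adjustment("X", "Y", chain, "total"), character(0))
  expect_equal(build_adjustment("X", "Y", chain, "direct"), "M")
  fork <- effect_dag(c("Z", "X", "Y"),
                     data.frame(from = c("Z", "Z", "X"),
                                to = c("X", "Y", "Y")))
  expect_equal(build_adjustment("X", "Y", fork, "total"), "Z")
  expect_equal(build_adjustment("X", "Y", fork, "direct"), "Z")
  expect_error(build_adjustment("Q", "Y", fork), "exposure")
  expect_error(effect_dag(c("A", "B"),
                          data.frame(from = c("A", "B"), to = c("B", "A"))),
               "cyclic")
})

test_that("the shipped diversity DAG reproduces the chamber-size model", {
  dags <- default_dags()
  adj <- build_adjustment("chamber_size", "diversity", dags$diversity,
                          "total")
  expect_setequal(adj, c("age", "sex"))
  f <- effect_formula("diversity", "chamber_size", adj)
  expect_equal(deparse(f), "diversity ~ chamber_size + age + sex")
  # exposures without mediators: total and direct coincide
  for (exp_var in c("tree_size", "network_position")) {
    expect_equal(build_adjustment(exp_var, "diversity", dags$diversity,
                                  "total"),
                 build_adjustment(exp_var, "diversity", dags$diversity,
                                  "direct"))
  }
  expect_equal(build_adjustment("tolerance", "acoustic_distance",
                                dags$similarity, "total"),
               build_adjustment("tolerance", "acoustic_distance",
                                dags$similarity, "direct"))
  # registry rows are internally consistent
  reg <- model_registry()
  expect_true(all(c("outcome", "exposure", "kind", "adjustment") %in%
                    names(reg)))
  expect_false(any(mapply(grepl, reg$exposure, reg$adjustment)))
})

test_that("measurement error widens slope posteriors", {
  sim <- simulate_measured_outcomes(n = 60, slope = 0.4, est_sd = 0.05,
                                    seed = 11)
  cfg <- quick_config(seed = 12, warmup = 800, samples = 800)
  f_small <- suppressWarnings(
    fit_individual_effect_model(sim$outcomes, sim$predictors, "x",
                                config = cfg))
  noisy <- sim$outcomes
  noisy$est_sd <- noisy$est_sd * 10
  f_big <- suppressWarnings(
    fit_individual_effect_model(noisy, sim$predictors, "x", config = cfg))
  sd_small <- f_small$slopes$sd[f_small$slopes$term == "x"]
  sd_big <- f_big$slopes$sd[f_big$slopes$term == "x"]
  expect_gt(sd_big, sd_small)
})

test_that("vanishing measurement error recovers ordinary regression", {
  sim <- simulate_measured_outcomes(n = 100, slope = 0.6, sigma_resid = 0.25,
                                    est_sd = 1e-6, seed = 21)
  f <- fit_individual_effect_model(sim$outcomes, sim$predictors, "x",
                                   config = quick_config(seed = 22,
                                                         warmup = 500))
  ols <- coef(lm(est_mean ~ x, data = merge(sim$outcomes, sim$predictors)))
  slope <- f$slopes[f$slopes$term == "x", ]
  expect_equal(slope$mean, unname(ols["x"]), tolerance = 0.03)
})

test_that("dyadic effect models are invariant to consistent relabeling", {
  sim <- simulate_dyadic_outcomes(n_individuals = 25, n_dyads = 150,
                                  slope = 0.4, seed = 31)
  cfg <- quick_config(seed = 32, warmup = 500)
  f1 <- suppressWarnings(fit_dyadic_effect_model(sim$outcomes,
                                                 sim$predictors, "x",
                                                 config = cfg))
  # permute dyads and rename ids consistently in outcomes and predictors
  set.seed(33)
  perm <- sample(nrow(sim$outcomes))
  out2 <- sim$outcomes[perm, ]
  pred2 <- sim$predictors[perm, ]
  ren <- function(x) paste0("relab_", x)
  out2$dyad_id <- ren(out2$dyad_id)
  out2$id_i <- ren(out2$id_i)
  out2$id_j <- ren(out2$id_j)
  pred2$dyad_id <- ren(pred2$dyad_id)
  f2 <- suppressWarnings(fit_dyadic_effect_model(out2, pred2, "x",
                                                 config = cfg))
  s1 <- f1$slopes[f1$slopes$term == "x", ]
  s2 <- f2$slopes[f2$slopes$term == "x", ]
  expect_lt(abs(s1$mean - s2$mean), 3 * sqrt(s1$sd^2 + s2$sd^2))
  # the positive edge effect is detected in both fits
  expect_gt(s1$pi89_low, 0)
  expect_gt(s2$pi89_low, 0)
})

test_that("information models respect their link structure", {
  sim <- simulate_peak_counts(n_individuals = 40, calls_per_individual = 6,
                              slope = 0, sigma_ind = 0.001, seed = 41)
  sim$counts$count <- 4L   # all counts equal
  f <- suppressWarnings(fit_information_model(sim$counts, sim$predictors,
                                              "x",
                                              config = quick_config(seed = 42)))
  expect_lt(f$slopes$mean[f$slopes$term == "sigma_ind"], 0.1)
  # doubling counts under the log link shifts the intercept by log 2
  sim2 <- simulate_peak_counts(n_individuals = 40, calls_per_individual = 8,
                               slope = 0.3, seed = 43)
  cfg <- quick_config(seed = 44, warmup = 500)
  fp <- suppressWarnings(fit_information_model(sim2$counts, sim2$predictors,
                                               "x", likelihood = "poisson",
                                               config = cfg))
  doubled <- sim2$counts
  doubled$count <- doubled$count * 2L
  fp2 <- suppressWarnings(fit_information_model(doubled, sim2$predictors,
                                                "x", likelihood = "poisson",
                                                config = cfg))
  a1 <- fp$slopes[fp$slopes$term == "a", ]
  a2 <- fp2$slopes[fp2$slopes$term == "a", ]
  expect_equal(a2$mean - a1$mean, log(2), tolerance = 0.1)
  b1 <- fp$slopes[fp$slopes$term == "x", ]
  b2 <- fp2$slopes[fp2$slopes$term == "x", ]
  expect_lt(abs(b1$mean - b2$mean), 3 * sqrt(b1$sd^2 + b2$sd^2))
})

test_that("missing predictors are reported by name", {
  sim <- simulate_measured_outcomes(n = 30, seed = 51)
  sim$predictors$bad <- NA_real_
  expect_error(fit_individual_effect_model(sim$outcomes, sim$predictors,
                                           "bad"),
               "bad")
  expect_error(fit_individual_effect_model(sim$outcomes, sim$predictors,
                                           "absent"),
               "absent")
})
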