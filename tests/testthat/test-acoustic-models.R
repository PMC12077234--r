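test_that("constant distances leave no dyadic variance to explain", {
  obs <- simulate_dyadic_distances(n_dyads = 30, obs_per_dyad = 4,
                                   n_recordings = 20, seed = 1)$observations
  obs$distance <- 1
  fit <- suppressWarnings(fit_dyadic_model(obs, quick_config(seed = 2)))
  # posterior median below the exponential(2) prior median log(2)/2
  expect_lt(median(fit$hyper_draws[, "sigma_dyad"]), 0.347)
})

test_that("dyad similarity estimates recover the generator's ranking", {
  sim <- simulate_dyadic_distances(seed = 31)
  fit <- suppressWarnings(
    fit_dyadic_model(sim$observations,
                     quick_config(seed = 32, warmup = 500)))
  est <- fit$dyads$mean[match(names(sim$truth$alpha_dyad),
                              fit$dyads$unit_id)]
  expect_gte(cor(est, sim$truth$alpha_dyad, method = "spearman"), 0.8)
  # back-transform keeps estimates on the input scale
  expect_lt(abs(mean(est) - mean(sim$observations$distance)), 0.1)
})

test_that("posterior summaries agree with the stored draws", {
  sim <- simulate_dyadic_distances(n_dyads = 40, obs_per_dyad = 5,
                                   n_recordings = 20, seed = 41)
  fit <- suppressWarnings(fit_dyadic_model(sim$observations,
                                           quick_config(seed = 42)))
  tab <- export_summaries(fit)
  expect_equal(nrow(tab), 40)
  # sd column equals the standard deviation recomputed from raw draws
  resd <- apply(fit$draws, 2, sd)
  expect_equal(tab$sd, unname(resd[tab$unit_id]))
  # near-symmetric posteriors: mean close to the interval midpoint
  mid <- (tab$pi89_low + tab$pi89_high) / 2
  expect_true(all(abs(tab$mean - mid) < 0.5 * tab$sd))
  expect_true(all(tab$pi89_low <= tab$mean & tab$mean <= tab$pi89_high))
})

test_that("dyads with few observations shrink harder toward the mean", {
  set.seed(5)
  # background dyads centred at 0; two focal dyads with raw mean 1,
  # one sparse (2 obs) and one dense (20 obs)
  bg <- do.call(rbind, lapply(1:20, function(d) data.frame(
    dyad_id = sprintf("bg%02d", d), distance = rnorm(8, 0, 0.2))))
  focal <- rbind(
    data.frame(dyad_id = "sparse", distance = 1 + rnorm(2, 0, 1e-3)),
    data.frame(dyad_id = "dense", distance = 1 + rnorm(20, 0, 1e-3)))
  obs <- rbind(bg, focal)
  n <- nrow(obs)
  obs$call_i <- sprintf("a%03d", 1:n)
  obs$call_j <- sprintf("b%03d", 1:n)
  obs$id_i <- paste0(obs$dyad_id, "_1")
  obs$id_j <- paste0(obs$dyad_id, "_2")
  obs$rec_i <- sample(sprintf("r%02d", 1:10), n, replace = TRUE)
  obs$rec_j <- sample(sprintf("r%02d", 1:10), n, replace = TRUE)
  obs$same_recording <- FALSE
  fit <- suppressWarnings(fit_dyadic_model(obs, quick_config(seed = 6,
                                                             warmup = 500)))
  abar <- mean(fit$hyper_draws[, "abar"])
  d <- fit$dyads
  pull <- function(id) abs(d$mean[d$unit_id == id] - abar)
  expect_lt(pull("sparse"), pull("dense"))
})

test_that("non-finite distances are rejected with a row report", {
  sim <- simulate_dyadic_distances(n_dyads = 5, obs_per_dyad = 2,
                                   n_recordings = 4, seed = 3)
  sim$observations$distance[3] <- NA
  expect_error(fit_dyadic_model(sim$observations), "rows")
  expect_error(fit_within_model(sim$observations), "rows")
})

test_that("within-individual model separates high- and low-diversity groups", {
  # two groups whose true alpha_ind differ clearly
  simA <- simulate_within_distances(
    n_individuals = 10, calls_per_individual = 8,
    truth = list(abar = 0.4, sigma_ind = 0.03, alpha_same_rec = -0.05,
                 sigma_rec_pair = 0.05, sigma_call = 0.08, sigma = 0.1),
    seed = 61)
  simB <- simulate_within_distances(
    n_individuals = 10, calls_per_individual = 8,
    truth = list(abar = 0.8, sigma_ind = 0.03, alpha_same_rec = -0.05,
                 sigma_rec_pair = 0.05, sigma_call = 0.08, sigma = 0.1),
    seed = 62)
  obsB <- simB$observations
  for (col in c("call_i", "call_j", "id_i", "id_j", "rec_i", "rec_j",
                "dyad_id"))
    obsB[[col]] <- paste0("B", obsB[[col]])
  obs <- rbind(simA$observations, obsB)
  fit <- suppressWarnings(fit_within_model(obs, quick_config(seed = 63,
                                                             warmup = 500)))
  est <- fit$individuals
  a_mean <- mean(est$mean[!startsWith(est$unit_id, "B")])
  b_mean <- mean(est$mean[startsWith(est$unit_id, "B")])
  expect_gt(b_mean, a_mean)
  tab <- export_summaries(fit)
  expect_equal(unique(tab$unit_type), "individual")
  expect_equal(nrow(tab), 20)
})

test_that("hyperparameter priors match their stated densities", {
  pd <- prior_draws("dyadic", n = 2e5, seed = 9)
  expect_equal(mean(pd$sigma), 0.5, tolerance = 0.02)
  expect_equal(sd(pd$abar), 0.5, tolerance = 0.02)
  pw <- prior_draws("within", n = 2e5, seed = 9)
  expect_equal(mean(pw$sigma), 0.2, tolerance = 0.02)
  expect_equal(mean(pw$sigma_ind), 1 / 3, tolerance = 0.02)
  expect_equal(sd(pw$abar), 0.25, tolerance = 0.02)
})
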