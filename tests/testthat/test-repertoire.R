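test_that("repertoire entropy matches analytic values and the summation oracle", {
  expect_equal(repertoire_entropy(c(0, 12, 0)), 0)
  expect_equal(repertoire_entropy(c(6, 6)), log(2))
  expect_equal(repertoire_entropy(c(5, 3, 2)),
               -(0.5 * log(0.5) + 0.3 * log(0.3) + 0.2 * log(0.2)))
  expect_equal(repertoire_entropy(c(5, 3, 2)), 1.0297, tolerance = 1e-4)
  expect_equal(repertoire_entropy(c(4, 4), base = 2), 1)
  expect_error(repertoire_entropy(c(0, 0)), "zero")
  expect_error(repertoire_entropy(c(-1, 2)), "non-negative")
  set.seed(17)
  for (k in 1:1000) {
    counts <- rpois(sample(2:11, 1), lambda = 5)
    if (sum(counts) == 0) counts[1] <- 1
    expect_equal(repertoire_entropy(counts), entropy_oracle(counts),
                 tolerance = 1e-12)
  }
})

test_that("entropy is maximal at the uniform composition", {
  # enumerate all compositions of given totals over K <= 4 types
  compositions <- function(total, k) {
    if (k == 1) return(matrix(total, 1, 1))
    out <- list()
    for (first in 0:total) {
      rest <- compositions(total - first, k - 1)
      out[[length(out) + 1]] <- cbind(first, rest)
    }
    do.call(rbind, out)
  }
  for (k in 2:4) {
    for (total in seq(k, 12, by = k)) {
      h_uniform <- repertoire_entropy(rep(total / k, k))
      cs <- compositions(total, k)
      hs <- apply(cs[rowSums(cs) > 0, , drop = FALSE], 1, repertoire_entropy)
      expect_true(all(hs <= h_uniform + 1e-12))
    }
  }
})

test_that("repertoire tables apply the minimum-call and rare-type filters", {
  calls <- data.frame(
    individual_id = c(rep("low", 29), rep("ok", 31)),
    call_type = c(rep("contact", 29), rep("contact", 25),
                  rep("frill", 3), rep("trill", 3)),
    stringsAsFactors = FALSE)
  expect_message(tab <- build_repertoire_table(calls, min_calls = 30),
                 "excluded")
  expect_equal(tab$individual_id, "ok")
  expect_equal(ncol(tab), 13)   # id + 11 types + total
  expect_equal(tab$total, 31)
  # dropping the two rare types leaves 9 type columns, filter still on 11
  tab9 <- suppressMessages(build_repertoire_table(
    calls, min_calls = 30, drop_types = c("frill", "other_tonal")))
  expect_equal(ncol(tab9), 11)  # id + 9 types + total
  expect_equal(tab9$total, 28)  # frill calls no longer counted in total
  expect_error(build_repertoire_table(
    data.frame(individual_id = "a", call_type = "yodel")), "yodel")
  expect_warning(empty <- build_repertoire_table(
    calls[0, ], min_calls = 30), "empty")
  expect_equal(nrow(empty), 0)
})

test_that("dispersion ordering: large theta concentrates individuals", {
  pop <- simulate_population(population_config(n_individuals = 25,
                                               prop_unknown_sex = 0),
                             seed = 71)
  base <- call_config(mean_calls = 80, calls_size = 1e6)
  tight <- base; tight$theta <- 200
  loose <- base; loose$theta <- 3
  fit_theta <- function(cfg, seed) {
    cs <- simulate_calls(pop$individuals, cfg, seed = seed)
    tab <- suppressMessages(build_repertoire_table(cs$calls, min_calls = 30))
    fit <- suppressWarnings(fit_dirichlet_multinomial(
      tab, config = quick_config(seed = seed + 1)))
    median(fit$draws$theta)
  }
  expect_gt(fit_theta(tight, 72), fit_theta(loose, 74))
})

test_that("sex contrasts recover a configured female contact deficit", {
  pop <- simulate_population(population_config(n_individuals = 40,
                                               prop_unknown_sex = 0),
                             seed = 81)
  cfg <- call_config(mean_calls = 80, calls_size = 1e6, theta = 15,
                     delta_sex = c(-0.5, rep(0, 10)))
  cs <- simulate_calls(pop$individuals, cfg, seed = 82)
  tab <- suppressMessages(build_repertoire_table(cs$calls, min_calls = 30))
  covs <- pop$individuals[c("id", "sex", "age")]
  names(covs)[1] <- "individual_id"
  fit <- suppressWarnings(fit_dirichlet_multinomial(
    tab, covs, continuous = "age", config = quick_config(seed = 83,
                                                         warmup = 500)))
  ct <- sex_contrast(fit)
  expect_lt(ct$mean[ct$unit_id == "contact"], 0)
  # contrasts live on the proportion scale and sum to zero
  expect_equal(sum(ct$mean), 0, tolerance = 1e-10)
  # without sex variation the contrast is refused
  fit0 <- suppressWarnings(fit_dirichlet_multinomial(
    tab, config = quick_config(seed = 84, warmup = 200, samples = 100)))
  expect_error(sex_contrast(fit0), "sex")
})

test_that("zero-count call types are dropped before fitting", {
  counts <- data.frame(individual_id = sprintf("i%02d", 1:12),
                       contact = rpois(12, 40) + 30, alarm = rpois(12, 5),
                       trill = 0L, stringsAsFactors = FALSE)
  counts$total <- counts$contact + counts$alarm + counts$trill
  expect_warning(fit <- fit_dirichlet_multinomial(
    counts, config = quick_config(seed = 91, warmup = 200, samples = 100)),
    "trill")
  expect_equal(fit$types, c("contact", "alarm"))
})
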