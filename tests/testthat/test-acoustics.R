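test_that("dtw distance is zero on identical traces and symmetric", {
  a <- c(1, 2, 3, 2, 1)
  expect_equal(dtw_distance(a, a), 0)
  set.seed(1)
  for (k in 1:10) {
    x <- rnorm(sample(5:20, 1))
    y <- rnorm(sample(5:20, 1))
    expect_equal(dtw_distance(x, y), dtw_distance(y, x))
  }
  expect_error(dtw_distance(1, c(1, 2)), "length")
  expect_error(dtw_distance(c(1, NA, 2), c(1, 2)), "missing")
})

test_that("dtw equals exhaustive warping-path minimisation on short traces", {
  # the stated example pair
  expect_equal(dtw_distance(c(1, 2, 3), c(1, 2, 2, 3), center = FALSE),
               dtw_oracle(c(1, 2, 3), c(1, 2, 2, 3)))
  set.seed(7)
  for (k in 1:30) {
    a <- sample(0:9, sample(2:6, 1), replace = TRUE)
    b <- sample(0:9, sample(2:6, 1), replace = TRUE)
    expect_equal(dtw_distance(a, b, center = FALSE), dtw_oracle(a, b),
                 info = paste("a =", paste(a, collapse = ","),
                              "b =", paste(b, collapse = ",")))
  }
})

test_that("dtw grows monotonically under increasing additive perturbation", {
  set.seed(3)
  a <- 100 * sin(seq(0, 2 * pi, length.out = 40))
  for (rep in 1:8) {
    b <- rnorm(40)
    d <- vapply(seq(0, 2, by = 0.2), function(e)
      dtw_distance(a, a + e * b, center = FALSE), numeric(1))
    expect_true(all(diff(d) >= -1e-9))
  }
})

test_that("amplitude-modulation peaks are counted by prominence", {
  expect_equal(count_am_peaks(rep(5, 50)), 0)
  # three bumps of amplitude 50 over baseline
  bump <- function(amp) c(rep(0, 5), rep(amp, 3), rep(0, 5))
  sig <- c(bump(50), bump(50), bump(50))
  expect_equal(count_am_peaks(sig, min_height = 30), 3)
  # same layout with amplitude 10: prominence below threshold
  sig10 <- c(bump(10), bump(10), bump(10))
  expect_equal(count_am_peaks(sig10, min_height = 30), 0)
  # offset invariance
  expect_equal(count_am_peaks(sig + 1000, min_height = 30), 3)
  # endpoints are not peaks: monotone ramp has none
  expect_equal(count_am_peaks(seq(0, 100, by = 10), min_height = 5), 0)
  expect_error(count_am_peaks(numeric(0)), "empty")
  # a shallow dip between tall peaks limits both peaks' prominence to the
  # height above the higher (inner) flanking trough
  sig2 <- c(0, 100, 80, 100, 0)
  expect_equal(count_am_peaks(sig2, min_height = 30), 0)
  expect_equal(count_am_peaks(sig2, min_height = 20), 2)
})

test_that("between-individual pairs cover all cross pairs with dyad metadata", {
  traces <- replicate(4, cumsum(rnorm(10)), simplify = FALSE)
  calls <- make_calls(traces, c("A", "A", "B", "B"))
  obs <- between_individual_distances(calls)
  expect_equal(nrow(obs), 4)        # 2 x 2 cross pairs
  expect_true(all(obs$dyad_id == "A--B"))
  expect_true(all(!obs$same_recording))
  # single individual -> empty
  solo <- make_calls(traces, "A")
  expect_equal(nrow(between_individual_distances(solo)), 0)
  # cap of one pair per dyad
  capped <- between_individual_distances(calls, max_pairs_per_dyad = 1)
  expect_equal(nrow(capped), 1)
  # symmetric dyad id regardless of order
  expect_equal(unique(obs$id_i), "A")
})

test_that("within-individual pairs flag same-recording comparisons", {
  traces <- replicate(3, cumsum(rnorm(10)), simplify = FALSE)
  calls <- make_calls(traces, "A", recording = c("r1", "r1", "r2"))
  obs <- within_individual_distances(calls)
  expect_equal(nrow(obs), 3)        # C(3,2)
  expect_equal(sum(obs$same_recording), 1)
  # a bird with one call contributes nothing
  calls2 <- rbind(calls, make_calls(traces[1], "B"))
  obs2 <- within_individual_distances(calls2)
  expect_equal(nrow(obs2), 3)
  expect_true(all(obs2$id_i == "A"))
})

test_that("distance matrices reflect the generator's within/between structure", {
  pop <- simulate_population(population_config(n_individuals = 12,
                                               n_trees = 4), seed = 13)
  cs <- simulate_calls(pop$individuals,
                       call_config(mean_calls = 8, within_sd = 0.3,
                                   between_sd = 1.5), seed = 13)
  bt <- between_individual_distances(cs$calls, max_pairs_per_dyad = 3)
  wt <- within_individual_distances(cs$calls)
  expect_gt(mean(bt$distance), mean(wt$distance))
})
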