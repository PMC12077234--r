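#' Call type labels
#'
#' The eleven call-type labels used throughout the package. The contact
#' call comes first and dominates most repertoires; `frill` and
#' `other_tonal` are rare types excluded from the composition model.
#'
#' @return character vector of length 11.
#' @export
call_type_labels <- function() {
  c("contact", "alarm", "chatter", "churr", "frill", "growl",
    "other_tonal", "screech", "trill", "warble", "whistle")
}

#' Ground-truth record for synthetic data
#'
#' Every generator returns (or embeds) a `ground_truth` object holding the
#' true parameter values used for simulation, so recovery tests can compare
#' posterior estimates against them by name.
#'
#' @param seed the seed the data were generated under.
#' @param ... named true parameter values (scalars, vectors, matrices).
#' @return an object of class `ground_truth` (a named list).
#' @export
ground_truth <- function(seed, ...) {
  structure(c(list(seed = seed), list(...)), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth: seed", x$seed, "| parameters:",
      paste(setdiff(names(x), "seed"), collapse = ", "), ">\n")
  invisible(x)
}

#' Configuration for the synthetic population
#'
#' Defaults emulate a colonial nesting population: chamber (nest-entry)
#' groups of 1-4 individuals, nesting trees holding up to 20 individuals,
#' a balanced sex ratio with some unsexed birds, and log-normal ages with
#' a median around 2.5 years (population means of roughly 1000-1400 days
#' are typical for an established urban colony).
#'
#' @param n_individuals population size.
#' @param n_trees number of candidate nesting trees.
#' @param chamber_size_probs sampling weights for chamber sizes 1..4.
#' @param max_tree_size cap on individuals per tree.
#' @param sex_ratio probability an individual is female.
#' @param prop_unknown_sex fraction with unknown sex.
#' @param age_meanlog,age_sdlog log-normal age parameters (days).
#' @param prop_unassigned fraction of individuals without a nest entry.
#' @param area_m side of the square study area (metres).
#' @return a validated config list.
#' @export
population_config <- function(n_individuals = 100, n_trees = 20,
                              chamber_size_probs = c(0.35, 0.40, 0.15, 0.10),
                              max_tree_size = 20, sex_ratio = 0.5,
                              prop_unknown_sex = 0.05,
                              age_meanlog = log(900), age_sdlog = 0.7,
                              prop_unassigned = 0.10, area_m = 1000) {
  cfg <- as.list(environment())
  if (n_individuals < 1) stop("n_individuals must be >= 1")
  if (n_trees < 1) stop("n_trees must be >= 1")
  if (length(chamber_size_probs) != 4 || any(chamber_size_probs < 0) ||
      sum(chamber_size_probs) <= 0)
    stop("chamber_size_probs must be 4 non-negative weights")
  n_assigned <- round((1 - prop_unassigned) * n_individuals)
  if (n_assigned > n_trees * max_tree_size)
    stop("infeasible config: ", n_assigned, " nesting individuals exceed ",
         "capacity of ", n_trees, " trees x ", max_tree_size)
  cfg
}

#' Simulate a population with nest assignments
#'
#' Draws individuals (id, sex, age) and assigns most of them to nest
#' chambers of 1-4 birds, packed into trees of at most `max_tree_size`
#' individuals placed uniformly in the study area. Entries of the same tree
#' share the tree location up to a metre-scale jitter. Deterministic for a
#' fixed seed.
#'
#' @param config a [population_config()].
#' @param seed integer seed.
#' @return list with `individuals` (id, sex, age, tree_id, entry_id) and
#'   `nest_sites` (tree_id, nest_id, entry_id, x, y).
#' @export
simulate_population <- function(config = population_config(), seed = 1L) {
  with_seed(seed, {
    n <- config$n_individuals
    ids <- sprintf("ind%03d", seq_len(n))
    sex <- sample(c("F", "M"), n, replace = TRUE,
                  prob = c(config$sex_ratio, 1 - config$sex_ratio))
    unk <- stats::runif(n) < config$prop_unknown_sex
    sex[unk] <- "unknown"
    age <- round(stats::rlnorm(n, config$age_meanlog, config$age_sdlog))
    n_assigned <- round((1 - config$prop_unassigned) * n)
    tree_id <- rep(NA_character_, n)
    entry_id <- rep(NA_character_, n)
    nest_sites <- data.frame(tree_id = character(), nest_id = character(),
                             entry_id = character(), x = numeric(),
                             y = numeric(), stringsAsFactors = FALSE)
    if (n_assigned > 0) {
      # chamber sizes 1..4 until the assigned pool is filled
      sizes <- integer()
      while (sum(sizes) < n_assigned) {
        sizes <- c(sizes, sample(1:4, 1, prob = config$chamber_size_probs))
      }
      over <- sum(sizes) - n_assigned
      if (over > 0) sizes[length(sizes)] <- sizes[length(sizes)] - over
      sizes <- sizes[sizes > 0]
      # pack chambers into trees respecting the per-tree cap
      capacity <- rep(config$max_tree_size, config$n_trees)
      tree_of_chamber <- integer(length(sizes))
      for (k in seq_along(sizes)) {
        ok <- which(capacity >= sizes[k])
        if (!length(ok)) stop("infeasible config: tree capacity exhausted")
        pick <- if (length(ok) == 1) ok else sample(ok, 1)
        tree_of_chamber[k] <- pick
        capacity[pick] <- capacity[pick] - sizes[k]
      }
      tx <- stats::runif(config$n_trees, 0, config$area_m)
      ty <- stats::runif(config$n_trees, 0, config$area_m)
      assigned <- sample(seq_len(n), n_assigned)
      pos <- 1L
      for (k in seq_along(sizes)) {
        members <- assigned[pos:(pos + sizes[k] - 1)]
        pos <- pos + sizes[k]
        tid <- sprintf("tree%02d", tree_of_chamber[k])
        eid <- sprintf("%s_e%02d", tid, sum(tree_of_chamber[seq_len(k)] ==
                                              tree_of_chamber[k]))
        tree_id[members] <- tid
        entry_id[members] <- eid
        nest_sites <- rbind(nest_sites, data.frame(
          tree_id = tid, nest_id = sub("_e", "_n", eid), entry_id = eid,
          x = tx[tree_of_chamber[k]] + stats::rnorm(1, 0, 1),
          y = ty[tree_of_chamber[k]] + stats::rnorm(1, 0, 1),
          stringsAsFactors = FALSE))
      }
    }
    list(individuals = data.frame(id = ids, sex = sex, age = age,
                                  tree_id = tree_id, entry_id = entry_id,
                                  stringsAsFactors = FALSE),
         nest_sites = nest_sites)
  })
}

#' Configuration for social-observation simulation
#'
#' Session-structured observations: in each survey session a subset of the
#' population is encountered foraging, partitioned into groups; typed
#' interactions (allopreen, tolerance, aggression) are drawn on top.
#' Allopreening is concentrated within shared nest entries (mated pairs).
#'
#' @param n_sessions number of survey sessions.
#' @param p_present probability an individual is encountered in a session.
#' @param mean_group_size mean foraging-group size.
#' @param rate_allopreen,rate_tolerance,rate_aggression expected events per
#'   session for each interaction type.
#' @param mate_fidelity probability an allopreen event is between entry
#'   mates rather than a random pair.
#' @return a config list.
#' @export
observation_config <- function(n_sessions = 30, p_present = 0.4,
                               mean_group_size = 5, rate_allopreen = 3,
                               rate_tolerance = 4, rate_aggression = 2,
                               mate_fidelity = 0.95) {
  if (n_sessions < 0) stop("n_sessions must be >= 0")
  as.list(environment())
}

#' Simulate foraging sightings and dyadic interactions
#'
#' @param individuals individuals table from [simulate_population()].
#' @param config an [observation_config()].
#' @param seed integer seed.
#' @return list with `sightings` (session, group, individual_id) and
#'   `interactions` (session, type, id_a, id_b).
#' @export
simulate_social_observations <- function(individuals,
                                         config = observation_config(),
                                         seed = 1L) {
  empty_s <- data.frame(session = character(), group = character(),
                        individual_id = character(), stringsAsFactors = FALSE)
  empty_i <- data.frame(session = character(), type = character(),
                        id_a = character(), id_b = character(),
                        stringsAsFactors = FALSE)
  if (config$n_sessions == 0) {
    warning("zero sessions configured: returning empty observation tables")
    return(list(sightings = empty_s, interactions = empty_i))
  }
  with_seed(seed, {
    ids <- individuals$id
    entries <- split(individuals$id, individuals$entry_id)
    entries <- entries[vapply(entries, length, 0L) >= 2]
    sightings <- list()
    interactions <- list()
    for (s in seq_len(config$n_sessions)) {
      ses <- sprintf("s%03d", s)
      present <- ids[stats::runif(length(ids)) < config$p_present]
      if (length(present) >= 1) {
        present <- sample(present)
        gsize <- pmax(1, stats::rpois(length(present),
                                      config$mean_group_size - 1) + 1)
        grp <- rep(seq_along(gsize), gsize)[seq_along(present)]
        sightings[[s]] <- data.frame(session = ses,
                                     group = sprintf("%s_g%02d", ses, grp),
                                     individual_id = present,
                                     stringsAsFactors = FALSE)
      }
      draw_pairs <- function(n, type) {
        if (n == 0) return(NULL)
        out <- vector("list", n)
        for (k in seq_len(n)) {
          if (type == "allopreen" && length(entries) &&
              stats::runif(1) < config$mate_fidelity) {
            e <- entries[[sample(length(entries), 1)]]
            pr <- sample(e, 2)
          } else {
            if (length(ids) < 2) return(NULL)
            pr <- sample(ids, 2)
          }
          out[[k]] <- data.frame(session = ses, type = type, id_a = pr[1],
                                 id_b = pr[2], stringsAsFactors = FALSE)
        }
        do.call(rbind, out)
      }
      interactions[[length(interactions) + 1]] <- rbind(
        draw_pairs(stats::rpois(1, config$rate_allopreen), "allopreen"),
        draw_pairs(stats::rpois(1, config$rate_tolerance), "tolerance"),
        draw_pairs(stats::rpois(1, config$rate_aggression), "aggression"))
    }
    sightings <- do.call(rbind, sightings)
    interactions <- do.call(rbind, interactions)
    list(sightings = if (is.null(sightings)) empty_s else sightings,
         interactions = if (is.null(interactions)) empty_i else interactions)
  })
}

#' Simulate a pairwise relatedness matrix
#'
#' Unrelated pairs get small beta-distributed values (mean
#' `unrelated_mean`); designated kin pairs (e.g. parent-offspring or full
#' siblings) are centred on 0.5 with modest noise. The matrix is symmetric
#' with `NA` on the diagonal and all values in \[0, 1\].
#'
#' @param individuals individuals table.
#' @param seed integer seed.
#' @param kin_pairs optional data.frame with `id_a`, `id_b` and optional
#'   `r` (expected relatedness, default 0.5).
#' @param unrelated_mean mean relatedness among non-kin.
#' @param kin_sd noise SD around the kin expectation.
#' @return a symmetric numeric matrix with individual ids as dimnames.
#' @export
simulate_relatedness <- function(individuals, seed = 1L, kin_pairs = NULL,
                                 unrelated_mean = 0.02, kin_sd = 0.04) {
  with_seed(seed, {
    ids <- individuals$id
    n <- length(ids)
    m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
    if (n >= 2) {
      idx <- which(upper.tri(m), arr.ind = TRUE)
      shape1 <- 0.5
      shape2 <- shape1 * (1 - unrelated_mean) / unrelated_mean
      vals <- stats::rbeta(nrow(idx), shape1, shape2)
      m[idx] <- vals
      if (!is.null(kin_pairs) && nrow(kin_pairs)) {
        r <- kin_pairs$r %||% rep(0.5, nrow(kin_pairs))
        for (k in seq_len(nrow(kin_pairs))) {
          i <- match(kin_pairs$id_a[k], ids)
          j <- match(kin_pairs$id_b[k], ids)
          if (is.na(i) || is.na(j)) stop("kin pair references unknown id")
          m[min(i, j), max(i, j)] <- min(1, max(0, stats::rnorm(1, r[k], kin_sd)))
        }
      }
      m[lower.tri(m)] <- t(m)[lower.tri(m)]
    }
    diag(m) <- NA_real_
    m
  })
}

#' Configuration for synthetic call data
#'
#' The call-type counts follow the Dirichlet-multinomial composition model
#' used in the analysis: each individual's expected proportions are a
#' softmax of per-type log-abundances `log(alpha) + beta * covariate +
#' delta_sex * female`, individual realised proportions are drawn from a
#' Dirichlet with concentration `proportions * theta`, and observed types
#' are multinomial. Acoustically, each individual has a centroid in a
#' low-dimensional latent embedding space; each call's embedding scatters
#' around it and parameterises a smooth F0 contour (sum of sinusoids), so
#' DTW distances between contours increase with embedding distance.
#'
#' @param mean_calls mean calls per individual (negative binomial,
#'   dispersion `calls_size`; counts range from 1 to a couple of hundred,
#'   as in field recordings).
#' @param calls_size negative-binomial size parameter.
#' @param calls_per_recording calls grouped into recordings of about this
#'   size.
#' @param alpha baseline call-type simplex (length 11; default
#'   contact-dominated).
#' @param beta per-type effect of the standardised continuous covariate
#'   (age) on log-abundance; centred to sum to zero for identifiability.
#' @param delta_sex per-type additive female effect on log-abundance,
#'   centred likewise.
#' @param theta Dirichlet concentration controlling how far individuals
#'   stray from their expected proportions (larger = less variable).
#' @param embedding_dim latent acoustic dimensions.
#' @param between_sd SD of individual centroids.
#' @param within_sd SD of call embeddings around the centroid.
#' @param within_sd_slope multiplicative log-scale effect of the covariate
#'   on the within-individual spread (drives true diversity differences).
#' @param dyad_effect optional list(`layer` = a [network_layer()], `effect`
#'   = numeric): centroids of connected dyads are pushed apart (positive
#'   effect) or pulled together (negative) along their difference vector.
#' @param base_hz,amp_hz,dur_s,step_s F0 contour parameters.
#' @return a config list.
#' @export
call_config <- function(mean_calls = 20, calls_size = 2,
                        calls_per_recording = 5,
                        alpha = NULL, beta = NULL, delta_sex = NULL,
                        theta = 10,
                        embedding_dim = 3, between_sd = 1, within_sd = 0.4,
                        within_sd_slope = 0, dyad_effect = NULL,
                        base_hz = 2000, amp_hz = 150, dur_s = 0.3,
                        step_s = 0.005) {
  k <- length(call_type_labels())
  if (is.null(alpha)) {
    alpha <- c(5, rep(0.5, k - 1))
    alpha <- alpha / sum(alpha)
  }
  if (abs(sum(alpha) - 1) > 1e-8 || any(alpha < 0))
    stop("alpha must be a simplex over the ", k, " call types")
  if (length(alpha) != k) stop("alpha must have length ", k)
  if (is.null(beta)) beta <- rep(0, k)
  if (is.null(delta_sex)) delta_sex <- rep(0, k)
  stopifnot(length(beta) == k, length(delta_sex) == k, theta > 0)
  beta <- beta - mean(beta)
  delta_sex <- delta_sex - mean(delta_sex)
  as.list(environment())[setdiff(ls(), "k")]
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

rdirichlet1 <- function(shape) {
  g <- stats::rgamma(length(shape), shape = shape, rate = 1)
  if (sum(g) == 0) g[which.max(shape)] <- 1
  g / sum(g)
}

#' Simulate classified calls with F0 traces
#'
#' @param individuals individuals table (uses `age`, `sex`).
#' @param config a [call_config()].
#' @param seed integer seed.
#' @return list with `calls` (data.frame: call_id, individual_id,
#'   recording_id, call_type, plus list-column `f0`) and `truth`
#'   (a [ground_truth()] with alpha, beta, delta_sex, theta, per-individual
#'   expected proportions and acoustic centroids).
#' @export
simulate_calls <- function(individuals, config = call_config(), seed = 1L) {
  with_seed(seed, {
    labels <- call_type_labels()
    k <- length(labels)
    n <- nrow(individuals)
    z_age <- as.numeric(scale(log(pmax(individuals$age, 1))))
    if (any(!is.finite(z_age))) z_age[] <- 0   # constant ages
    female <- as.integer(individuals$sex == "F")
    pi_ind <- t(vapply(seq_len(n), function(i) {
      softmax(log(config$alpha) + config$beta * z_age[i] +
                config$delta_sex * female[i])
    }, numeric(k)))
    n_calls <- stats::rnbinom(n, size = config$calls_size,
                              mu = config$mean_calls) + 1L
    # acoustic centroids, optionally displaced along network edges
    centroids <- matrix(stats::rnorm(n * config$embedding_dim, 0,
                                     config$between_sd),
                        n, config$embedding_dim,
                        dimnames = list(individuals$id, NULL))
    if (!is.null(config$dyad_effect)) {
      eff <- config$dyad_effect$effect
      edges <- config$dyad_effect$layer$edges
      shift <- centroids * 0
      for (r in seq_len(nrow(edges))) {
        i <- match(edges$id_i[r], individuals$id)
        j <- match(edges$id_j[r], individuals$id)
        if (is.na(i) || is.na(j)) next
        d <- centroids[i, ] - centroids[j, ]
        nm <- sqrt(sum(d^2))
        if (nm < 1e-9) next
        u <- d / nm * eff * edges$weight[r] / 2
        shift[i, ] <- shift[i, ] + u
        shift[j, ] <- shift[j, ] - u
      }
      centroids <- centroids + shift
    }
    within_sd_i <- config$within_sd * exp(config$within_sd_slope * z_age)
    freqs <- (seq_len(config$embedding_dim) * 2 + 1) / config$dur_s
    phases <- (seq_len(config$embedding_dim) - 1) * pi / 3
    tgrid <- seq(0, config$dur_s, by = config$step_s)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      m <- n_calls[i]
      p_i <- rdirichlet1(pi_ind[i, ] * config$theta)
      types <- sample(labels, m, replace = TRUE, prob = p_i)
      rec <- sprintf("%s_r%02d", individuals$id[i],
                     ceiling(seq_len(m) / config$calls_per_recording))
      f0 <- vector("list", m)
      for (cidx in seq_len(m)) {
        e <- centroids[i, ] + stats::rnorm(config$embedding_dim, 0,
                                           within_sd_i[i])
        f0[[cidx]] <- config$base_hz + config$amp_hz *
          colSums(e * sin(outer(freqs, tgrid) * 2 * pi + phases))
      }
      df <- data.frame(call_id = sprintf("%s_c%03d", individuals$id[i],
                                         seq_len(m)),
                       individual_id = individuals$id[i],
                       recording_id = rec, call_type = types,
                       stringsAsFactors = FALSE)
      df$f0 <- f0
      rows[[i]] <- df
    }
    calls <- do.call(rbind, rows)
    rownames(calls) <- NULL
    truth <- ground_truth(seed, alpha = config$alpha, beta = config$beta,
                          delta_sex = config$delta_sex, theta = config$theta,
                          within_sd = config$within_sd,
                          within_sd_slope = config$within_sd_slope,
                          between_sd = config$between_sd,
                          pi_ind = pi_ind, centroids = centroids,
                          n_calls = n_calls)
    list(calls = calls, truth = truth)
  })
}

#' Simulate observations directly from the dyadic distance model
#'
#' Draws acoustic-distance observations from the hierarchical model the
#' dyadic fit assumes (dyad offsets, per-recording offsets entering once
#' per recording on each side, residual noise). Used for parameter-recovery
#' and calibration testing of [fit_dyadic_model()].
#'
#' @param n_dyads number of dyads.
#' @param obs_per_dyad observations per dyad.
#' @param n_recordings number of recordings shared across observations.
#' @param truth list with `abar`, `sigma_dyad`, `sigma_rec`, `sigma`.
#' @param seed integer seed.
#' @return list with `observations` (distance-table schema) and `truth`
#'   (a [ground_truth()] including the drawn `alpha_dyad` vector).
#' @export
simulate_dyadic_distances <- function(n_dyads = 150, obs_per_dyad = 8,
                                      n_recordings = 60,
                                      truth = list(abar = 0, sigma_dyad = 0.4,
                                                   sigma_rec = 0.1,
                                                   sigma = 0.2),
                                      seed = 1L) {
  with_seed(seed, {
    a_dyad <- stats::rnorm(n_dyads, truth$abar, truth$sigma_dyad)
    a_rec <- stats::rnorm(n_recordings, 0, truth$sigma_rec)
    N <- n_dyads * obs_per_dyad
    dyad <- rep(seq_len(n_dyads), each = obs_per_dyad)
    r1 <- sample(n_recordings, N, replace = TRUE)
    r2 <- sample(n_recordings, N, replace = TRUE)
    y <- stats::rnorm(N, a_dyad[dyad] + a_rec[r1] + a_rec[r2], truth$sigma)
    obs <- data.frame(call_i = sprintf("c%05d_a", seq_len(N)),
                      call_j = sprintf("c%05d_b", seq_len(N)),
                      distance = y,
                      dyad_id = sprintf("dyad%04d", dyad),
                      id_i = sprintf("indA%04d", dyad),
                      id_j = sprintf("indB%04d", dyad),
                      rec_i = sprintf("rec%03d", r1),
                      rec_j = sprintf("rec%03d", r2),
                      same_recording = FALSE, stringsAsFactors = FALSE)
    tr <- ground_truth(seed, abar = truth$abar, sigma_dyad = truth$sigma_dyad,
                       sigma_rec = truth$sigma_rec, sigma = truth$sigma,
                       alpha_dyad = stats::setNames(a_dyad,
                                                    unique(obs$dyad_id)))
    list(observations = obs, truth = tr)
  })
}

#' Simulate observations directly from the within-individual model
#'
#' Generates all pairwise distances among each individual's calls from the
#' hierarchical model the diversity fit assumes: individual offsets,
#' a same-recording offset, recording-pair offsets and per-call offsets.
#' Used for recovery/calibration testing of [fit_within_model()].
#'
#' @param n_individuals number of individuals.
#' @param calls_per_individual calls per individual.
#' @param recordings_per_individual recordings each individual's calls are
#'   spread over.
#' @param truth list with `abar`, `sigma_ind`, `alpha_same_rec`,
#'   `sigma_rec_pair`, `sigma_call`, `sigma`.
#' @param seed integer seed.
#' @return list with `observations` and `truth` (including per-individual
#'   `alpha_ind`).
#' @export
simulate_within_distances <- function(n_individuals = 60,
                                      calls_per_individual = 15,
                                      recordings_per_individual = 3,
                                      truth = list(abar = 0.5,
                                                   sigma_ind = 0.1,
                                                   alpha_same_rec = -0.05,
                                                   sigma_rec_pair = 0.05,
                                                   sigma_call = 0.1,
                                                   sigma = 0.1),
                                      seed = 1L) {
  with_seed(seed, {
    ids <- sprintf("ind%03d", seq_len(n_individuals))
    a_ind <- stats::rnorm(n_individuals, truth$abar, truth$sigma_ind)
    rows <- vector("list", n_individuals)
    for (i in seq_len(n_individuals)) {
      m <- calls_per_individual
      call_id <- sprintf("%s_c%03d", ids[i], seq_len(m))
      rec <- sprintf("%s_r%02d", ids[i],
                     ceiling(seq_len(m) * recordings_per_individual / m))
      a_call <- stats::rnorm(m, 0, truth$sigma_call)
      idx <- t(utils::combn(m, 2))
      rp_key <- paste(pmin(rec[idx[, 1]], rec[idx[, 2]]),
                      pmax(rec[idx[, 1]], rec[idx[, 2]]))
      rp <- factor(rp_key)
      a_rp <- stats::rnorm(nlevels(rp), 0, truth$sigma_rec_pair)
      same <- rec[idx[, 1]] == rec[idx[, 2]]
      y <- stats::rnorm(nrow(idx),
                        a_ind[i] + truth$alpha_same_rec * same +
                          a_rp[as.integer(rp)] +
                          a_call[idx[, 1]] + a_call[idx[, 2]],
                        truth$sigma)
      rows[[i]] <- data.frame(call_i = call_id[idx[, 1]],
                              call_j = call_id[idx[, 2]],
                              distance = y,
                              dyad_id = unordered_pair_id(ids[i], ids[i]),
                              id_i = ids[i], id_j = ids[i],
                              rec_i = rec[idx[, 1]], rec_j = rec[idx[, 2]],
                              same_recording = same, stringsAsFactors = FALSE)
    }
    obs <- do.call(rbind, rows)
    rownames(obs) <- NULL
    tr <- ground_truth(seed, abar = truth$abar, sigma_ind = truth$sigma_ind,
                       alpha_same_rec = truth$alpha_same_rec,
                       sigma_rec_pair = truth$sigma_rec_pair,
                       sigma_call = truth$sigma_call, sigma = truth$sigma,
                       alpha_ind = stats::setNames(a_ind, ids))
    list(observations = obs, truth = tr)
  })
}

#' Simulate measured outcomes for second-stage regression testing
#'
#' Generates a latent outcome per unit from a linear model, then observes
#' it with known per-unit measurement error (`est_sd`), mimicking the
#' export of posterior means and SDs from the first-stage fits.
#'
#' @param n number of units.
#' @param slope true slope on the single standardised predictor `x`.
#' @param intercept true intercept.
#' @param sigma_resid residual SD of the latent outcome.
#' @param est_sd measurement SD(s); scalar or length-n vector.
#' @param seed integer seed.
#' @return list with `outcomes` (unit_id, est_mean, est_sd), `predictors`
#'   (unit_id, x) and `truth`.
#' @export
simulate_measured_outcomes <- function(n = 80, slope = 0.5, intercept = 0,
                                       sigma_resid = 0.3, est_sd = 0.1,
                                       seed = 1L) {
  with_seed(seed, {
    unit_id <- sprintf("u%03d", seq_len(n))
    x <- as.numeric(scale(stats::rnorm(n)))
    est_sd <- rep(est_sd, length.out = n)
    latent <- intercept + slope * x + stats::rnorm(n, 0, sigma_resid)
    est_mean <- stats::rnorm(n, latent, est_sd)
    list(outcomes = data.frame(unit_id = unit_id, est_mean = est_mean,
                               est_sd = est_sd, stringsAsFactors = FALSE),
         predictors = data.frame(unit_id = unit_id, x = x,
                                 stringsAsFactors = FALSE),
         truth = ground_truth(seed, slope = slope, intercept = intercept,
                              sigma_resid = sigma_resid, latent = latent))
  })
}

#' Simulate dyadic measured outcomes with multi-membership structure
#'
#' Like [simulate_measured_outcomes()] but for dyads: the latent outcome of
#' a dyad includes varying intercepts for both member individuals, and the
#' single predictor is a binary edge indicator (e.g. a tolerance edge).
#'
#' @param n_individuals number of individuals dyads are drawn from.
#' @param n_dyads number of dyads.
#' @param slope true effect of the edge on the latent outcome.
#' @param p_edge probability a dyad carries the edge.
#' @param sigma_id SD of individual varying intercepts.
#' @inheritParams simulate_measured_outcomes
#' @return list with `outcomes` (dyad_id, id_i, id_j, est_mean, est_sd),
#'   `predictors` (dyad_id, x) and `truth`.
#' @export
simulate_dyadic_outcomes <- function(n_individuals = 40, n_dyads = 300,
                                     slope = 0.3, p_edge = 0.3,
                                     intercept = 0, sigma_id = 0.15,
                                     sigma_resid = 0.2, est_sd = 0.1,
                                     seed = 1L) {
  with_seed(seed, {
    ids <- sprintf("ind%03d", seq_len(n_individuals))
    all_pairs <- t(utils::combn(n_individuals, 2))
    pick <- sample(nrow(all_pairs), min(n_dyads, nrow(all_pairs)))
    pairs <- all_pairs[pick, , drop = FALSE]
    u <- stats::rnorm(n_individuals, 0, sigma_id)
    x <- stats::rbinom(nrow(pairs), 1, p_edge)
    est_sd <- rep(est_sd, length.out = nrow(pairs))
    latent <- intercept + slope * x + u[pairs[, 1]] + u[pairs[, 2]] +
      stats::rnorm(nrow(pairs), 0, sigma_resid)
    est_mean <- stats::rnorm(nrow(pairs), latent, est_sd)
    list(outcomes = data.frame(
           dyad_id = unordered_pair_id(ids[pairs[, 1]], ids[pairs[, 2]]),
           id_i = ids[pairs[, 1]], id_j = ids[pairs[, 2]],
           est_mean = est_mean, est_sd = est_sd, stringsAsFactors = FALSE),
         predictors = data.frame(
           dyad_id = unordered_pair_id(ids[pairs[, 1]], ids[pairs[, 2]]),
           x = x, stringsAsFactors = FALSE),
         truth = ground_truth(seed, slope = slope, intercept = intercept,
                              sigma_id = sigma_id, sigma_resid = sigma_resid,
                              u = stats::setNames(u, ids)))
  })
}

#' Simulate per-call information-content counts
#'
#' Amplitude-modulation peak counts per call from a Poisson log-link model
#' with individual varying intercepts and a covariate effect on the
#' log-mean. Used for recovery testing of [fit_information_model()].
#'
#' @param n_individuals number of individuals.
#' @param calls_per_individual calls per individual.
#' @param log_mean baseline log-mean count.
#' @param slope covariate effect on the log-mean.
#' @param sigma_ind SD of individual intercepts on the log scale.
#' @param seed integer seed.
#' @return list with `counts` (call_id, individual_id, count), `predictors`
#'   (id, x) and `truth`.
#' @export
simulate_peak_counts <- function(n_individuals = 50, calls_per_individual = 10,
                                 log_mean = log(4), slope = 0.4,
                                 sigma_ind = 0.2, seed = 1L) {
  with_seed(seed, {
    ids <- sprintf("ind%03d", seq_len(n_individuals))
    x <- as.numeric(scale(stats::rnorm(n_individuals)))
    u <- stats::rnorm(n_individuals, 0, sigma_ind)
    rows <- lapply(seq_len(n_individuals), function(i) {
      lam <- exp(log_mean + slope * x[i] + u[i])
      data.frame(call_id = sprintf("%s_c%03d", ids[i],
                                   seq_len(calls_per_individual)),
                 individual_id = ids[i],
                 count = stats::rpois(calls_per_individual, lam),
                 stringsAsFactors = FALSE)
    })
    list(counts = do.call(rbind, rows),
         predictors = data.frame(id = ids, x = x, stringsAsFactors = FALSE),
         truth = ground_truth(seed, log_mean = log_mean, slope = slope,
                              sigma_ind = sigma_ind,
                              u = stats::setNames(u, ids)))
  })
}

#' Write the synthetic input tables as delimited text
#'
#' Writes the six input tables (individuals, nest sites, sightings,
#' interactions, call metadata, relatedness) as tab-separated files, F0
#' traces as one file per recording (columns call_id, time_s, f0_hz) under
#' `traces/`, and the ground truth as JSON.
#'
#' @param sim list with elements `individuals`, `nest_sites`, `sightings`,
#'   `interactions`, `calls`, `relatedness` and optionally `truth`.
#' @param dir output directory (created if missing).
#' @param step_s sampling step of the traces (for the time column).
#' @return `dir`, invisibly.
#' @export
write_input_tables <- function(sim, dir, step_s = 0.005) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  wt(sim$individuals, "individuals.tsv")
  wt(sim$nest_sites, "nest_sites.tsv")
  wt(sim$sightings, "sightings.tsv")
  wt(sim$interactions, "interactions.tsv")
  calls_meta <- sim$calls[setdiff(names(sim$calls), "f0")]
  wt(calls_meta, "calls.tsv")
  if (!is.null(sim$relatedness)) {
    utils::write.table(sim$relatedness, file.path(dir, "relatedness.tsv"),
                       sep = "\t", quote = FALSE, na = "")
  }
  if ("f0" %in% names(sim$calls)) {
    tdir <- file.path(dir, "traces")
    dir.create(tdir, showWarnings = FALSE)
    for (rec in unique(sim$calls$recording_id)) {
      rows <- which(sim$calls$recording_id == rec)
      tr <- do.call(rbind, lapply(rows, function(r) {
        f0 <- sim$calls$f0[[r]]
        data.frame(call_id = sim$calls$call_id[r],
                   time_s = (seq_along(f0) - 1) * step_s, f0_hz = f0)
      }))
      utils::write.table(tr, file.path(tdir, paste0(rec, ".tsv")), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    }
  }
  if (!is.null(sim$truth)) {
    jsonlite::write_json(unclass(sim$truth),
                         file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  invisible(dir)
}

#' Read calls and traces back from an input directory
#'
#' @param dir directory written by [write_input_tables()].
#' @return calls data.frame with the `f0` list-column restored.
#' @export
read_calls <- function(dir) {
  calls <- utils::read.table(file.path(dir, "calls.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
  tdir <- file.path(dir, "traces")
  calls$f0 <- vector("list", nrow(calls))
  for (rec in unique(calls$recording_id)) {
    f <- file.path(tdir, paste0(rec, ".tsv"))
    if (!file.exists(f))
      stop("missing trace file for recording: ", rec)
    tr <- utils::read.table(f, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    for (cid in unique(tr$call_id)) {
      calls$f0[[which(calls$call_id == cid)]] <- tr$f0_hz[tr$call_id == cid]
    }
  }
  calls
}
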