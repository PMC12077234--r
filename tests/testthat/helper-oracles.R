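# Independent oracles used across the suite. Each is a deliberately naive
# implementation (brute force, enumeration) kept separate from the package
# code paths it checks.

quick_config <- function(seed = 1L, chains = 2L, warmup = 300L,
                         samples = 300L) {
  sampler_config(chains = chains, warmup = warmup, samples = samples,
                 seed = seed)
}

# entropy by direct summation
entropy_oracle <- function(counts) {
  total <- sum(counts)
  h <- 0
  for (c in counts) {
    if (c > 0) {
      p <- c / total
      h <- h - p * log(p)
    }
  }
  h
}

# simple ratio index recounted from raw sightings, session by session
sri_oracle <- function(sightings, id_a, id_b) {
  x <- y_ab <- y_a <- y_b <- 0
  for (ses in unique(sightings$session)) {
    s <- sightings[sightings$session == ses, ]
    seen_a <- id_a %in% s$individual_id
    seen_b <- id_b %in% s$individual_id
    together <- FALSE
    if (seen_a && seen_b) {
      for (g in unique(s$group)) {
        mem <- s$individual_id[s$group == g]
        if (id_a %in% mem && id_b %in% mem) together <- TRUE
      }
    }
    if (together) x <- x + 1
    else if (seen_a && seen_b) y_ab <- y_ab + 1
    else if (seen_a) y_a <- y_a + 1
    else if (seen_b) y_b <- y_b + 1
  }
  if (x + y_ab + y_a + y_b == 0) return(NA_real_)
  x / (x + y_ab + y_a + y_b)
}

# betweenness by exhaustive shortest-path enumeration (graphs <= 8 nodes);
# adj is a symmetric 0/1 matrix
betweenness_oracle <- function(adj) {
  n <- nrow(adj)
  # all-pairs shortest path lengths (Floyd-Warshall)
  d <- ifelse(adj > 0, 1, Inf)
  diag(d) <- 0
  for (k in 1:n) for (i in 1:n) for (j in 1:n)
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  # enumerate all shortest paths s -> t by DFS along distance-decreasing steps
  paths_through <- function(s, t) {
    if (!is.finite(d[s, t]) || s == t) return(numeric(0))
    all_paths <- list()
    walk <- function(v, path) {
      if (v == t) {
        all_paths[[length(all_paths) + 1]] <<- path
        return()
      }
      for (w in which(adj[v, ] > 0)) {
        if (d[w, t] == d[v, t] - 1) walk(w, c(path, w))
      }
    }
    walk(s, s)
    all_paths
  }
  btw <- numeric(n)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    ps <- paths_through(s, t)
    if (!length(ps)) next
    for (v in setdiff(1:n, c(s, t))) {
      btw[v] <- btw[v] + sum(vapply(ps, function(p) v %in% p, TRUE)) /
        length(ps)
    }
  }
  btw
}

# DTW by exhaustive enumeration of all monotone warping paths (lengths <= 6):
# minimise (total cost, path length) lexicographically, return cost / length
dtw_oracle <- function(a, b) {
  n <- length(a); m <- length(b)
  best <- c(Inf, Inf)
  walk <- function(i, j, total, len) {
    total <- total + abs(a[i] - b[j])
    len <- len + 1
    if (i == n && j == m) {
      if (total < best[1] - 1e-12 ||
          (abs(total - best[1]) <= 1e-12 && len < best[2]))
        best <<- c(total, len)
      return()
    }
    if (i < n) walk(i + 1, j, total, len)
    if (j < m) walk(i, j + 1, total, len)
    if (i < n && j < m) walk(i + 1, j + 1, total, len)
  }
  walk(1, 1, 0, 0)
  best[1] / best[2]
}

# random binary layer over given nodes
random_layer <- function(nodes, p = 0.3, name = "layer") {
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < p
  if (!any(keep)) return(network_layer(name, nodes, NULL))
  network_layer(name, nodes,
                data.frame(id_i = pairs[keep, 1], id_j = pairs[keep, 2],
                           weight = rep(1, sum(keep)),
                           stringsAsFactors = FALSE))
}

# build a call table with given traces (list of numeric vectors)
make_calls <- function(traces, individual, recording = NULL,
                       type = "contact") {
  n <- length(traces)
  individual <- rep(individual, length.out = n)
  if (is.null(recording)) recording <- paste0(individual, "_r1")
  recording <- rep(recording, length.out = n)
  df <- data.frame(call_id = sprintf("c%03d_%s", seq_len(n),
                                     make.unique(individual)),
                   individual_id = individual, recording_id = recording,
                   call_type = rep(type, length.out = n),
                   stringsAsFactors = FALSE)
  df$f0 <- traces
  df
}
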