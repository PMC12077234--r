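test_that("simple ratio index matches hand counts and handles edge cases", {
  expect_equal(simple_ratio_index(5, 0, 0, 0), 1.0)
  expect_equal(simple_ratio_index(0, 3, 2, 1), 0.0)
  expect_equal(simple_ratio_index(2, 1, 1, 0), 0.5)
  expect_true(is.na(simple_ratio_index(0, 0, 0, 0)))
  expect_error(simple_ratio_index(-1, 0, 0, 0), "non-negative")
})

sightings_row <- function(session, group, ids) {
  data.frame(session = session, group = group, individual_id = ids,
             stringsAsFactors = FALSE)
}

test_that("foraging layer weights equal the simple ratio index", {
  # two individuals together in every one of 4 sessions -> edge 1
  s <- do.call(rbind, lapply(1:4, function(k)
    sightings_row(paste0("s", k), paste0("s", k, "_g1"), c("A", "B"))))
  f <- foraging_layer(s)
  expect_equal(edge_weight(f, "A", "B"), 1.0)
  # one joint session, one session each alone -> 1/3
  s <- rbind(sightings_row("s1", "s1_g1", c("A", "B")),
             sightings_row("s2", "s2_g1", "A"),
             sightings_row("s3", "s3_g1", "B"))
  f <- foraging_layer(s)
  expect_equal(edge_weight(f, "A", "B"), 1 / 3)
  # disjoint sighting sets -> no edge
  s <- rbind(sightings_row("s1", "s1_g1", "A"),
             sightings_row("s2", "s2_g1", "B"))
  f <- foraging_layer(s)
  expect_equal(nrow(f$edges), 0)
  # duplicated individual in a group deduplicates with a warning
  s <- sightings_row("s1", "s1_g1", c("A", "A", "B"))
  expect_warning(f <- foraging_layer(s), "deduplicated")
  expect_equal(edge_weight(f, "A", "B"), 1)
})

test_that("foraging weights equal a brute-force recount on random instances", {
  set.seed(42)
  for (rep in 1:5) {
    ids <- sprintf("i%02d", 1:12)
    rows <- list()
    for (ses in 1:8) {
      present <- ids[runif(12) < 0.5]
      if (!length(present)) next
      grp <- sample(1:3, length(present), replace = TRUE)
      rows[[ses]] <- sightings_row(paste0("s", ses),
                                   paste0("s", ses, "_g", grp), present)
    }
    s <- do.call(rbind, rows)
    f <- foraging_layer(s)
    for (k in 1:20) {
      pair <- sample(ids, 2)
      expected <- sri_oracle(s, pair[1], pair[2])
      got <- edge_weight(f, pair[1], pair[2])
      if (is.na(expected) || expected == 0) expect_equal(got, 0)
      else expect_equal(got, expected)
    }
  }
})

test_that("binary layers follow the interaction rules", {
  ind <- data.frame(id = c("A", "B", "C", "D"),
                    entry_id = c("e1", "e1", "e2", NA),
                    stringsAsFactors = FALSE)
  ev <- data.frame(session = "s1",
                   type = c("aggression", "allopreen"),
                   id_a = c("A", "C"), id_b = c("C", "D"),
                   stringsAsFactors = FALSE)
  # shared entry alone creates a mate edge; allopreening adds one
  mate <- binary_layer(ev, "mate", ind)
  expect_equal(edge_weight(mate, "A", "B"), 1)
  expect_equal(edge_weight(mate, "C", "D"), 1)
  expect_equal(edge_weight(mate, "A", "C"), 0)
  # one fight gives an undirected aggression edge
  agg <- binary_layer(ev, "aggression", ind)
  expect_equal(edge_weight(agg, "C", "A"), 1)
  expect_equal(edge_weight(agg, "A", "C"), 1)
  # no events -> empty affiliative edge set apart from allopreen
  aff <- binary_layer(ev[0, ], "affiliative", ind)
  expect_equal(nrow(aff$edges), 0)
  expect_error(binary_layer(ev, "bogus", ind))
})

test_that("nest distances are normalized euclidean tree distances", {
  ind <- data.frame(id = c("A", "B", "C", "D"),
                    entry_id = c("eA", "eB", "eC", "eA2"),
                    stringsAsFactors = FALSE)
  ns <- data.frame(tree_id = c("t1", "t2", "t3", "t1"),
                   nest_id = paste0("n", 1:4),
                   entry_id = c("eA", "eB", "eC", "eA2"),
                   x = c(0, 3, 6, 0), y = c(0, 4, 8, 0),
                   stringsAsFactors = FALSE)
  layer <- nest_distance_layer(ind, ns)
  # max distance is A--C = 10, so A--B (5) scores 0.5
  expect_equal(edge_weight(layer, "A", "C"), 1.0)
  expect_equal(edge_weight(layer, "A", "B"), 0.5)
  # same tree scores 0
  expect_equal(edge_weight(layer, "A", "D"), 0)
  # unassigned individuals are excluded with a message
  ind2 <- rbind(ind, data.frame(id = "E", entry_id = NA))
  expect_message(l2 <- nest_distance_layer(ind2, ns), "excluded")
  expect_false("E" %in% l2$nodes)
})

test_that("centralities match analytic small-graph values", {
  path <- network_layer("foraging", c("A", "B", "C"),
                        data.frame(id_i = c("A", "B"), id_j = c("B", "C"),
                                   weight = 1))
  cen <- centralities(path)
  expect_equal(cen$betweenness[cen$id == "B"], 1)
  expect_equal(cen$betweenness[cen$id == "A"], 0)
  # star with 5 leaves: centre lies on all C(5,2) leaf pairs
  star <- network_layer("foraging", c("hub", paste0("l", 1:5)),
                        data.frame(id_i = "hub", id_j = paste0("l", 1:5),
                                   weight = 1))
  cen <- centralities(star)
  expect_equal(cen$betweenness[cen$id == "hub"], 10)
  expect_equal(max(cen$eigenvector), 1)
  # complete graph: zero betweenness, equal eigenvector everywhere
  ids <- paste0("k", 1:5)
  pairs <- t(combn(ids, 2))
  comp <- network_layer("foraging", ids,
                        data.frame(id_i = pairs[, 1], id_j = pairs[, 2],
                                   weight = 1))
  cen <- centralities(comp)
  expect_true(all(cen$betweenness == 0))
  expect_equal(cen$eigenvector, rep(1, 5))
  # empty graph -> empty metrics
  expect_equal(nrow(centralities(network_layer("foraging", character(),
                                               NULL))), 0)
})

test_that("betweenness equals exhaustive shortest-path enumeration", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    adj <- matrix(0, n, n)
    pairs <- which(upper.tri(adj), arr.ind = TRUE)
    on <- runif(nrow(pairs)) < 0.4
    adj[pairs[on, , drop = FALSE]] <- 1
    adj <- adj + t(adj)
    ids <- sprintf("v%d", 1:n)
    edges <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
    layer <- network_layer("foraging", ids,
                           if (nrow(edges)) data.frame(
                             id_i = ids[edges[, 1]], id_j = ids[edges[, 2]],
                             weight = 1) else NULL)
    cen <- centralities(layer)
    expected <- betweenness_oracle(adj)
    expect_equal(cen$betweenness[match(ids, cen$id)], expected,
                 tolerance = 1e-10)
  }
})

test_that("degree versatility equals summed per-layer degrees", {
  set.seed(21)
  nodes <- sprintf("n%02d", 1:10)
  for (rep in 1:100) {
    layers <- lapply(1:4, function(k) random_layer(nodes, p = runif(1, 0.1, 0.5)))
    mp <- multiplex_network(layers[[1]], layers[[2]], layers[[3]], layers[[4]])
    v <- degree_versatility(mp)
    # independent per-layer degree count from the raw edge lists
    expected <- setNames(rep(0, length(nodes)), nodes)
    for (l in layers) {
      for (r in seq_len(nrow(l$edges))) {
        expected[l$edges$id_i[r]] <- expected[l$edges$id_i[r]] + 1
        expected[l$edges$id_j[r]] <- expected[l$edges$id_j[r]] + 1
      }
    }
    expect_equal(setNames(v$versatility, v$id), expected[v$id])
  }
  # one-layer multiplex: versatility equals degree; isolates are 0
  one <- random_layer(nodes, 0.3)
  empty <- network_layer("x", nodes, NULL)
  mp <- multiplex_network(one, empty, empty, empty)
  v <- degree_versatility(mp)
  cen <- centralities(one)
  expect_equal(setNames(v$versatility, v$id)[cen$id],
               setNames(cen$degree, cen$id))
  iso <- multiplex_network(empty, empty, empty, empty)
  expect_true(all(degree_versatility(iso)$versatility == 0))
})

test_that("group sizes count the focal individual and respect assignments", {
  ind <- data.frame(id = sprintf("i%d", 1:7),
                    tree_id = c(rep("t1", 6), NA),
                    entry_id = c(rep("e1", 4), rep("e2", 2), NA),
                    stringsAsFactors = FALSE)
  gs <- group_sizes(ind)
  expect_equal(gs$chamber_size[gs$id == "i1"], 4)
  expect_equal(gs$tree_size[gs$id == "i1"], 6)
  expect_equal(gs$chamber_size[gs$id == "i5"], 2)
  expect_true(is.na(gs$chamber_size[gs$id == "i7"]))
  # sole occupant
  solo <- group_sizes(data.frame(id = "x", tree_id = "t", entry_id = "e"))
  expect_equal(solo$chamber_size, 1)
  expect_equal(solo$tree_size, 1)
  # synthetic defaults never exceed the documented caps
  pop <- simulate_population(population_config(), seed = 31)
  g <- group_sizes(pop$individuals)
  expect_lte(max(g$chamber_size, na.rm = TRUE), 4)
  expect_lte(max(g$tree_size, na.rm = TRUE), 20)
})

test_that("network layers round-trip through edge-list files", {
  set.seed(5)
  l <- random_layer(sprintf("a%d", 1:6), 0.5, name = "foraging")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_layer(l, f)
  back <- read_layer(f, "foraging")
  expect_equal(back$edges, l$edges)
})
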