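#' Social network layers
#'
#' A network layer is a symmetric weighted graph over the individual
#' universe, stored as an edge list. Foraging and nest-distance layers carry
#' weights in \[0, 1\]; mate, affiliative and aggression layers are binary.
#'
#' @param name layer name.
#' @param nodes character vector of individual ids (the node universe; may
#'   include isolated nodes).
#' @param edges data.frame with columns `id_i`, `id_j`, `weight`; each
#'   unordered pair stored once, no self-edges.
#' @return an object of class `network_layer`.
#' @export
network_layer <- function(name, nodes, edges) {
  nodes <- unique(as.character(nodes))
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!nrow(edges)) {
    edges <- data.frame(id_i = character(), id_j = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("id_i", "id_j", "weight") %in% names(edges)))
    if (any(edges$id_i == edges$id_j)) stop("self-edges are not allowed")
    # canonical unordered storage
    a <- pmin(edges$id_i, edges$id_j)
    b <- pmax(edges$id_i, edges$id_j)
    edges$id_i <- a; edges$id_j <- b
    edges <- edges[!duplicated(paste(a, b)), , drop = FALSE]
    edges <- edges[order(edges$id_i, edges$id_j), , drop = FALSE]
    rownames(edges) <- NULL
    nodes <- unique(c(nodes, edges$id_i, edges$id_j))
  }
  structure(list(name = name, nodes = sort(nodes), edges = edges),
            class = "network_layer")
}

#' @export
print.network_layer <- function(x, ...) {
  cat(sprintf("<network_layer '%s': %d nodes, %d edges>\n",
              x$name, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Symmetric edge weight lookup
#'
#' @param layer a [network_layer()].
#' @param id_a,id_b individual ids (vectors recycle).
#' @param default weight returned for absent edges.
#' @return numeric vector of weights.
#' @export
edge_weight <- function(layer, id_a, id_b, default = 0) {
  key <- unordered_pair_id(as.character(id_a), as.character(id_b))
  stored <- unordered_pair_id(layer$edges$id_i, layer$edges$id_j)
  w <- layer$edges$weight[match(key, stored)]
  w[is.na(w)] <- default
  w
}

#' Simple ratio index
#'
#' Association weight between two individuals from co-sighting counts:
#' `x / (x + yAB + yA + yB)`, where `x` counts sampling periods with both
#' seen together, `yA`/`yB` periods with only one seen, and `yAB` periods
#' with both seen but apart. Ranges from 0 (never together) to 1 (always
#' together). When all four counts are zero the index is undefined and
#' `NA` is returned (never 0 — an unobserved dyad is not a never-associating
#' dyad).
#'
#' @param n_together,n_only_a,n_only_b,n_both_seen_apart non-negative
#'   counts (vectors recycle).
#' @return numeric vector in \[0, 1\] or `NA`.
#' @export
simple_ratio_index <- function(n_together, n_only_a, n_only_b,
                               n_both_seen_apart = 0) {
  args <- cbind(n_together, n_only_a, n_only_b, n_both_seen_apart)
  if (any(args < 0)) stop("counts must be non-negative")
  denom <- rowSums(args)
  out <- n_together / denom
  out[denom == 0] <- NA_real_
  unname(out)
}

#' Foraging-association layer from group sightings
#'
#' Gambit of the group: all members of an observed foraging group are taken
#' to associate pairwise. Co-sightings are deduplicated at the session
#' level (one joint sighting per session, however many groups it held), and
#' edges are weighted by the simple ratio index over sessions. Individuals
#' never co-sighted share no edge.
#'
#' @param sightings data.frame with columns `session`, `group`,
#'   `individual_id`; one row per individual per observed group.
#' @return a [network_layer()] named `"foraging"`.
#' @export
foraging_layer <- function(sightings) {
  stopifnot(all(c("session", "group", "individual_id") %in% names(sightings)))
  if (!nrow(sightings))
    return(network_layer("foraging", character(), NULL))
  dup <- duplicated(sightings[c("session", "group", "individual_id")])
  if (any(dup)) {
    warning(sum(dup), " duplicate individual-in-group rows deduplicated")
    sightings <- sightings[!dup, , drop = FALSE]
  }
  sightings$session <- as.character(sightings$session)
  ids <- sort(unique(sightings$individual_id))
  sessions <- split(sightings, sightings$session)
  # per session: set of individuals seen, and set of together-pairs
  seen <- lapply(sessions, function(s) unique(s$individual_id))
  together <- lapply(sessions, function(s) {
    pairs <- lapply(split(s$individual_id, s$group), function(g) {
      g <- unique(g)
      if (length(g) < 2) return(character())
      cmb <- utils::combn(sort(g), 2)
      paste(cmb[1, ], cmb[2, ], sep = "--")
    })
    unique(unlist(pairs))
  })
  x <- table(unlist(together))
  # sessions in which each individual was seen
  seen_count <- table(unlist(seen))
  # both-seen counts per pair
  both <- table(unlist(lapply(seen, function(g) {
    g <- sort(unique(g))
    if (length(g) < 2) return(character())
    cmb <- utils::combn(g, 2)
    paste(cmb[1, ], cmb[2, ], sep = "--")
  })))
  pair_ids <- names(both)
  if (!length(pair_ids))
    return(network_layer("foraging", ids, NULL))
  parts <- strsplit(pair_ids, "--", fixed = TRUE)
  a <- vapply(parts, `[`, "", 1)
  b <- vapply(parts, `[`, "", 2)
  x_ab <- as.numeric(x[pair_ids]); x_ab[is.na(x_ab)] <- 0
  n_both <- as.numeric(both)
  y_ab <- n_both - x_ab                    # both seen, never together
  y_a <- as.numeric(seen_count[a]) - n_both
  y_b <- as.numeric(seen_count[b]) - n_both
  w <- simple_ratio_index(x_ab, y_a, y_b, y_ab)
  keep <- !is.na(w) & w > 0
  network_layer("foraging", ids,
                data.frame(id_i = a[keep], id_j = b[keep], weight = w[keep],
                           stringsAsFactors = FALSE))
}

#' Binary interaction layers (mate, affiliative, aggression)
#'
#' Builds the three undirected binary layers from typed interaction events:
#' * `mate` — an edge between individuals sharing a nest entry (chamber),
#'   plus any pair with at least one allopreening event (allopreening
#'   occurs almost exclusively within mated pairs);
#' * `affiliative` — at least one close-tolerance or allopreening event;
#' * `aggression` — at least one displacement or fight, direction ignored.
#'
#' @param interactions data.frame with columns `type` (one of `mate`,
#'   `allopreen`, `tolerance`, `aggression`), `id_a`, `id_b`.
#' @param kind which layer to build.
#' @param individuals data.frame with `id` and `entry_id`; required for
#'   `kind = "mate"` (chamber co-membership).
#' @return a binary [network_layer()].
#' @export
binary_layer <- function(interactions,
                         kind = c("mate", "affiliative", "aggression"),
                         individuals = NULL) {
  kind <- match.arg(kind)
  stopifnot(all(c("type", "id_a", "id_b") %in% names(interactions)) ||
              nrow(interactions) == 0)
  pairs <- function(types) {
    ev <- interactions[interactions$type %in% types, , drop = FALSE]
    if (!nrow(ev)) return(character())
    unique(unordered_pair_id(ev$id_a, ev$id_b))
  }
  edge_pairs <- switch(kind,
    mate = {
      if (is.null(individuals))
        stop("mate layer needs the individuals table for entry assignments")
      ass <- individuals[!is.na(individuals$entry_id), , drop = FALSE]
      shared <- unlist(lapply(split(ass$id, ass$entry_id), function(g) {
        g <- sort(unique(g))
        if (length(g) < 2) return(character())
        cmb <- utils::combn(g, 2)
        paste(cmb[1, ], cmb[2, ], sep = "--")
      }), use.names = FALSE)
      unique(c(shared, pairs("allopreen")))
    },
    affiliative = pairs(c("tolerance", "allopreen")),
    aggression = pairs("aggression"))
  nodes <- if (!is.null(individuals)) individuals$id else character()
  if (!length(edge_pairs))
    return(network_layer(kind, nodes, NULL))
  parts <- strsplit(edge_pairs, "--", fixed = TRUE)
  network_layer(kind, nodes,
                data.frame(id_i = vapply(parts, `[`, "", 1),
                           id_j = vapply(parts, `[`, "", 2),
                           weight = 1, stringsAsFactors = FALSE))
}

#' Nest-distance layer
#'
#' Planar Euclidean distance between the nest entries individuals are
#' assigned to, normalised by the maximum observed distance so values span
#' \[0, 1\]. Two entries in the same tree score 0 (entries of one tree share
#' coordinates up to survey jitter; the distance is computed tree-to-tree).
#' Individuals without an entry assignment are excluded with a message.
#'
#' @param individuals data.frame with `id`, `entry_id`.
#' @param nest_sites data.frame with `tree_id`, `entry_id`, `x`, `y`.
#' @return a [network_layer()] named `"nest_distance"` over assigned
#'   individuals.
#' @export
nest_distance_layer <- function(individuals, nest_sites) {
  ass <- individuals[!is.na(individuals$entry_id), , drop = FALSE]
  dropped <- setdiff(individuals$id, ass$id)
  if (length(dropped))
    message(length(dropped), " individuals without nest assignment excluded ",
            "from the nest-distance layer")
  if (nrow(ass) < 2) return(network_layer("nest_distance", ass$id, NULL))
  m <- match(ass$entry_id, nest_sites$entry_id)
  if (anyNA(m)) stop("entry assignments not found in nest_sites: ",
                     paste(unique(ass$entry_id[is.na(m)]), collapse = ", "))
  tree <- nest_sites$tree_id[m]
  # tree-level coordinates: entries of a tree share a location (mean over
  # the small jitter)
  tx <- tapply(nest_sites$x, nest_sites$tree_id, mean)
  ty <- tapply(nest_sites$y, nest_sites$tree_id, mean)
  idx <- t(utils::combn(nrow(ass), 2))
  d <- sqrt((tx[tree[idx[, 1]]] - tx[tree[idx[, 2]]])^2 +
            (ty[tree[idx[, 1]]] - ty[tree[idx[, 2]]])^2)
  d[tree[idx[, 1]] == tree[idx[, 2]]] <- 0
  dmax <- max(d)
  w <- if (dmax > 0) d / dmax else d
  network_layer("nest_distance", ass$id,
                data.frame(id_i = ass$id[idx[, 1]], id_j = ass$id[idx[, 2]],
                           weight = unname(w), stringsAsFactors = FALSE))
}

as_igraph <- function(layer, binary = TRUE) {
  g <- igraph::graph_from_data_frame(
    layer$edges[layer$edges$weight > 0, c("id_i", "id_j", "weight")],
    directed = FALSE,
    vertices = data.frame(name = layer$nodes, stringsAsFactors = FALSE))
  if (!binary) igraph::E(g)$weight <- layer$edges$weight[layer$edges$weight > 0]
  g
}

#' Node centralities on a layer
#'
#' Unweighted degree, betweenness and eigenvector centrality on the
#' binarised layer (an edge is present where weight > 0). Betweenness is
#' the number of shortest paths between dyads on which the focal individual
#' lies (multiple shortest paths contribute fractionally). Eigenvector
#' centrality is the leading-eigenvector score computed per connected
#' component and normalised to a maximum of 1.
#'
#' @param layer a [network_layer()].
#' @return data.frame with columns `id`, `degree`, `betweenness`,
#'   `eigenvector`; empty for an empty graph.
#' @export
centralities <- function(layer) {
  if (!length(layer$nodes))
    return(data.frame(id = character(), degree = integer(),
                      betweenness = numeric(), eigenvector = numeric()))
  g <- as_igraph(layer)
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, weights = NA)
  comp <- igraph::components(g)$membership
  eig <- rep(0, length(comp))
  for (cc in unique(comp)) {
    sub <- igraph::induced_subgraph(g, which(comp == cc))
    # leading eigenvector via dense symmetric eigendecomposition: exact and
    # deterministic, unlike ARPACK's randomly started iteration
    a <- igraph::as_adjacency_matrix(sub, sparse = FALSE)
    if (nrow(a) == 1) {
      eig[comp == cc] <- 1
    } else {
      v <- abs(eigen(a, symmetric = TRUE)$vectors[, 1])
      eig[comp == cc] <- v / max(v)
    }
  }
  data.frame(id = igraph::V(g)$name, degree = unname(deg),
             betweenness = unname(btw), eigenvector = unname(eig),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Multiplex network over four layers
#'
#' Bundles the foraging, mate, aggression and affiliative layers over the
#' union of their node sets. The nest-distance layer is not part of the
#' multiplex (it largely duplicates the mate layer's information).
#'
#' @param foraging,mate,aggression,affiliative [network_layer()] objects.
#' @return an object of class `multiplex_network`.
#' @export
multiplex_network <- function(foraging, mate, aggression, affiliative) {
  layers <- list(foraging = foraging, mate = mate,
                 aggression = aggression, affiliative = affiliative)
  structure(list(layers = layers,
                 nodes = sort(unique(unlist(lapply(layers, `[[`, "nodes"))))),
            class = "multiplex_network")
}

#' @export
print.multiplex_network <- function(x, ...) {
  cat(sprintf("<multiplex_network: %d nodes, layers: %s>\n",
              length(x$nodes), paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' Degree versatility across multiplex layers
#'
#' The unweighted degree of each individual summed across the multiplex
#' layers; a node absent from a layer contributes 0 there. A measure of how
#' many conspecifics an individual has contact with across interaction
#' types.
#'
#' @param multiplex a [multiplex_network()].
#' @return data.frame with columns `id`, `versatility`.
#' @export
degree_versatility <- function(multiplex) {
  v <- stats::setNames(rep(0L, length(multiplex$nodes)), multiplex$nodes)
  for (layer in multiplex$layers) {
    e <- layer$edges[layer$edges$weight > 0, , drop = FALSE]
    if (!nrow(e)) next
    d <- table(c(e$id_i, e$id_j))
    v[names(d)] <- v[names(d)] + as.integer(d)
  }
  data.frame(id = names(v), versatility = unname(as.integer(v)),
             stringsAsFactors = FALSE)
}

#' Chamber and tree group sizes
#'
#' Number of individuals assigned to each individual's nest entry (chamber
#' group size) and nesting tree (tree group size), counting the focal
#' individual. Individuals without an assignment get `NA`, not 0.
#'
#' @param individuals data.frame with `id`, `tree_id`, `entry_id`.
#' @return data.frame with `id`, `chamber_size`, `tree_size`.
#' @export
group_sizes <- function(individuals) {
  ch <- table(individuals$entry_id[!is.na(individuals$entry_id)])
  tr <- table(individuals$tree_id[!is.na(individuals$tree_id)])
  data.frame(id = individuals$id,
             chamber_size = ifelse(is.na(individuals$entry_id), NA_integer_,
                                   as.integer(ch[individuals$entry_id])),
             tree_size = ifelse(is.na(individuals$tree_id), NA_integer_,
                                as.integer(tr[individuals$tree_id])),
             stringsAsFactors = FALSE)
}

#' Node metric table for the effect models
#'
#' Combines foraging-layer centralities, multiplex degree versatility and
#' nesting group sizes into the per-individual predictor table used by the
#' second-stage models.
#'
#' @param foraging foraging [network_layer()].
#' @param multiplex a [multiplex_network()].
#' @param individuals individuals table (for ids and nest assignments).
#' @return data.frame with one row per individual.
#' @export
node_metrics <- function(foraging, multiplex, individuals) {
  cen <- centralities(foraging)
  ver <- degree_versatility(multiplex)
  gs <- group_sizes(individuals)
  out <- data.frame(id = individuals$id, stringsAsFactors = FALSE)
  out <- merge(out, cen, by = "id", all.x = TRUE, sort = TRUE)
  out <- merge(out, ver, by = "id", all.x = TRUE, sort = TRUE)
  merge(out, gs, by = "id", all.x = TRUE, sort = TRUE)
}

#' Write / read a network layer as a delimited edge list
#'
#' @param layer a [network_layer()].
#' @param path file path (tab-separated: id_i, id_j, weight).
#' @export
write_layer <- function(layer, path) {
  utils::write.table(layer$edges, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @param name layer name for the object read back.
#' @rdname write_layer
#' @export
read_layer <- function(path, name) {
  edges <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE,
                             colClasses = c("character", "character", "numeric"))
  network_layer(name, unique(c(edges$id_i, edges$id_j)), edges)
}
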