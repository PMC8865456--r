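#' Mean connectivity strength within or between node sets
#'
#' With only `set_a`, the mean weight over all unordered pairs of nodes in
#' the set (diagonal excluded); with `set_b`, the mean weight over all pairs
#' with one node in each (disjoint) set — the between-network strength.
#'
#' @param m A `connectivity_matrix` or symmetric weight matrix.
#' @param set_a,set_b Node ids (character, matching the matrix dimnames) or
#'   integer indices. `set_a = NULL` uses all nodes.
#' @return Mean strength.
#' @export
mean_strength <- function(m, set_a = NULL, set_b = NULL) {
  w <- as_weights(m)
  a <- resolve_nodes(w, set_a)
  if (is.null(set_b)) {
    if (length(a) < 2L)
      stop("mean_strength: a single node has no within-set pairs", call. = FALSE)
    sub <- w[a, a, drop = FALSE]
    mean(sub[upper.tri(sub)])
  } else {
    b <- resolve_nodes(w, set_b)
    if (length(intersect(a, b)))
      stop("mean_strength: node sets must be disjoint", call. = FALSE)
    mean(w[a, b, drop = FALSE])
  }
}

resolve_nodes <- function(w, nodes) {
  if (is.null(nodes)) return(seq_len(nrow(w)))
  if (is.character(nodes)) {
    idx <- match(nodes, rownames(w))
    if (anyNA(idx)) stop("unknown node id(s): ",
                         paste(nodes[is.na(idx)], collapse = ", "), call. = FALSE)
    idx
  } else as.integer(nodes)
}

graph_of <- function(w) {
  if (any(w[upper.tri(w)] <= 0))
    stop("graph metrics require strictly positive weights", call. = FALSE)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  g
}

#' All-pairs shortest distances on edge lengths 1/weight
#'
#' Strong weights mean short functional distance: the weighted path metrics
#' operate on edge lengths `l_ij = 1 / w_ij` (Dijkstra from every node).
#'
#' @inheritParams mean_strength
#' @param nodes Optional node subset; distances are computed on the induced
#'   subgraph only.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
distance_matrix <- function(m, nodes = NULL) {
  w <- as_weights(m)
  idx <- resolve_nodes(w, nodes)
  w <- w[idx, idx, drop = FALSE]
  g <- graph_of(w)
  d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight,
                         algorithm = "dijkstra")
  d[rownames(w), rownames(w), drop = FALSE]
}

#' Nodal and network characteristic path length
#'
#' `nodal_path_length` is each node's mean shortest distance to all other
#' nodes; `characteristic_path_length` is the mean over all ordered pairs —
#' the network's integration measure (lower = more integrated). Subnetwork
#' scopes use the induced submatrix.
#'
#' @inheritParams distance_matrix
#' @export
characteristic_path_length <- function(m, nodes = NULL) {
  d <- distance_matrix(m, nodes)
  if (nrow(d) < 2L)
    stop("characteristic_path_length: need at least 2 nodes", call. = FALSE)
  mean(d[row(d) != col(d)])
}

#' @rdname characteristic_path_length
#' @export
nodal_path_length <- function(m, nodes = NULL) {
  d <- distance_matrix(m, nodes)
  if (nrow(d) < 2L)
    stop("nodal_path_length: need at least 2 nodes", call. = FALSE)
  rowSums(d) / (nrow(d) - 1L)
}

#' Weighted clustering coefficient (Onnela geometric-mean form)
#'
#' On max-normalized weights `wh = w / max(w)`, the clustering of node i is
#' `C_i = sum_{j != h} (wh_ij wh_ih wh_jh)^(1/3) / (k_i (k_i - 1))` with
#' `k_i` the number of neighbours; `C_i` lies in \[0, 1\] and equals 1 on an
#' equal-weight complete graph. A functional segregation measure.
#'
#' @inheritParams distance_matrix
#' @return List with `nodes` (named per-node coefficients) and `average`.
#' @export
weighted_clustering <- function(m, nodes = NULL) {
  w <- as_weights(m)
  idx <- resolve_nodes(w, nodes)
  w <- w[idx, idx, drop = FALSE]
  n <- nrow(w)
  if (n < 3L) stop("weighted_clustering: need at least 3 nodes", call. = FALSE)
  diag(w) <- 0
  wh <- w / max(w)
  wc <- wh^(1 / 3)
  tri <- diag(wc %*% wc %*% wc)  # 2 x sum of triangle intensities at i
  k <- rowSums(w > 0)
  ci <- ifelse(k > 1, tri / (k * (k - 1)), 0)
  names(ci) <- rownames(w)
  list(nodes = ci, average = mean(ci))
}

#' Weighted local efficiency
#'
#' For each node i, the efficiency of the subgraph induced by its
#' neighbours:
#' `E_i = sum_{j != h in N_i} (w_ij w_ih / d_jh(N_i))^(1/3) / (k_i (k_i - 1))`
#' where `d_jh(N_i)` are shortest distances within the neighbour subgraph on
#' lengths 1/w. Equals 1 on an equal-weight complete graph; a segregation
#' measure of local connectedness.
#'
#' @inheritParams distance_matrix
#' @return List with `nodes` (named per-node efficiencies) and `average`.
#' @export
local_efficiency <- function(m, nodes = NULL) {
  w <- as_weights(m)
  idx <- resolve_nodes(w, nodes)
  w <- w[idx, idx, drop = FALSE]
  n <- nrow(w)
  if (n < 3L) stop("local_efficiency: need at least 3 nodes", call. = FALSE)
  diag(w) <- 0
  eff <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    k <- length(nb)
    if (k < 2L) { eff[i] <- 0; next }
    wn <- w[nb, nb, drop = FALSE]
    d <- distance_matrix_pos(wn)
    inv_d <- 1 / d
    diag(inv_d) <- 0  # j == h terms excluded
    wi <- w[i, nb]
    s <- sum((outer(wi, wi) * inv_d)^(1 / 3))
    eff[i] <- s / (k * (k - 1))
  }
  names(eff) <- rownames(w)
  list(nodes = eff, average = mean(eff))
}

# distances tolerating absent edges (weight 0 = no edge)
distance_matrix_pos <- function(w) {
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::distances(g, weights = 1 / igraph::E(g)$weight,
                    algorithm = "dijkstra")
}

#' Weighted betweenness centrality
#'
#' Brandes betweenness on edge lengths 1/weight (endpoints excluded): the
#' number of shortest paths passing through each node, fractionally credited
#' when shortest paths tie.
#'
#' @inheritParams mean_strength
#' @return Named per-node betweenness values.
#' @export
betweenness_centrality <- function(m) {
  w <- as_weights(m)
  g <- graph_of(w)
  b <- igraph::betweenness(g, weights = 1 / igraph::E(g)$weight,
                           directed = FALSE)
  b[rownames(w)]
}

#' Per-node metric table
#'
#' Degree (implemented as strength, the sum of a node's weights — on a fully
#' weighted complete graph the binary degree would be constant and
#' uninformative), nodal characteristic path length, Onnela clustering
#' coefficient, local efficiency and betweenness centrality, computed on the
#' whole matrix.
#'
#' @inheritParams mean_strength
#' @return Data frame, one row per node.
#' @export
nodal_metrics <- function(m) {
  w <- as_weights(m)
  diag(w) <- 0
  data.frame(
    node = rownames(w),
    degree = rowSums(w),
    path_length = nodal_path_length(m),
    clustering = weighted_clustering(m)$nodes,
    local_efficiency = local_efficiency(m)$nodes,
    betweenness = betweenness_centrality(m),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Identify hub nodes
#'
#' A node collects one hub criterion flag for membership in the top 20%
#' (by default) of nodes with (a) highest degree, (b) lowest nodal path
#' length, (c) lowest clustering coefficient and (d) highest betweenness
#' centrality. The hub score is the number of flags; a node with score >= 2
#' is a hub. Each criterion flags exactly `round(top_fraction * n)` nodes
#' (half rounded up); ties at the cutoff are broken by ascending node order
#' for determinism.
#'
#' @param nodal Data frame from [nodal_metrics()].
#' @param top_fraction Fraction of nodes flagged per criterion (default 0.20).
#' @return `nodal` augmented with the four flags, `hub_score` and `is_hub`.
#' @export
identify_hubs <- function(nodal, top_fraction = 0.20) {
  n <- nrow(nodal)
  k <- as.integer(round_half_up(top_fraction * n))
  if (k < 1L)
    stop("identify_hubs: too few nodes for one top slot", call. = FALSE)
  flag_top <- function(x, decreasing) {
    ord <- order(if (decreasing) -x else x, seq_len(n))
    f <- logical(n)
    f[ord[seq_len(k)]] <- TRUE
    f
  }
  nodal$flag_degree <- flag_top(nodal$degree, TRUE)
  nodal$flag_path <- flag_top(nodal$path_length, FALSE)
  nodal$flag_clustering <- flag_top(nodal$clustering, FALSE)
  nodal$flag_betweenness <- flag_top(nodal$betweenness, TRUE)
  nodal$hub_score <- nodal$flag_degree + nodal$flag_path +
    nodal$flag_clustering + nodal$flag_betweenness
  nodal$is_hub <- nodal$hub_score >= 2L
  nodal
}

#' Count hubs per functional network
#'
#' @param hubs Hub table from [identify_hubs()].
#' @param parcels Parcel table (columns `parcel_id`, `network`) defining the
#'   network of each node; networks without retained nodes count 0.
#' @return Data frame with one row per network plus a `whole_brain` row.
#' @export
count_hubs_by_scope <- function(hubs, parcels) {
  net <- parcels$network[match(hubs$node, as.character(parcels$parcel_id))]
  nets <- unique(parcels$network)
  counts <- vapply(nets, function(g) sum(hubs$is_hub & net == g, na.rm = TRUE),
                   integer(1))
  data.frame(scope = c("whole_brain", nets),
             n_hubs = c(sum(hubs$is_hub), unname(counts)),
             stringsAsFactors = FALSE)
}

#' Export strong edges for connectome visualization
#'
#' Edges with weight greater than or equal to `threshold`. Visualization
#' export only — every metric in this package operates on the full weighted
#' matrix.
#'
#' @inheritParams mean_strength
#' @param threshold Weight cutoff in (0, 1\] (default 0.80), inclusive.
#' @return Data frame `node_i`, `node_j`, `weight` (unordered pairs).
#' @export
threshold_edges <- function(m, threshold = 0.80) {
  if (threshold <= 0 || threshold > 1)
    stop("threshold_edges: threshold must be in (0, 1]", call. = FALSE)
  w <- as_weights(m)
  ut <- which(upper.tri(w) & w >= threshold, arr.ind = TRUE)
  data.frame(node_i = rownames(w)[ut[, 1L]],
             node_j = colnames(w)[ut[, 2L]],
             weight = w[ut],
             stringsAsFactors = FALSE)
}

#' Whole-brain, within-network and between-network summaries
#'
#' One row per scope: the whole brain and each functional network carry mean
#' connectivity strength, characteristic path length, average clustering and
#' average local efficiency on the induced submatrix; between-network pairs
#' carry mean strength only.
#'
#' @inheritParams mean_strength
#' @param parcels Parcel table (columns `parcel_id`, `network`).
#' @param include_pairs Include all between-network pairs (default TRUE).
#' @param metrics Which metrics to compute; between-network pairs always use
#'   strength only.
#' @return Data frame with columns `scope`, `type`, `n_nodes`, `strength`,
#'   `path_length`, `clustering`, `local_efficiency`.
#' @export
network_summary <- function(m, parcels, include_pairs = TRUE,
                            metrics = c("strength", "path_length",
                                        "clustering", "local_efficiency")) {
  w <- as_weights(m)
  metrics <- match.arg(metrics, several.ok = TRUE)
  net_of <- function(g) {
    ids <- as.character(parcels$parcel_id[parcels$network == g])
    intersect(rownames(w), ids)
  }
  nets <- unique(parcels$network)
  scope_row <- function(name, type, ids) {
    r <- data.frame(scope = name, type = type, n_nodes = length(ids),
                    strength = NA_real_, path_length = NA_real_,
                    clustering = NA_real_, local_efficiency = NA_real_,
                    stringsAsFactors = FALSE)
    if (length(ids) >= 2L && "strength" %in% metrics)
      r$strength <- mean_strength(w, ids)
    if (length(ids) >= 2L && "path_length" %in% metrics)
      r$path_length <- characteristic_path_length(w, ids)
    if (length(ids) >= 3L) {
      if ("clustering" %in% metrics)
        r$clustering <- weighted_clustering(w, ids)$average
      if ("local_efficiency" %in% metrics)
        r$local_efficiency <- local_efficiency(w, ids)$average
    }
    r
  }
  rows <- list(scope_row("whole_brain", "global", rownames(w)))
  for (g in nets) rows[[length(rows) + 1L]] <- scope_row(g, "network", net_of(g))
  if (include_pairs && length(nets) > 1L) {
    cmb <- utils::combn(nets, 2L)
    for (j in seq_len(ncol(cmb))) {
      a <- net_of(cmb[1L, j]); b <- net_of(cmb[2L, j])
      r <- data.frame(scope = paste(cmb[1L, j], cmb[2L, j], sep = ":"),
                      type = "pair", n_nodes = length(a) + length(b),
                      strength = NA_real_, path_length = NA_real_,
                      clustering = NA_real_, local_efficiency = NA_real_,
                      stringsAsFactors = FALSE)
      if (length(a) && length(b)) r$strength <- mean_strength(w, a, b)
      rows[[length(rows) + 1L]] <- r
    }
  }
  do.call(rbind, rows)
}
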