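three_node <- function() {
  w <- matrix(c(1, 0.2, 0.4,
                0.2, 1, 0.6,
                0.4, 0.6, 1), 3, 3,
              dimnames = list(as.character(1:3), as.character(1:3)))
  w
}

test_that("mean strength averages within and between node sets", {
  w <- three_node()
  expect_equal(mean_strength(w), 0.4)
  expect_equal(mean_strength(w, "1", c("2", "3")), 0.3)
  expect_error(mean_strength(w, "1"), "single node")
  expect_error(mean_strength(w, c("1", "2"), c("2", "3")), "disjoint")
  # block fixture: within 0.8, across 0.2
  b <- matrix(0.2, 6, 6)
  b[1:3, 1:3] <- 0.8; b[4:6, 4:6] <- 0.8
  diag(b) <- 1
  dimnames(b) <- list(as.character(1:6), as.character(1:6))
  expect_equal(mean_strength(b, as.character(1:3)), 0.8)
  expect_equal(mean_strength(b, as.character(1:3), as.character(4:6)), 0.2)
})

test_that("shortest distances use lengths 1/w and match hand fixtures", {
  n <- 4
  w <- matrix(1, n, n); diag(w) <- 1
  dimnames(w) <- list(as.character(1:n), as.character(1:n))
  d <- distance_matrix(w)
  expect_true(all(d[row(d) != col(d)] == 1))
  w3 <- matrix(c(1, 1, 0.5,
                 1, 1, 0.5,
                 0.5, 0.5, 1), 3, 3,
               dimnames = list(as.character(1:3), as.character(1:3)))
  d3 <- distance_matrix(w3)
  expect_equal(d3["1", "2"], 1)
  expect_equal(d3["1", "3"], 2)
  expect_equal(d3["2", "3"], 2)
  expect_error(distance_matrix(matrix(c(1, 0, 0, 1), 2, 2)), "positive")
})

test_that("characteristic path length scales as 1/c under weight scaling", {
  set.seed(2)
  w <- random_weight_matrix(7)
  L <- characteristic_path_length(w)
  expect_equal(characteristic_path_length(w * 4), L / 4, tolerance = 1e-12)
  tri <- matrix(1, 3, 3)
  expect_equal(characteristic_path_length(tri), 1)
  w3 <- matrix(c(1, 1, 0.5, 1, 1, 0.5, 0.5, 0.5, 1), 3, 3)
  expect_equal(characteristic_path_length(w3), 5 / 3)
  expect_error(characteristic_path_length(w[1, 1, drop = FALSE]), "2 nodes")
})

test_that("Onnela clustering matches hand values and the triple-loop oracle", {
  eq <- matrix(0.7, 5, 5); diag(eq) <- 1
  expect_equal(unname(weighted_clustering(eq)$nodes), rep(1, 5))
  tri <- matrix(c(1, 1, 0.5, 1, 1, 0.5, 0.5, 0.5, 1), 3, 3)
  expect_equal(unname(weighted_clustering(tri)$nodes),
               rep((1 * 0.5 * 0.5)^(1 / 3), 3), tolerance = 1e-12)
  expect_error(weighted_clustering(eq[1:2, 1:2]), "3 nodes")
  set.seed(3)
  for (i in 1:20) {
    n <- sample(6:10, 1)
    w <- random_weight_matrix(n)
    expect_equal(unname(weighted_clustering(w)$nodes), clustering_loop(w),
                 tolerance = 1e-12)
  }
})

test_that("local efficiency matches hand values and the brute-force oracle", {
  eq <- matrix(1, 5, 5)
  expect_equal(unname(local_efficiency(eq)$nodes), rep(1, 5))
  # node 1 with neighbours 2, 3 connected by w23: single neighbour pair, the
  # direct edge is the shortest path, so E_1 = (w12 w13 w23)^(1/3)
  w <- matrix(c(1, 0.6, 0.8, 0.6, 1, 0.5, 0.8, 0.5, 1), 3, 3)
  e <- local_efficiency(w)$nodes
  expect_equal(unname(e[1]), (0.6 * 0.8 * 0.5)^(1 / 3), tolerance = 1e-12)
  set.seed(4)
  for (i in 1:20) {
    n <- sample(6:10, 1)
    w <- random_weight_matrix(n)
    expect_equal(unname(local_efficiency(w)$nodes), local_eff_loop(w),
                 tolerance = 1e-10)
  }
})

test_that("betweenness matches counting and enumeration oracles", {
  eq <- matrix(0.5, 6, 6); diag(eq) <- 1
  expect_true(all(betweenness_centrality(eq) == 0))
  # node 2 relays everything between node 1 and nodes 3, 4
  w <- matrix(0.1, 4, 4)
  w[1, 2] <- w[2, 1] <- 0.9
  w[2, 3] <- w[3, 2] <- 0.9
  w[2, 4] <- w[4, 2] <- 0.9
  diag(w) <- 1
  b <- betweenness_centrality(w)
  expect_gt(b[2], 0)
  expect_equal(unname(b[1]), 0)
  expect_equal(unname(b), betweenness_enum(w), tolerance = 1e-10)
  set.seed(5)
  for (i in 1:20) {
    n <- sample(6:10, 1)
    w <- random_weight_matrix(n)
    expect_equal(unname(betweenness_centrality(w)), betweenness_count(w),
                 tolerance = 1e-8)
  }
  for (i in 1:5) {
    w <- random_weight_matrix(6)
    expect_equal(unname(betweenness_centrality(w)), betweenness_enum(w),
                 tolerance = 1e-8)
  }
})

test_that("hub identification flags exactly the top fraction per criterion", {
  set.seed(6)
  atlas <- build_phantom_atlas(phantom_spec())
  s <- simulate_subject(atlas, 30, default_age_effects(), seed = 2)
  m <- subject_matrix(s$volume, atlas)
  hubs <- identify_hubs(nodal_metrics(m))
  expect_equal(sum(hubs$flag_degree), 20L)
  expect_equal(sum(hubs$flag_path), 20L)
  expect_equal(sum(hubs$flag_clustering), 20L)
  expect_equal(sum(hubs$flag_betweenness), 20L)
  expect_equal(hubs$hub_score,
               hubs$flag_degree + hubs$flag_path + hubs$flag_clustering +
                 hubs$flag_betweenness)
  expect_identical(hubs$is_hub, hubs$hub_score >= 2L)
  # scale invariance of the hub set
  m2 <- m; m2$weights <- m$weights * 0.35
  hubs2 <- identify_hubs(nodal_metrics(m2))
  expect_identical(hubs$is_hub, hubs2$is_hub)
  expect_identical(hubs$hub_score, hubs2$hub_score)
})

test_that("a strongly connected star centre is a hub", {
  n <- 5
  w <- matrix(0.1, n, n)
  w[1, ] <- w[, 1] <- 0.9
  diag(w) <- 1
  dimnames(w) <- list(as.character(1:n), as.character(1:n))
  hubs <- identify_hubs(nodal_metrics(w))
  expect_equal(sum(hubs$flag_degree), 1L)  # round(0.2 * 5) = 1
  expect_true(hubs$is_hub[1])
  expect_true(all(hubs$hub_score[-1] <= 1))
  expect_error(identify_hubs(hubs[1:2, ]), "too few nodes")
})

test_that("equal-weight ties are resolved deterministically", {
  eq <- matrix(0.5, 10, 10); diag(eq) <- 1
  dimnames(eq) <- list(as.character(1:10), as.character(1:10))
  hubs <- identify_hubs(nodal_metrics(eq))
  expect_equal(sum(hubs$flag_clustering), 2L)
  # ascending node order wins ties
  expect_true(all(which(hubs$flag_clustering) == 1:2))
  hubs_again <- identify_hubs(nodal_metrics(eq))
  expect_identical(hubs, hubs_again)
})

test_that("hub counts aggregate by network, including empty ones", {
  atlas <- small_atlas(sizes = c(a = 3L, b = 3L), voxels = 50L)
  parcels <- rbind(atlas$parcels[c("parcel_id", "parcel_name", "network")],
                   data.frame(parcel_id = 7L, parcel_name = "ghost",
                              network = "empty_net"))
  w <- random_weight_matrix(6)
  rownames(w) <- colnames(w) <- as.character(1:6)
  hubs <- identify_hubs(nodal_metrics(w))
  counts <- count_hubs_by_scope(hubs, parcels)
  expect_equal(counts$n_hubs[counts$scope == "whole_brain"], sum(hubs$is_hub))
  expect_equal(counts$n_hubs[counts$scope == "empty_net"], 0L)
  expect_equal(sum(counts$n_hubs[counts$scope != "whole_brain"]),
               sum(hubs$is_hub))
})

test_that("edge thresholding is inclusive and visualization-only", {
  w <- matrix(c(1, 0.79, 0.80, 0.79, 1, 0.81, 0.80, 0.81, 1), 3, 3,
              dimnames = list(as.character(1:3), as.character(1:3)))
  e <- threshold_edges(w, 0.80)
  expect_equal(nrow(e), 2L)
  expect_true(all(e$weight >= 0.80))
  low <- matrix(0.5, 3, 3); diag(low) <- 1
  expect_equal(nrow(threshold_edges(low, 0.8)), 0L)
  expect_error(threshold_edges(w, 0), "threshold")
})

test_that("subnetwork metrics never touch out-of-network edges", {
  set.seed(8)
  w <- random_weight_matrix(10)
  ids <- as.character(1:4)
  ref <- c(characteristic_path_length(w, ids),
           weighted_clustering(w, ids)$average,
           local_efficiency(w, ids)$average,
           mean_strength(w, ids))
  # perturb all edges with at least one endpoint outside the subnetwork
  w2 <- w
  out <- 5:10
  w2[out, ] <- w2[out, ] * 0.3
  w2[, out] <- t(w2[out, ])
  diag(w2) <- 1
  got <- c(characteristic_path_length(w2, ids),
           weighted_clustering(w2, ids)$average,
           local_efficiency(w2, ids)$average,
           mean_strength(w2, ids))
  expect_identical(ref, got)
})
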