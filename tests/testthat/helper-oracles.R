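# Independent brute-force oracles used to validate the graph and regression
# code paths. These deliberately avoid the package's implementations
# (igraph distances/betweenness, matrix-algebra clustering, lm fits).

# random symmetric weight matrix with weights in (lo, hi], diagonal 1
random_weight_matrix <- function(n, lo = 0.05, hi = 1) {
  w <- matrix(0, n, n)
  w[upper.tri(w)] <- runif(n * (n - 1) / 2, lo, hi)
  w <- w + t(w)
  diag(w) <- 1
  dimnames(w) <- list(as.character(seq_len(n)), as.character(seq_len(n)))
  w
}

# all-pairs shortest distances on lengths 1/w by Floyd-Warshall
fw_distances <- function(w) {
  n <- nrow(w)
  d <- 1 / w
  diag(d) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# Onnela clustering by direct triple loop on max-normalized weights
clustering_loop <- function(w) {
  diag(w) <- 0
  wh <- w / max(w)
  n <- nrow(w)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(w[i, ] > 0)
    if (k < 2) next
    s <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j == i || h == i || j == h) next
      s <- s + (wh[i, j] * wh[i, h] * wh[j, h])^(1 / 3)
    }
    ci[i] <- s / (k * (k - 1))
  }
  ci
}

# local efficiency by direct loops, neighbour-subgraph distances via FW
local_eff_loop <- function(w) {
  diag(w) <- 0
  n <- nrow(w)
  e <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    d <- fw_distances(w[nb, nb, drop = FALSE])
    s <- 0
    for (a in seq_len(k)) for (b in seq_len(k)) {
      if (a == b) next
      s <- s + (w[i, nb[a]] * w[i, nb[b]] / d[a, b])^(1 / 3)
    }
    e[i] <- s / (k * (k - 1))
  }
  e
}

# betweenness by shortest-path counting through distance composition:
# sigma_s(v) accumulated over nodes in order of distance from s, pair
# dependencies from d(s,v) + d(v,t) == d(s,t). Independent of Brandes.
betweenness_count <- function(w, tol = 1e-10) {
  n <- nrow(w)
  len <- 1 / w
  diag(len) <- 0
  d <- fw_distances(w)
  sig <- matrix(0, n, n)  # sig[s, v] = number of shortest s->v paths
  for (s in seq_len(n)) {
    ord <- order(d[s, ])
    sig[s, s] <- 1
    for (v in ord) {
      if (v == s) next
      cnt <- 0
      for (u in seq_len(n)) {
        if (u == v) next
        if (abs(d[s, u] + len[u, v] - d[s, v]) < tol) cnt <- cnt + sig[s, u]
      }
      sig[s, v] <- cnt
    }
  }
  b <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
      if (s == v || t == v) next
      if (abs(d[s, v] + d[v, t] - d[s, t]) < tol)
        b[v] <- b[v] + sig[s, v] * sig[t, v] / sig[s, t]
    }
  }
  b
}

# betweenness by exhaustive simple-path enumeration (tiny graphs only)
betweenness_enum <- function(w, tol = 1e-10) {
  n <- nrow(w)
  len <- 1 / w
  b <- numeric(n)
  paths_between <- function(s, t) {
    found <- list()
    rec <- function(path, lensum) {
      v <- path[length(path)]
      if (v == t) {
        found[[length(found) + 1]] <<- list(path = path, len = lensum)
        return()
      }
      for (u in seq_len(n)) {
        if (u %in% path) next
        rec(c(path, u), lensum + len[v, u])
      }
    }
    rec(s, 0)
    found
  }
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    ps <- paths_between(s, t)
    lens <- vapply(ps, `[[`, numeric(1), "len")
    mn <- min(lens)
    short <- ps[lens < mn + tol]
    for (p in short) {
      mid <- setdiff(p$path, c(s, t))
      b[mid] <- b[mid] + 1 / length(short)
    }
  }
  b
}

# OLS by explicit normal equations
ols_normal_eq <- function(y, X) {
  as.vector(solve(t(X) %*% X, t(X) %*% y))
}

# analytic Gaussian density sampled on a standard grid
gauss_on_grid <- function(grid, mu, sd) dnorm(grid$points, mu, sd)

# small phantom atlas helper (two networks by default)
small_atlas <- function(sizes = c(net_a = 6L, net_b = 6L), voxels = 800L,
                        seed = 1L, delta_sd = 0.05, sigma = 0.1) {
  total <- sum(sizes) * voxels
  side <- ceiling(total^(1 / 3))
  shape <- c(side, side, ceiling(total / side^2))
  build_phantom_atlas(phantom_spec(volume_shape = shape,
                                   parcel_voxels = voxels,
                                   network_sizes = sizes,
                                   delta_sd = delta_sd, sigma = sigma,
                                   seed = seed))
}

# trapezoidal integral of grid-sampled values (independent of the package's
# internal quadrature helper)
trapz_row <- function(y, g) {
  w <- rep(g$step, g$bins); w[c(1, g$bins)] <- g$step / 2
  sum(y * w)
}
trapz_est <- function(est) trapz_row(est$density, est$grid)

# run one subject volume through density + network stages
subject_matrix <- function(volume, atlas, grid = standard_grid(),
                           min_voxels = 800L,
                           bandwidth_method = "botev") {
  build_matrix(estimate_subject_pdfs(volume, atlas, grid, min_voxels,
                                     bandwidth_method))
}
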