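complete_graph <- function(n) {
  a <- matrix(1L, n, n); diag(a) <- 0L; a
}

star_graph <- function(n) {
  a <- matrix(0L, n, n)
  a[1, 2:n] <- a[2:n, 1] <- 1L
  a
}

path3 <- function() {
  a <- matrix(0L, 3, 3)
  a[1, 2] <- a[2, 1] <- a[2, 3] <- a[3, 2] <- 1L
  a
}

test_that("canonical graphs give textbook metric values", {
  k5 <- complete_graph(5)
  expect_equal(clustering_coefficient(k5)$mean, 1)
  expect_equal(char_path_length(k5)$L, 1)
  expect_equal(global_efficiency(k5), 1)
  expect_equal(local_efficiency(k5), 1)

  st <- star_graph(6)
  expect_equal(clustering_coefficient(st)$mean, 0)
  expect_equal(local_efficiency(st), 0)

  p3 <- path3()
  expect_equal(char_path_length(p3)$L, 4 / 3)
  expect_equal(global_efficiency(p3), 5 / 6)

  # two disjoint dyads: L = 1 with 8 of 12 ordered pairs excluded
  two_k2 <- matrix(0L, 4, 4)
  two_k2[1, 2] <- two_k2[2, 1] <- two_k2[3, 4] <- two_k2[4, 3] <- 1L
  cpl <- char_path_length(two_k2)
  expect_equal(cpl$L, 1)
  expect_equal(cpl$frac_excluded, 8 / 12)

  empty <- matrix(0L, 5, 5)
  expect_equal(global_efficiency(empty), 0)
})

test_that("all raw metrics agree with brute-force oracles", {
  set.seed(11)
  for (i in 1:30) {
    n <- sample(4:10, 1)
    adj <- rand_adjacency(n, runif(1, 0.2, 0.8))
    expect_equal(clustering_coefficient(adj)$per_node,
                 bf_clustering(adj)$per_node)
    expect_equal(char_path_length(adj)$L, bf_char_path(adj))
    expect_equal(global_efficiency(adj), bf_global_eff(adj))
    expect_equal(local_efficiency(adj), bf_local_eff(adj))
  }
})

test_that("proportional thresholding keeps the strongest positive edges", {
  set.seed(12)
  C_ <- 5
  w <- matrix(0, C_, C_)
  w[upper.tri(w)] <- seq(0.1, 1, length.out = 10)
  w <- w + t(w)
  bg <- binarize_at_sparsity(w, 0.4)
  expect_equal(bg$n_edges, 4L)          # round(0.4 * 10)
  kept <- which(bg$adjacency[upper.tri(bg$adjacency)] == 1)
  vals <- w[upper.tri(w)]
  expect_true(all(vals[kept] >= sort(vals, decreasing = TRUE)[4]))

  # all-negative weights: empty graph, achieved sparsity 0, warning
  expect_warning(neg <- binarize_at_sparsity(-w, 0.3), "positive")
  expect_equal(neg$n_edges, 0L)
  expect_equal(neg$achieved_sparsity, 0)

  # tie spanning the cutoff: deterministic lexicographic resolution,
  # checked against an exhaustive ranking oracle on a 6-node toy
  C6 <- 6
  tied <- matrix(0, C6, C6)
  idx <- dynfc:::edge_index(C6)
  vals6 <- c(rep(0.9, 3), rep(0.5, 8), rep(0.2, 4))
  tied[cbind(idx[, 1], idx[, 2])] <- vals6
  tied <- tied + t(tied)
  s <- 6 / 15  # request 6 edges: the 0.5 tie spans the cutoff
  bg6 <- binarize_at_sparsity(tied, s)
  ord <- order(-vals6, seq_along(vals6))   # brute-force ranking
  expect_equal(which(bg6$adjacency[cbind(idx[, 1], idx[, 2])] == 1),
               sort(ord[1:6]))
  expect_identical(bg6$adjacency,
                   binarize_at_sparsity(tied, s)$adjacency)
})

test_that("degree-preserving rewiring keeps degrees and breaks structure", {
  set.seed(13)
  adj <- rand_adjacency(12, 0.4)
  ref <- random_reference(adj, seed = 14)
  expect_equal(sort(igraph::degree(ref)), sort(rowSums(adj)))

  # K3 admits no valid double-edge swap
  k3 <- complete_graph(3)
  ref3 <- random_reference(k3, seed = 15)
  expect_equal(igraph::as_adjacency_matrix(ref3, sparse = FALSE),
               k3, ignore_attr = TRUE)

  # rewiring a ring lattice destroys its clustering
  ring <- ring_lattice(20, 4)
  c_ring <- clustering_coefficient(ring)$mean
  set.seed(16)
  c_rew <- mean(vapply(1:20, function(i) {
    clustering_coefficient(random_reference(ring))$mean
  }, numeric(1)))
  expect_lt(c_rew, c_ring)
})

test_that("small-world normalization behaves as expected", {
  set.seed(17)
  adj <- rand_adjacency(15, 0.4)
  sw <- small_world(adj, n_rand = 20, seed = 18)
  expect_equal(sw$sigma, sw$gamma / sw$lambda)

  # Erdos-Renyi-like graph: gamma and lambda near 1
  er <- rand_adjacency(30, 0.3)
  sw_er <- small_world(er, n_rand = 20, seed = 19)
  expect_lt(abs(sw_er$gamma - 1), 0.3)
  expect_lt(abs(sw_er$lambda - 1), 0.1)

  # ring lattice with a few shortcuts: the canonical small world
  ws <- ring_lattice(20, 4)
  ws[1, 10] <- ws[10, 1] <- 1L
  ws[5, 15] <- ws[15, 5] <- 1L
  sw_ws <- small_world(ws, n_rand = 20, seed = 20)
  expect_gt(sw_ws$sigma, 1)

  # triangle-free references: gamma undefined, NA propagated
  sparse <- matrix(0L, 4, 4)
  sparse[1, 2] <- sparse[2, 1] <- sparse[3, 4] <- sparse[4, 3] <- 1L
  sw_na <- small_world(sparse, n_rand = 3, seed = 21)
  expect_true(is.na(sw_na$gamma) || sw_na$C_rand == 0)

  # determinism under a fixed seed
  sw2 <- small_world(adj, n_rand = 20, seed = 18)
  expect_identical(sw[c("gamma", "lambda", "sigma")],
                   sw2[c("gamma", "lambda", "sigma")])
})

test_that("metric curves integrate correctly and respect monotonicity", {
  grid <- sparsity_grid()
  expect_length(grid, 41)

  # flat curve integrates to 0.40 * m
  m <- 2.5
  expect_equal(auc_trapz(grid, rep(m, 41)), 0.40 * m, tolerance = 1e-12)

  set.seed(22)
  conn <- matrix(rnorm(20^2), 20); conn <- (conn + t(conn)) / 2
  # high sparsities may exhaust the positive edges here; that pathway warns
  mc <- suppressWarnings(metric_curves(conn, n_rand = 3, seed = 23,
                                       metrics = c("eg", "eloc")))
  expect_false(is.unsorted(mc$values[, "eg"]))
  expect_equal(unname(mc$auc["eg"]),
               auc_trapz(mc$grid, mc$values[, "eg"]))

  # edge count non-decreasing along the grid
  counts <- vapply(grid, function(s) {
    suppressWarnings(binarize_at_sparsity(conn, s))$n_edges
  }, integer(1))
  expect_false(is.unsorted(counts))
})

test_that("across-window AUC variance reflects connectivity dynamics", {
  set.seed(24)
  dense <- matrix(0.8, 10, 10); diag(dense) <- 0
  sparse <- matrix(-0.1, 10, 10)
  sparse[1:3, 1:3] <- 0.9; diag(sparse) <- 0
  grid <- seq(0.1, 0.4, 0.1)

  # identical windows: variance exactly zero, even for normalized metrics
  same <- stack_from_matrices(rep(list(dense), 3))
  dv0 <- dynamic_metric_variance(same, grid = grid, n_rand = 3, seed = 25)
  expect_equal(unname(dv0$variance), rep(0, 5))
  expect_equal(nrow(dv0$per_window_auc), 3)

  # two-state alternation: eg-AUC varies more than a single-state subject
  alt <- stack_from_matrices(rep(list(dense, sparse), 4))
  # the sparse state has only 3 positive edges, so high thresholds warn
  dv_alt <- suppressWarnings(
    dynamic_metric_variance(alt, grid = grid, seed = 26, metrics = "eg"))
  dv_same <- dynamic_metric_variance(
    stack_from_matrices(rep(list(dense), 8)), grid = grid, seed = 26,
    metrics = "eg")
  expect_gt(dv_alt$variance[["eg"]], dv_same$variance[["eg"]])

  expect_error(dynamic_metric_variance(stack_from_matrices(list(dense)),
                                       grid = grid),
               "at least 2")
})
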