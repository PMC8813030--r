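# Brute-force graph oracles, independent of the package implementation:
# explicit Floyd-Warshall shortest paths and triangle enumeration on plain
# adjacency matrices.

bf_shortest_paths <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

bf_clustering <- function(adj) {
  n <- nrow(adj)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    links <- 0
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        if (adj[nb[a], nb[b]] > 0) links <- links + 1
      }
    }
    ci[i] <- 2 * links / (k * (k - 1))
  }
  list(per_node = ci, mean = mean(ci))
}

bf_char_path <- function(adj) {
  d <- bf_shortest_paths(adj)
  off <- !diag(nrow(adj))
  conn <- is.finite(d) & off
  if (!any(conn)) return(NA_real_)
  mean(d[conn])
}

bf_global_eff <- function(adj) {
  n <- nrow(adj)
  if (n < 2) return(0)
  d <- bf_shortest_paths(adj)
  total <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && is.finite(d[i, j])) total <- total + 1 / d[i, j]
    }
  }
  total / (n * (n - 1))
}

bf_local_eff <- function(adj) {
  n <- nrow(adj)
  contrib <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] > 0)
    if (length(nb) >= 2) {
      contrib[i] <- bf_global_eff(adj[nb, nb, drop = FALSE])
    }
  }
  mean(contrib)
}

rand_adjacency <- function(n, p) {
  a <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (runif(1) < p) a[i, j] <- a[j, i] <- 1L
    }
  }
  a
}

ring_lattice <- function(n, k) {
  a <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (off in seq_len(k / 2)) {
      j <- ((i - 1 + off) %% n) + 1
      a[i, j] <- a[j, i] <- 1L
    }
  }
  a
}

# Window stack built directly from a list of symmetric matrices, for tests
# that need full control over the windowed connectivity values.
stack_from_matrices <- function(mats, subject_id = "toy") {
  C_ <- nrow(mats[[1]])
  arr <- array(0, dim = c(length(mats), C_, C_))
  for (i in seq_along(mats)) arr[i, , ] <- mats[[i]]
  structure(list(windows = arr, onsets = seq_along(mats),
                 window_length_tr = 22L, sigma_tr = 3, step_tr = 1L,
                 tr_seconds = 2, subject_id = subject_id,
                 n_degenerate = 0L),
            class = "window_stack")
}

# Edge vector of the Fisher-z transform of a state covariance, used as the
# reference when matching fitted states to generator truth.
truth_state_edges <- function(states) {
  t(vapply(states, function(st) {
    dynfc:::upper_vec(fisher_z(st$covariance))
  }, numeric(nrow(states[[1]]$covariance) *
             (nrow(states[[1]]$covariance) - 1) / 2)))
}

nuisance_covars <- function(meta) meta[, c("age", "sex", "education",
                                           "mean_fd")]
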