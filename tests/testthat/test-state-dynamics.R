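two_cloud_pool <- function(n_each = 40, d = 6, sep = 10, sd = 0.5,
                           seed = 1) {
  set.seed(seed)
  edges <- rbind(matrix(rnorm(n_each * d, -sep, sd), n_each),
                 matrix(rnorm(n_each * d, sep, sd), n_each))
  list(edges = edges,
       subject = rep(c("s1", "s2"), each = n_each),
       window = rep(seq_len(n_each), 2))
}

test_that("k-means separates well-separated clouds and is deterministic", {
  pooled <- two_cloud_pool()
  model <- cluster_states(pooled, k = 2, max_iter = 100,
                          n_replicates = 5, seed = 2)
  lab <- model$labels$state
  expect_equal(length(unique(lab[1:40])), 1)
  expect_equal(length(unique(lab[41:80])), 1)
  expect_false(lab[1] == lab[41])

  model2 <- cluster_states(pooled, k = 2, max_iter = 100,
                           n_replicates = 5, seed = 2)
  expect_identical(model$labels, model2$labels)
  expect_identical(model$centroids, model2$centroids)

  expect_error(cluster_states(pooled, k = 1), "at least 2")
})

test_that("more restarts never worsen the clustering objective", {
  set.seed(3)
  pooled <- list(edges = matrix(rnorm(600), 100, 6),
                 subject = rep("s", 100), window = 1:100)
  one <- cluster_states(pooled, k = 4, max_iter = 20, n_replicates = 1,
                        seed = 7)
  many <- cluster_states(pooled, k = 4, max_iter = 20, n_replicates = 10,
                         seed = 7)
  expect_lte(many$inertia, one$inertia)
})

test_that("temporal metrics match run-length enumeration", {
  m <- state_metrics(c(1, 1, 2, 2, 2, 1), k = 2)
  expect_equal(unname(m$fraction), c(0.5, 0.5))
  expect_equal(unname(m$mean_dwell), c(1.5, 3))
  expect_equal(m$n_transitions, 2L)

  cst <- state_metrics(rep(1L, 193), k = 2, tr_seconds = 2, step = 1)
  expect_equal(unname(cst$fraction), c(1, 0))
  expect_equal(unname(cst$mean_dwell), c(193, NA_real_))
  expect_equal(unname(cst$mean_dwell_seconds), c(386, NA_real_))
  expect_equal(cst$n_transitions, 0L)

  alt <- state_metrics(rep(c(1L, 2L), 20))
  expect_equal(unname(alt$mean_dwell), c(1, 1))
  expect_equal(alt$n_transitions, 39L)
})

test_that("temporal metric identities hold for arbitrary label sequences", {
  set.seed(4)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    W <- sample(10:200, 1)
    labels <- sample.int(k, W, replace = TRUE)
    m <- state_metrics(labels, k = k)
    runs <- rle(labels)
    expect_equal(sum(m$fraction), 1)
    expect_equal(m$n_transitions, length(runs$lengths) - 1L)
    n_runs <- tabulate(runs$values, nbins = k)
    dwell <- m$mean_dwell
    dwell[is.na(dwell)] <- 0
    expect_equal(sum(dwell * n_runs), W)
  }
})

test_that("silhouette selection recovers the generating state count", {
  # three states, each coupling a different third of the components
  C_ <- 12
  part <- rep(c("N1", "N2", "N3"), each = 4)
  names(part) <- sprintf("IC%02d", 1:C_)
  states <- lapply(1:3, function(s) {
    m <- matrix(0.05, C_, C_)
    sel <- part == paste0("N", s)
    m[sel, sel] <- 0.8
    diag(m) <- 1
    dynfc:::state_spec(s, dynfc:::repair_pd(m, m, max_repair = Inf),
                       paste0("net", s))
  })
  tm3 <- matrix(0.05, 3, 3); diag(tm3) <- 0.9
  spec <- cohort_spec(n_per_group = c(HC = 6), n_components = C_,
                      partition = part,
                      transition_matrices = list(HC = tm3),
                      noise_sd = 0.2, seed = 5)
  stacks <- lapply(1:6, function(i) {
    windowed_fc(simulate_subject(spec, "HC", states, seed = 60 + i,
                                 subject_id = paste0("sub", i))$ts)
  })
  sel <- select_k(stacks, k_range = 2:5, seed = 6, n_replicates = 3,
                  max_iter = 100, max_silhouette_n = 1000)
  expect_equal(sel$k, 3)

  # (near-)perfectly separated equal clusters: silhouette approaches 1
  set.seed(77)
  jittered <- function(i, j) {
    m <- matrix(rnorm(36, sd = 0.01), 6)
    m <- (m + t(m)) / 2
    m[i, j] <- m[j, i] <- 100
    diag(m) <- 0
    m
  }
  blob_stack <- stack_from_matrices(c(
    replicate(20, jittered(1, 2), simplify = FALSE),
    replicate(20, jittered(5, 6), simplify = FALSE)))
  sil <- select_k(list(blob_stack), k_range = 2:3, seed = 7,
                  n_replicates = 2, max_iter = 50)
  expect_gt(sil$silhouette_by_k[["2"]], 0.95)
  expect_equal(sil$k, 2)
})

test_that("stickier chains yield longer estimated dwell times", {
  # tested in the regime the window can resolve: true dwells at or above
  # the 22-TR window length, and states separated strongly enough that
  # per-window label noise does not fragment long runs
  part <- default_network_partition(10)
  states <- build_state_covariances(part, within_strength = 0.7,
                                    between_strength = 0.05, seed = 8)
  stays <- 1 - 1 / c(22, 33, 50, 75, 110)   # true mean dwell in TRs
  dwell <- vapply(seq_along(stays), function(li) {
    p <- stays[li]
    tm <- matrix(c(p, 1 - p, 1 - p, p), 2, byrow = TRUE)
    spec <- cohort_spec(n_per_group = c(HC = 4), n_components = 10,
                        n_timepoints = 800, partition = part,
                        transition_matrices = list(HC = tm),
                        noise_sd = 0.1, seed = 9)
    stacks <- lapply(1:4, function(i) {
      windowed_fc(simulate_subject(spec, "HC", states,
                                   seed = 700 + 10 * li + i,
                                   subject_id = paste0("sub", i))$ts)
    })
    model <- cluster_states(stacks, k = 2, max_iter = 100,
                            n_replicates = 2, seed = 10 + li)
    smt <- state_metrics_table(model)
    # pooled mean run length: total windows / total runs, the most stable
    # dwell estimator at this cohort size
    W_total <- 4 * dim(stacks[[1]]$windows)[1]
    W_total / sum(smt$n_transitions + 1)
  }, numeric(1))
  expect_gt(cor(dwell, stays, method = "spearman"), 0.9)
})

test_that("group-mean occupancy recovers the chains' stationary levels", {
  # 10 seeds averaged; groups scaled to 15 subjects for runtime, which the
  # seed average more than compensates
  part <- default_network_partition(43)
  errs <- matrix(NA_real_, 10, 2, dimnames = list(NULL, c("HC", "RTLE")))
  for (s in 1:10) {
    spec <- cohort_spec(n_per_group = c(HC = 15, RTLE = 15),
                        seed = 900 + s)
    co <- simulate_cohort(spec)
    stacks <- lapply(co$timecourses, windowed_fc)
    model <- cluster_states(stacks, k = 2, max_iter = 50,
                            n_replicates = 1, seed = s)
    perm <- match_states(model$centroids, truth_state_edges(co$states))
    smt <- state_metrics_table(model)
    frac2 <- smt[[paste0("fraction_state", which(perm == 2))]]
    names(frac2) <- smt$subject_id
    for (g in c("HC", "RTLE")) {
      pi0 <- stationary_distribution(spec$transition_matrices[[g]])
      sids <- co$meta$subject_id[co$meta$group == g]
      errs[s, g] <- mean(frac2[sids]) - pi0[2]
    }
  }
  expect_lt(abs(mean(errs[, "HC"])), 0.07)
  expect_lt(abs(mean(errs[, "RTLE"])), 0.07)
})

test_that("state matching undoes label permutation", {
  ref <- rbind(c(1, 0, 0, 1), c(0, 1, 1, 0))
  cent <- rbind(c(0.1, 0.9, 1.1, 0.1), c(0.9, 0.1, 0, 1.2))
  expect_equal(match_states(cent, ref), c(2L, 1L))
  expect_equal(match_states(ref, ref), c(1L, 2L))
})
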