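test_that("state covariances honour the block design and stay PD", {
  part <- default_network_partition(20)

  # zero-effect case: both states collapse to the identity
  st0 <- build_state_covariances(part, within_strength = 0,
                                 between_strength = 0, jitter_sd = 0)
  expect_equal(st0[[1]]$covariance, diag(20), ignore_attr = TRUE)
  expect_equal(st0[[2]]$covariance, diag(20), ignore_attr = TRUE)

  st <- build_state_covariances(part, within_strength = 0.5,
                                between_strength = 0.1, jitter_sd = 0.02,
                                seed = 11)
  same_net <- outer(part, part, "==")
  off <- !diag(20)
  for (s in 1:2) {
    cov_s <- st[[s]]$covariance
    expect_equal(cov_s, t(cov_s))
    expect_equal(unname(diag(cov_s)), rep(1, 20))
    expect_gt(min(eigen(cov_s, symmetric = TRUE,
                        only.values = TRUE)$values), 0)
  }
  # state I: within-block mean exceeds between-block mean
  expect_gt(mean(st[[1]]$covariance[same_net & off]),
            mean(st[[1]]$covariance[!same_net]))
  # state II: between-network blocks elevated relative to state I
  expect_gt(mean(st[[2]]$covariance[!same_net]),
            mean(st[[1]]$covariance[!same_net]))

  # strengths that cannot form a correlation matrix fail loudly
  expect_error(build_state_covariances(part, within_strength = 0,
                                       between_strength = 0.85,
                                       jitter_sd = 0),
               "repair")
})

test_that("subject simulation follows the hidden Markov chain", {
  part <- default_network_partition(10)
  spec <- cohort_spec(n_per_group = c(HC = 1), n_components = 10,
                      partition = part, noise_sd = 0, seed = 3)
  states <- build_state_covariances(part, seed = 3)

  # absorbing chain: the state sequence never moves
  spec_abs <- spec
  spec_abs$transition_matrices$HC <- diag(2)
  sim <- simulate_subject(spec_abs, "HC", states, seed = 5)
  expect_true(all(sim$states == sim$states[1]))

  # determinism: same seed, bit-identical output
  sim2 <- simulate_subject(spec_abs, "HC", states, seed = 5)
  expect_identical(sim$ts$data, sim2$ts$data)
  expect_identical(sim$states, sim2$states)

  # non-stochastic transition matrix is rejected
  spec_bad <- spec
  spec_bad$transition_matrices$HC <- matrix(c(0.5, 0.4, 0.2, 0.8), 2,
                                            byrow = TRUE)
  expect_error(simulate_subject(spec_bad, "HC", states, seed = 1),
               "stochastic")
})

test_that("long single-state series recovers the state covariance", {
  part <- default_network_partition(10)
  spec <- cohort_spec(n_per_group = c(HC = 1), n_components = 10,
                      n_timepoints = 20000, partition = part,
                      noise_sd = 0, jitter_sd = 0, seed = 9)
  spec$transition_matrices$HC <- matrix(1, 1, 1)
  states <- build_state_covariances(part, jitter_sd = 0)[1]
  sim <- simulate_subject(spec, "HC", states, seed = 21)
  emp <- cor(sim$ts$data)
  expect_lt(max(abs(emp - states[[1]]$covariance)), 0.05)
})

test_that("occupancy converges to the chain's stationary distribution", {
  part <- default_network_partition(10)
  spec <- cohort_spec(n_per_group = c(HC = 1), n_components = 10,
                      n_timepoints = 5000, partition = part, seed = 2)
  states <- build_state_covariances(part, seed = 2)
  pi0 <- stationary_distribution(spec$transition_matrices$HC)
  occ <- vapply(1:4, function(s) {
    mean(simulate_subject(spec, "HC", states, seed = 100 + s)$states == 2L)
  }, numeric(1))
  expect_lt(abs(mean(occ) - pi0[2]), 0.02)
})

test_that("cohort generation respects counts, metadata and determinism", {
  spec <- cohort_spec(n_per_group = c(HC = 2), n_components = 10,
                      partition = default_network_partition(10), seed = 4)
  co <- simulate_cohort(spec)
  expect_length(co$timecourses, 2)
  expect_true(all(co$meta$group == "HC"))
  expect_equal(nrow(co$meta), 2)

  # mean_fd consistent with the stored trace
  expect_equal(co$meta$mean_fd,
               vapply(co$fd_traces[co$meta$subject_id], mean, numeric(1)),
               ignore_attr = TRUE)
  # MoCA sub-items within instrument ranges
  ranges <- c(moca_visuospatial_executive = 5, moca_naming = 3,
              moca_attention = 6, moca_language = 3, moca_abstraction = 2,
              moca_delayed_recall = 5, moca_orientation = 6)
  for (item in names(ranges)) {
    expect_true(all(co$meta[[item]] >= 0 & co$meta[[item]] <= ranges[item]))
  }

  co2 <- simulate_cohort(spec)
  expect_identical(co$meta, co2$meta)
  expect_identical(co$timecourses[[1]]$data, co2$timecourses[[1]]$data)
  expect_identical(co$truth, co2$truth)
})

test_that("per-group occupancy matches the configured stationary levels", {
  spec <- cohort_spec(n_per_group = c(HC = 32, RTLE = 32),
                      n_components = 10,
                      partition = default_network_partition(10), seed = 6)
  co <- simulate_cohort(spec)
  for (g in c("HC", "RTLE")) {
    occ <- mean(co$truth$occupancy_state2[co$truth$group == g])
    pi0 <- stationary_distribution(spec$transition_matrices[[g]])
    expect_lt(abs(occ - pi0[2]), 0.05)
  }
})

test_that("truth record round-trips through the JSON writer unchanged", {
  spec <- cohort_spec(n_per_group = c(HC = 2, RTLE = 2), n_components = 8,
                      partition = default_network_partition(8), seed = 12)
  co <- simulate_cohort(spec)
  path <- tempfile(fileext = ".json")
  write_truth(co$truth, path)
  back <- read_truth(path)
  expect_equal(back$subject_id, co$truth$subject_id)
  expect_equal(back$group, co$truth$group)
  expect_equal(back$subject_seed, co$truth$subject_seed)
  expect_equal(back$occupancy_state2, co$truth$occupancy_state2)
  expect_equal(back$state_sequences, co$truth$state_sequences)
  expect_equal(back$stationary, lapply(co$truth$stationary, as.numeric),
               ignore_attr = TRUE)
})

test_that("injected group effects shift subcortical-cortical coupling", {
  part <- default_network_partition(43)
  idx <- dynfc:::edge_index(43)
  scn_smn <- (part[idx[, 1]] == "SCN" & part[idx[, 2]] == "SMN") |
    (part[idx[, 1]] == "SMN" & part[idx[, 2]] == "SCN")
  wins <- vapply(1:10, function(s) {
    spec <- cohort_spec(n_per_group = c(HC = 30, RTLE = 30),
                        seed = 500 + s)
    co <- simulate_cohort(spec)
    mean_scn_smn <- vapply(co$timecourses, function(ts) {
      mean(dynfc:::upper_vec(static_fc(ts)$values)[scn_smn])
    }, numeric(1))
    mean(mean_scn_smn[co$meta$group == "RTLE"]) >
      mean(mean_scn_smn[co$meta$group == "HC"])
  }, logical(1))
  # sign test over 10 seeds: RTLE above HC essentially always
  expect_gte(sum(wins), 9)
})
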