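#' Default component-to-network partition
#'
#' Assigns `n_components` independent components to the seven canonical
#' resting-state networks used throughout the pipeline: subcortical (SCN),
#' auditory (AUD), somatomotor (SMN), visual (VIS), cognitive control (CCN),
#' default mode (DMN) and cerebellar (CBN). The default block sizes
#' (5, 2, 6, 8, 9, 9, 4 for 43 components) mirror the typical relative sizes
#' of these networks in group-ICA decompositions.
#'
#' @param n_components number of components (default 43).
#' @return named character vector mapping component ids (`IC01`, ...) to
#'   network labels.
#' @export
default_network_partition <- function(n_components = 43L) {
  base_sizes <- c(SCN = 5, AUD = 2, SMN = 6, VIS = 8, CCN = 9, DMN = 9,
                  CBN = 4)
  if (n_components == 43L) {
    sizes <- base_sizes
  } else {
    # scale blocks proportionally, keeping every network non-empty
    sizes <- round(base_sizes / sum(base_sizes) * n_components)
    sizes[sizes < 1L] <- 1L
    while (sum(sizes) > n_components) {
      k <- which.max(sizes)
      sizes[k] <- sizes[k] - 1L
    }
    while (sum(sizes) < n_components) {
      k <- which.min(sizes)
      sizes[k] <- sizes[k] + 1L
    }
  }
  part <- rep(names(sizes), times = sizes)
  names(part) <- sprintf("IC%02d", seq_len(n_components))
  part
}

networks <- function(partition) unique(unname(partition))

#' Build the two recurring connectivity-state covariance archetypes
#'
#' State I ("within-network dominant") has off-diagonal correlation
#' `within_strength` inside network blocks and `between_strength` between
#' networks. State II ("between-network dominant") keeps the within-block
#' coherence but raises the between-network blocks most of the way toward
#' the within level (a mixing fraction of 0.6), reflecting how such states
#' appear in real data: networks remain internally coherent while coupling
#' between them strengthens. (A literal swap of the two strengths is not a
#' valid correlation structure — strong between-network correlation with
#' weak within-network correlation violates positive definiteness.)
#' Both matrices are jittered with symmetric Gaussian noise, symmetrized and
#' repaired to positive definiteness by clamping eigenvalues at a floor and
#' rescaling to unit diagonal.
#'
#' @param partition component-to-network map (see
#'   [default_network_partition()]).
#' @param within_strength,between_strength block correlations in (-1, 1).
#' @param jitter_sd standard deviation of the symmetric off-diagonal jitter.
#' @param seed RNG seed for the jitter (optional).
#' @param eig_floor eigenvalue floor used in the positive-definiteness
#'   repair.
#' @param max_repair maximum element-wise change the repair may introduce;
#'   larger changes signal a non-repairable strength combination and raise
#'   an error rather than silently distorting the design.
#' @return list of two `state_spec` objects (fields `state_id`,
#'   `covariance`, `label`).
#' @export
build_state_covariances <- function(partition,
                                    within_strength = 0.45,
                                    between_strength = 0.12,
                                    jitter_sd = 0.02,
                                    seed = NULL,
                                    eig_floor = 1e-4,
                                    max_repair = 0.1) {
  stopifnot(abs(within_strength) < 1, abs(between_strength) < 1,
            jitter_sd >= 0)
  n_comp <- length(partition)
  if (!is.null(seed)) set.seed(seed)
  same_net <- outer(partition, partition, "==")
  block_matrix <- function(within, between) {
    m <- ifelse(same_net, within, between)
    diag(m) <- 1
    dimnames(m) <- list(names(partition), names(partition))
    m
  }
  between2 <- between_strength + 0.6 * (within_strength - between_strength)
  targets <- list(block_matrix(within_strength, between_strength),
                  block_matrix(within_strength, between2))
  labels <- c("within-network dominant", "between-network dominant")
  lapply(seq_along(targets), function(s) {
    m <- targets[[s]]
    if (jitter_sd > 0) {
      j <- matrix(rnorm(n_comp^2, sd = jitter_sd), n_comp)
      j <- (j + t(j)) / 2
      diag(j) <- 0
      m <- m + j
    }
    state_spec(s, repair_pd(m, targets[[s]], eig_floor, max_repair),
               labels[[s]])
  })
}

state_spec <- function(state_id, covariance, label) {
  structure(list(state_id = as.integer(state_id), covariance = covariance,
                 label = label),
            class = "state_spec")
}

# Clamp eigenvalues at `eig_floor`, rescale to unit diagonal, and refuse the
# result if it strays further than `max_repair` from the intended target.
repair_pd <- function(m, target, eig_floor = 1e-4, max_repair = 0.1) {
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) < eig_floor) {
    vals <- pmax(e$values, eig_floor)
    m <- e$vectors %*% (vals * t(e$vectors))
  }
  d <- sqrt(diag(m))
  m <- m / tcrossprod(d)
  diag(m) <- 1
  dimnames(m) <- dimnames(target)
  dev <- max(abs(m - target))
  if (dev > max_repair) {
    stop("covariance repair moved entries by ", signif(dev, 3),
         " (> max_repair = ", max_repair,
         "); the requested strengths do not yield a usable correlation matrix")
  }
  m
}

#' Default per-group state-transition matrices
#'
#' Two-state Markov chains whose stationary occupancies encode the designed
#' group differences: controls favour the within-network state, the
#' right-lateralized patient group occupies the between-network state far
#' more, and the left-lateralized group sits close to controls.
#'
#' @return named list of 2 x 2 row-stochastic matrices for groups
#'   `HC`, `LTLE`, `RTLE`.
#' @export
default_transition_matrices <- function() {
  tm <- function(p12, p21) matrix(c(1 - p12, p12, p21, 1 - p21), 2,
                                  byrow = TRUE)
  list(HC   = tm(0.04, 0.10),   # stationary occupancy state I ~ 0.71
       LTLE = tm(0.05, 0.10),   # ~ 0.67
       RTLE = tm(0.10, 0.08))   # ~ 0.44
}

#' Default group edge-block multipliers
#'
#' Multipliers applied to state covariances per group: `cc` scales
#' cortical-cortical blocks (every pair of non-SCN networks) and `sc` scales
#' subcortical-cortical blocks (SCN paired with any other network). The
#' patient-like right-lateralized group has reduced cortical-cortical and
#' elevated subcortical-cortical coupling; the left-lateralized group is
#' deliberately left at control levels, matching a design in which only one
#' patient group carries connectivity effects.
#'
#' @return named list of lists with elements `cc` and `sc` per group.
#' @export
default_group_effects <- function() {
  list(HC   = list(cc = 1.0,  sc = 1.0),
       LTLE = list(cc = 1.0,  sc = 1.0),
       RTLE = list(cc = 0.75, sc = 1.8))
}

#' Cohort specification for the synthetic generator
#'
#' Bundles every knob of the Markov-switching Gaussian cohort generator.
#' Defaults reproduce the study design the pipeline targets: 37/22/31
#' subjects in groups HC/LTLE/RTLE, 43 components, 215 retained TRs at
#' TR = 2 s, two recurring covariance states with group-specific occupancy,
#' and multiplicative group effects on covariance blocks.
#'
#' @param n_per_group named integer vector of subjects per group.
#' @param n_components,n_timepoints,tr_seconds dimensions of each subject's
#'   time-course matrix.
#' @param transition_matrices named list (per group) of k x k row-stochastic
#'   matrices.
#' @param partition component-to-network map.
#' @param within_strength,between_strength,jitter_sd state-covariance
#'   parameters, see [build_state_covariances()].
#' @param group_effects per-group `cc`/`sc` block multipliers.
#' @param noise_sd independent Gaussian observation noise added on top of
#'   the state-driven signal (signal variance is 1, so 0.3 attenuates
#'   correlations by a factor ~0.92).
#' @param moca_link how the cognition score is tied to the latent dynamics:
#'   list with `item` (sub-item name), `intercept`, `slope` (points per unit
#'   of true between-network-state occupancy, negative by default so more
#'   time in the between-network state means worse performance), `center`,
#'   `noise_sd`, `min`, `max`.
#' @param seed master RNG seed; per-subject seeds are derived from it.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(HC = 37L, LTLE = 22L, RTLE = 31L),
                        n_components = 43L,
                        n_timepoints = 215L,
                        tr_seconds = 2,
                        transition_matrices = default_transition_matrices(),
                        partition = default_network_partition(n_components),
                        within_strength = 0.45,
                        between_strength = 0.12,
                        jitter_sd = 0.02,
                        group_effects = default_group_effects(),
                        noise_sd = 0.3,
                        moca_link = list(item = "language", intercept = 2.8,
                                         slope = -6, center = 0.35,
                                         noise_sd = 0.7, min = 0, max = 3),
                        seed = 1L) {
  n_per_group <- n_per_group[n_per_group > 0]
  stopifnot(length(n_per_group) >= 1, all(n_per_group == round(n_per_group)),
            n_components >= 2, n_timepoints >= 3, tr_seconds > 0,
            noise_sd >= 0)
  if (length(partition) != n_components) {
    stop("partition must assign every one of the ", n_components,
         " components to a network")
  }
  for (g in names(n_per_group)) {
    tm <- transition_matrices[[g]]
    if (is.null(tm)) stop("no transition matrix for group ", g)
    check_stochastic(tm)
    if (is.null(group_effects[[g]])) {
      stop("no group effects entry for group ", g)
    }
  }
  structure(list(n_per_group = n_per_group, n_components = n_components,
                 n_timepoints = as.integer(n_timepoints),
                 tr_seconds = tr_seconds,
                 transition_matrices = transition_matrices,
                 partition = partition,
                 within_strength = within_strength,
                 between_strength = between_strength,
                 jitter_sd = jitter_sd,
                 group_effects = group_effects, noise_sd = noise_sd,
                 moca_link = moca_link, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Null cohort specification (no group differences)
#'
#' Same generator with every group sharing the control transition matrix and
#' unit block multipliers: the correct negative control for type-I error
#' studies of the group statistics.
#'
#' @param ... overrides passed on to [cohort_spec()].
#' @export
null_cohort_spec <- function(...) {
  hc_tm <- default_transition_matrices()$HC
  cohort_spec(transition_matrices = list(HC = hc_tm, LTLE = hc_tm,
                                         RTLE = hc_tm),
              group_effects = list(HC = list(cc = 1, sc = 1),
                                   LTLE = list(cc = 1, sc = 1),
                                   RTLE = list(cc = 1, sc = 1)),
              ...)
}

check_stochastic <- function(tm, tol = 1e-8) {
  if (!is.matrix(tm) || nrow(tm) != ncol(tm) || any(tm < -tol) ||
      any(abs(rowSums(tm) - 1) > tol)) {
    stop("transition matrix must be square, non-negative and row-stochastic")
  }
  invisible(tm)
}

#' Stationary distribution of a row-stochastic matrix
#' @param tm row-stochastic transition matrix.
#' @return probability vector pi with pi %*% tm = pi.
#' @export
stationary_distribution <- function(tm) {
  check_stochastic(tm)
  k <- nrow(tm)
  a <- rbind(t(tm) - diag(k), rep(1, k))
  if (qr(a)$rank < k) {
    # reducible chain (e.g. the identity): every distribution is
    # stationary; the uniform one is the natural convention
    return(rep(1 / k, k))
  }
  pi <- qr.solve(a, c(rep(0, k), 1))
  pi / sum(pi)
}

# Apply a group's cc/sc multipliers to a state covariance and re-repair.
apply_group_effects <- function(cov, partition, effects,
                                subcortical = "SCN") {
  is_sc <- partition == subcortical
  cc_block <- outer(!is_sc, !is_sc, "&")
  sc_block <- outer(is_sc, !is_sc, "&") | outer(!is_sc, is_sc, "&")
  m <- cov
  m[cc_block] <- m[cc_block] * effects$cc
  m[sc_block] <- m[sc_block] * effects$sc
  diag(m) <- 1
  repair_pd(m, m, eig_floor = 1e-4, max_repair = Inf)
}

#' Simulate one subject's component time courses
#'
#' The hidden state follows the group's Markov chain started from its
#' stationary distribution; at each TR the observation is multivariate
#' normal with the active state's covariance (after the group's block
#' multipliers) plus independent Gaussian noise.
#'
#' @param spec a [cohort_spec()].
#' @param group group label (must have a transition matrix in `spec`).
#' @param states list of `state_spec` (see [build_state_covariances()]).
#' @param seed RNG seed for this subject.
#' @param subject_id id stored in the returned time-course set.
#' @return list with `ts` (a [timecourse_set()]) and `states` (the true
#'   per-TR state sequence, 1-based).
#' @export
simulate_subject <- function(spec, group, states, seed,
                             subject_id = "sub-01") {
  tm <- spec$transition_matrices[[group]]
  check_stochastic(tm)
  k <- nrow(tm)
  stopifnot(length(states) == k)
  chols <- lapply(states, function(st) {
    chol(apply_group_effects(st$covariance, spec$partition,
                             spec$group_effects[[group]]))
  })
  T_ <- spec$n_timepoints
  C_ <- spec$n_components
  set.seed(seed)
  pi0 <- stationary_distribution(tm)
  seq_states <- integer(T_)
  seq_states[1L] <- sample.int(k, 1L, prob = pi0)
  for (t in seq_len(T_ - 1L)) {
    seq_states[t + 1L] <- sample.int(k, 1L, prob = tm[seq_states[t], ])
  }
  z <- matrix(rnorm(T_ * C_), T_, C_)
  x <- matrix(0, T_, C_)
  for (s in seq_len(k)) {
    rows <- seq_states == s
    if (any(rows)) x[rows, ] <- z[rows, , drop = FALSE] %*% chols[[s]]
  }
  if (spec$noise_sd > 0) {
    x <- x + matrix(rnorm(T_ * C_, sd = spec$noise_sd), T_, C_)
  }
  colnames(x) <- names(spec$partition)
  list(ts = timecourse_set(x, spec$tr_seconds, subject_id),
       states = seq_states)
}

#' Simulate a full cohort with metadata and a ground-truth record
#'
#' Draws per-subject seeds from the master seed, simulates every subject's
#' time courses with [simulate_subject()], and generates demographic /
#' motion / cognition metadata. Age, education and mean frame-wise
#' displacement are drawn from truncated normal (or folded-normal-like
#' gamma) distributions loosely matched to a typical adult epilepsy cohort;
#' the configured MoCA sub-item is a linear function of the subject's
#' realized occupancy of the between-network state plus noise, giving the
#' partial-correlation stage a recoverable, sign-known signal.
#'
#' @param spec a [cohort_spec()].
#' @return list with `timecourses` (list of [timecourse_set()]), `meta`
#'   (data.frame), `fd_traces` (named list of per-volume FD in mm), `states`
#'   (the generating `state_spec`s) and `truth` (all latent quantities:
#'   per-subject seeds, true state sequences, occupancies, chain stationary
#'   occupancies).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  states <- build_state_covariances(spec$partition, spec$within_strength,
                                    spec$between_strength, spec$jitter_sd,
                                    seed = spec$seed)
  groups <- rep(names(spec$n_per_group), times = spec$n_per_group)
  n <- length(groups)
  subject_ids <- sprintf("sub-%03d", seq_len(n))
  subject_seeds <- sample.int(.Machine$integer.max - 1L, n)
  meta_seeds <- sample.int(.Machine$integer.max - 1L, n)

  timecourses <- vector("list", n)
  fd_traces <- vector("list", n)
  names(timecourses) <- names(fd_traces) <- subject_ids
  occ2 <- numeric(n)
  state_seqs <- vector("list", n)

  for (i in seq_len(n)) {
    sim <- simulate_subject(spec, groups[i], states, subject_seeds[i],
                            subject_ids[i])
    timecourses[[i]] <- sim$ts
    state_seqs[[i]] <- sim$states
    occ2[i] <- mean(sim$states == 2L)
  }

  link <- spec$moca_link
  meta_rows <- lapply(seq_len(n), function(i) {
    set.seed(meta_seeds[i])
    age <- round(trunc_norm(30, 8, 18, 60), 1)
    education <- round(trunc_norm(13, 2.5, 6, 20), 1)
    sex <- if (runif(1) < 0.5) "M" else "F"
    fd_mean_target <- abs(rnorm(1, 0.08, 0.04)) + 0.01
    fd <- rgamma(spec$n_timepoints, shape = 4,
                 scale = fd_mean_target / 4)
    fd_traces[[i]] <<- fd
    items <- moca_items(occ2[i], link)
    data.frame(subject_id = subject_ids[i], group = groups[i], age = age,
               sex = sex, education = education, mean_fd = mean(fd),
               as.list(items),
               moca_total = sum(items),
               stringsAsFactors = FALSE)
  })
  meta <- do.call(rbind, meta_rows)
  meta$group <- factor(meta$group, levels = names(spec$n_per_group))

  truth <- list(
    master_seed = spec$seed,
    subject_id = subject_ids,
    group = groups,
    subject_seed = subject_seeds,
    state_sequences = state_seqs,
    occupancy_state2 = occ2,
    stationary = lapply(spec$transition_matrices[names(spec$n_per_group)],
                        stationary_distribution),
    state_labels = vapply(states, `[[`, "", "label"),
    moca_link = link
  )
  list(timecourses = timecourses, meta = meta, fd_traces = fd_traces,
       states = states, truth = truth)
}

trunc_norm <- function(mean, sd, lo, hi) {
  repeat {
    x <- rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
}

# MoCA-style sub-item scores. Non-linked items are near-ceiling binomials on
# their instrument ranges; the linked item is linear in the subject's true
# between-network-state occupancy plus noise, rounded and clipped.
moca_items <- function(occ2, link) {
  ranges <- c(visuospatial_executive = 5, naming = 3, attention = 6,
              language = 3, abstraction = 2, delayed_recall = 5,
              orientation = 6)
  items <- vapply(ranges, function(mx) rbinom(1, mx, 0.92), numeric(1))
  linked <- link$intercept + link$slope * (occ2 - link$center) +
    rnorm(1, sd = link$noise_sd)
  items[[link$item]] <- min(max(round(linked), link$min), link$max)
  names(items) <- paste0("moca_", names(ranges))
  items
}
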