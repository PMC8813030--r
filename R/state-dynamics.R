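#' Concatenate all subjects' window stacks into one edge matrix
#'
#' @param stacks named list of [windowed_fc()] stacks.
#' @return list with `edges` (total-windows x E matrix), `subject`
#'   (character, one entry per row) and `window` (within-subject index).
#' @export
pool_windows <- function(stacks) {
  mats <- lapply(stacks, stack_edges)
  subject <- rep(vapply(stacks, function(s) s$subject_id, ""),
                 vapply(mats, nrow, 0L))
  window <- unlist(lapply(mats, function(m) seq_len(nrow(m))),
                   use.names = FALSE)
  list(edges = do.call(rbind, mats), subject = unname(subject),
       window = window)
}

# k-means++ seeding on the rows of x (squared-Euclidean sampling).
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  first <- sample.int(n, 1L)
  centers[1L, ] <- x[first, ]
  d2 <- rowSums((x - rep(centers[1L, ], each = n))^2)
  if (k > 1L) {
    for (j in 2:k) {
      probs <- d2 / sum(d2)
      pick <- sample.int(n, 1L, prob = probs)
      centers[j, ] <- x[pick, ]
      d2 <- pmin(d2, rowSums((x - rep(centers[j, ], each = n))^2))
    }
  }
  centers
}

#' Cluster windowed connectivity into recurring states
#'
#' Pools every subject's windowed Fisher-z matrices as upper-triangle edge
#' vectors and runs squared-Euclidean k-means (Lloyd iterations,
#' k-means++ seeding) with `n_replicates` restarts, keeping the solution
#' with the lowest total within-cluster sum of squares. Replicates that end
#' with an empty cluster are re-seeded (and counted).
#'
#' @param stacks named list of [windowed_fc()] stacks (or a pooled result
#'   from [pool_windows()]).
#' @param k number of states (>= 2; use [select_k()] to choose it).
#' @param max_iter Lloyd iteration cap per replicate.
#' @param n_replicates random restarts.
#' @param seed RNG seed making the whole fit deterministic.
#' @return object of class `state_model`: `k`, `centroids` (k x E),
#'   `labels` (data.frame subject / window / state), `inertia`, `sizes`,
#'   `n_reseeds`.
#' @export
cluster_states <- function(stacks, k, max_iter = 500L, n_replicates = 150L,
                           seed = NULL) {
  if (k < 2) stop("k must be at least 2")
  pooled <- if (is.list(stacks) && !is.null(stacks$edges)) stacks
            else pool_windows(stacks)
  x <- pooled$edges
  if (nrow(x) < k ||
      (nrow(x) <= 2000L && nrow(unique(x)) < k)) {
    stop("fewer than k distinct window vectors")
  }
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  n_reseeds <- 0L
  for (rep_i in seq_len(n_replicates)) {
    fit <- NULL
    attempts <- 0L
    while (is.null(fit) && attempts < 10L) {
      attempts <- attempts + 1L
      init <- kmeanspp_init(x, k)
      fit <- tryCatch(
        suppressWarnings(stats::kmeans(x, centers = init,
                                       iter.max = max_iter,
                                       algorithm = "Lloyd")),
        error = function(e) NULL)
      if (!is.null(fit) && any(fit$size == 0L)) fit <- NULL
      if (is.null(fit)) n_reseeds <- n_reseeds + 1L
    }
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) stop("k-means failed to produce a valid partition")
  structure(list(k = as.integer(k), centroids = best$centers,
                 labels = data.frame(subject = pooled$subject,
                                     window = pooled$window,
                                     state = as.integer(best$cluster)),
                 inertia = best$tot.withinss, sizes = best$size,
                 n_reseeds = n_reseeds),
            class = "state_model")
}

#' @export
print.state_model <- function(x, ...) {
  cat("<state_model> k = ", x$k, ", ", nrow(x$labels), " windows, inertia ",
      signif(x$inertia, 5), "\n", sep = "")
  invisible(x)
}

# Pairwise Euclidean distances between the rows of x, BLAS-accelerated.
euclid_dmatrix <- function(x) {
  sq <- rowSums(x^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(x)
  d2[d2 < 0] <- 0
  diag(d2) <- 0
  sqrt(d2)
}

#' Choose the number of connectivity states by the silhouette criterion
#'
#' Fits [cluster_states()] for every k in `k_range` and scores each fit by
#' the mean silhouette width (Euclidean distances on the same edge vectors
#' the squared-Euclidean k-means clusters). For cost, the silhouette is
#' evaluated on a deterministic, evenly-strided subsample of at most
#' `max_silhouette_n` windows. The selected k maximizes the mean
#' silhouette; ties go to the smaller k.
#'
#' @param stacks named list of window stacks.
#' @param k_range candidate state counts (default 2:8).
#' @param seed RNG seed.
#' @param n_replicates,max_iter forwarded to [cluster_states()].
#' @param max_silhouette_n silhouette subsample cap.
#' @return list with `k` (selected), `silhouette_by_k` (named numeric) and
#'   `models` (the fitted `state_model` per k).
#' @export
select_k <- function(stacks, k_range = 2:8, seed = NULL,
                     n_replicates = 150L, max_iter = 500L,
                     max_silhouette_n = 5000L) {
  pooled <- pool_windows(stacks)
  n <- nrow(pooled$edges)
  stopifnot(all(k_range >= 2), max(k_range) < n)
  idx <- if (n > max_silhouette_n) {
    unique(round(seq(1L, n, length.out = max_silhouette_n)))
  } else seq_len(n)
  dmat <- euclid_dmatrix(pooled$edges[idx, , drop = FALSE])
  sil <- numeric(length(k_range))
  models <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    models[[i]] <- cluster_states(pooled, k_range[i], max_iter = max_iter,
                                  n_replicates = n_replicates,
                                  seed = if (is.null(seed)) NULL
                                         else seed + i - 1L)
    lab <- models[[i]]$labels$state[idx]
    sil[i] <- mean(cluster::silhouette(lab, dmatrix = dmat)[, "sil_width"])
  }
  names(sil) <- as.character(k_range)
  names(models) <- as.character(k_range)
  list(k = k_range[which.max(sil)], silhouette_by_k = sil, models = models)
}

#' Temporal state statistics for one subject
#'
#' From a subject's per-window state sequence: the fraction of windows
#' spent in each state, the mean dwell time (mean length of maximal runs,
#' in windows; multiply by `tr_seconds * step` for seconds), and the total
#' number of transitions. States never visited get `NA` dwell time and are
#' excluded from group statistics downstream.
#'
#' @param labels integer state sequence for one subject (one entry per
#'   window).
#' @param k total number of states in the model (defaults to
#'   `max(labels)`).
#' @param tr_seconds,step used for the seconds conversion.
#' @return list with `fraction`, `mean_dwell`, `mean_dwell_seconds`
#'   (per-state named vectors), `n_transitions` and `n_windows`.
#' @export
state_metrics <- function(labels, k = max(labels), tr_seconds = 2,
                          step = 1L) {
  stopifnot(length(labels) >= 1, all(labels >= 1), all(labels <= k))
  W <- length(labels)
  runs <- rle(as.integer(labels))
  states <- seq_len(k)
  fraction <- tabulate(labels, nbins = k) / W
  mean_dwell <- vapply(states, function(s) {
    len <- runs$lengths[runs$values == s]
    if (length(len) == 0L) NA_real_ else mean(len)
  }, numeric(1))
  names(fraction) <- names(mean_dwell) <- paste0("state", states)
  list(fraction = fraction, mean_dwell = mean_dwell,
       mean_dwell_seconds = mean_dwell * tr_seconds * step,
       n_transitions = length(runs$lengths) - 1L, n_windows = W)
}

#' Per-subject temporal statistics table for a fitted state model
#'
#' @param model a `state_model` from [cluster_states()].
#' @param tr_seconds,step forwarded to [state_metrics()].
#' @return data.frame with one row per subject: fraction and mean dwell per
#'   state, transitions.
#' @export
state_metrics_table <- function(model, tr_seconds = 2, step = 1L) {
  subjects <- unique(model$labels$subject)
  rows <- lapply(subjects, function(s) {
    lab <- model$labels$state[model$labels$subject == s]
    m <- state_metrics(lab, k = model$k, tr_seconds = tr_seconds,
                       step = step)
    out <- data.frame(subject_id = s, n_transitions = m$n_transitions,
                      stringsAsFactors = FALSE)
    for (st in seq_len(model$k)) {
      out[[paste0("fraction_state", st)]] <- m$fraction[st]
      out[[paste0("dwell_state", st)]] <- m$mean_dwell[st]
    }
    out
  })
  do.call(rbind, rows)
}

#' Match fitted states to reference states by centroid correlation
#'
#' Greedy maximum-correlation matching between fitted centroids and
#' reference edge vectors (for example the generating covariances'
#' upper triangles). Used to undo k-means label permutation before any
#' recovery comparison.
#'
#' @param centroids k x E fitted centroid matrix.
#' @param reference k x E reference matrix (row r = reference state r).
#' @return integer vector `perm` with `perm[fitted_state] = reference
#'   state`.
#' @export
match_states <- function(centroids, reference) {
  k <- nrow(centroids)
  stopifnot(nrow(reference) == k)
  cc <- cor(t(centroids), t(reference))  # k_fit x k_ref
  perm <- integer(k)
  used <- logical(k)
  ord <- order(-apply(cc, 1, max, na.rm = TRUE))
  for (i in ord) {
    j <- order(-cc[i, ])
    j <- j[!used[j]][1L]
    perm[i] <- j
    used[j] <- TRUE
  }
  perm
}
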