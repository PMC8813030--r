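#' Fisher r-to-z transform with clipping
#'
#' @param r correlation values; clipped to `+/-(1 - 1e-7)` before `atanh`
#'   so degenerate perfect correlations stay finite.
#' @param clip clipping bound.
#' @return z values.
#' @export
fisher_z <- function(r, clip = 1 - 1e-7) {
  atanh(pmin(pmax(r, -clip), clip))
}

conn_matrix <- function(values, scale = c("fisher_z", "pearson_r"),
                        component_ids = colnames(values)) {
  scale <- match.arg(scale)
  structure(list(values = values, scale = scale,
                 component_ids = component_ids),
            class = "conn_matrix")
}

#' @export
print.conn_matrix <- function(x, ...) {
  cat("<conn_matrix> ", nrow(x$values), " x ", ncol(x$values), " (",
      x$scale, ")\n", sep = "")
  invisible(x)
}

#' Static functional connectivity matrix
#'
#' Pearson correlation between every pair of component time courses over
#' the full series, Fisher z-transformed. The diagonal is set to zero (it
#' is excluded from every edge statistic downstream). Constant components
#' yield zero edges with a warning rather than an error.
#'
#' @param ts a [timecourse_set()].
#' @return a `conn_matrix` on the `fisher_z` scale.
#' @export
static_fc <- function(ts) {
  x <- ts$data
  stopifnot(nrow(x) >= 3)
  sds <- apply(x, 2, sd)
  r <- suppressWarnings(cor(x))
  if (any(sds == 0)) {
    warning("constant component(s) ",
            paste(colnames(x)[sds == 0], collapse = ", "),
            ": their edges set to 0")
    r[sds == 0, ] <- 0
    r[, sds == 0] <- 0
  }
  z <- fisher_z(r)
  diag(z) <- 0
  conn_matrix(z, "fisher_z", colnames(x))
}

#' Tapered sliding-window weights
#'
#' A rectangular window of `window_length` TRs convolved with a Gaussian
#' kernel (standard deviation `sigma` TRs, support +/- 3 sigma), truncated
#' to the central `window_length` samples and normalized to unit sum. The
#' taper is symmetric and monotonically decreasing toward the window edges;
#' as `sigma` shrinks to zero it reduces to the flat window.
#'
#' @param window_length window length in TRs (default 22).
#' @param sigma Gaussian taper width in TRs (default 3).
#' @return numeric weight vector of length `window_length` summing to 1.
#' @export
make_window_weights <- function(window_length = 22L, sigma = 3) {
  stopifnot(window_length >= 3, sigma > 0)
  half <- max(1L, ceiling(3 * sigma))
  kern <- exp(-((-half):half)^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  full <- convolve(rep(1, window_length), rev(kern), type = "open")
  w <- full[(half + 1L):(half + window_length)]
  w <- (w + rev(w)) / 2     # enforce exact symmetry against FFT round-off
  w <- w / sum(w)
  attr(w, "sigma") <- sigma
  w
}

# Weighted Pearson correlation of the columns of X under unit-sum weights.
# Columns with (near) zero weighted variance get zero correlations.
weighted_cor <- function(x, w, eps = 1e-12) {
  mu <- colSums(x * w)
  xc <- (x - rep(mu, each = nrow(x))) * sqrt(w)
  s <- crossprod(xc)
  v <- diag(s)
  bad <- v <= eps
  denom <- sqrt(pmax(v, eps))
  r <- s / tcrossprod(denom)
  if (any(bad)) {
    r[bad, ] <- 0
    r[, bad] <- 0
  }
  diag(r) <- 1
  attr(r, "n_degenerate") <- sum(bad)
  r
}

#' Sliding-window functional connectivity stack
#'
#' Slides a tapered window along the time courses in steps of `step` TRs
#' and computes the weighted Pearson correlation (weighted means and
#' covariances) within each window, Fisher z-transformed. Window onsets run
#' from 1 to `T - L` so a series of 215 TRs with a 22-TR window yields 193
#' windows. Edges with zero weighted variance in a window are set to 0 and
#' counted in the `n_degenerate` field.
#'
#' @param ts a [timecourse_set()].
#' @param weights taper from [make_window_weights()].
#' @param step window step in TRs.
#' @return object of class `window_stack`: list with `windows`
#'   (W x C x C array of z values, zero diagonal), `onsets`,
#'   `window_length_tr`, `sigma_tr` (if known), `step_tr`, `tr_seconds`,
#'   `subject_id`.
#' @export
windowed_fc <- function(ts, weights = make_window_weights(), step = 1L) {
  x <- ts$data
  L <- length(weights)
  T_ <- nrow(x)
  C_ <- ncol(x)
  if (T_ <= L) stop("need more timepoints (", T_, ") than window length (",
                    L, ")")
  onsets <- seq.int(1L, T_ - L, by = step)
  W <- length(onsets)
  windows <- array(0, dim = c(W, C_, C_),
                   dimnames = list(NULL, colnames(x), colnames(x)))
  n_degenerate <- 0L
  for (wi in seq_len(W)) {
    o <- onsets[wi]
    r <- weighted_cor(x[o:(o + L - 1L), , drop = FALSE], weights)
    n_degenerate <- n_degenerate + attr(r, "n_degenerate")
    z <- fisher_z(r)
    diag(z) <- 0
    windows[wi, , ] <- z
  }
  structure(list(windows = windows, onsets = onsets,
                 window_length_tr = L,
                 sigma_tr = attr(weights, "sigma"),
                 step_tr = as.integer(step),
                 tr_seconds = ts$tr_seconds,
                 subject_id = ts$subject_id,
                 n_degenerate = n_degenerate),
            class = "window_stack")
}

#' @export
print.window_stack <- function(x, ...) {
  cat("<window_stack> ", x$subject_id, ": ", dim(x$windows)[1],
      " windows of ", x$window_length_tr, " TRs (step ", x$step_tr,
      ")\n", sep = "")
  invisible(x)
}

#' Windows-by-edges matrix from a window stack
#'
#' Flattens each windowed connectivity matrix to its upper-triangle edge
#' vector (row-major order, see the package conventions), giving the W x E
#' feature matrix consumed by the state-clustering stage.
#'
#' @param stack a [windowed_fc()] stack.
#' @return W x E numeric matrix.
#' @export
stack_edges <- function(stack) {
  d <- dim(stack$windows)
  idx <- edge_index(d[2])
  flat <- matrix(stack$windows, nrow = d[1])   # W x (C*C), column-major
  flat[, (idx[, 2L] - 1L) * d[2] + idx[, 1L], drop = FALSE]
}

#' Per-edge temporal variance across windows
#'
#' Sample variance (denominator W - 1) of the Fisher-z connectivity of each
#' edge across the sliding windows: the "connectivity variability" measure.
#'
#' @param stack a [windowed_fc()] stack.
#' @return C x C symmetric matrix of variances with zero diagonal.
#' @export
edge_variance <- function(stack) {
  em <- stack_edges(stack)
  W <- nrow(em)
  stopifnot(W >= 2)
  v <- colSums(em^2) - W * colMeans(em)^2
  v <- pmax(v, 0) / (W - 1)
  C_ <- dim(stack$windows)[2]
  sym_from_vec(v, C_, dimnames(stack$windows)[c(2, 3)])
}

#' Network-block summary of an edge-level matrix
#'
#' Averages off-diagonal edge values within and between network blocks.
#' Diagonal blocks exclude self-edges.
#'
#' @param values C x C symmetric matrix (connectivity or edge variance), or
#'   a `conn_matrix`.
#' @param partition component-to-network map.
#' @return N x N matrix of block means (N = number of networks), networks
#'   in order of first appearance in `partition`.
#' @export
network_block_means <- function(values, partition) {
  if (inherits(values, "conn_matrix")) values <- values$values
  stopifnot(nrow(values) == length(partition))
  nets <- networks(partition)
  out <- matrix(NA_real_, length(nets), length(nets),
                dimnames = list(nets, nets))
  off <- !diag(nrow(values))
  for (a in seq_along(nets)) {
    for (b in seq_len(a)) {
      sel <- outer(partition == nets[a], partition == nets[b], "&") & off
      out[a, b] <- out[b, a] <- mean(values[sel | t(sel)])
    }
  }
  out
}
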