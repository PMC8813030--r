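#' Binarize a connectivity matrix at a proportional sparsity threshold
#'
#' Ranks the positive edges by weight (descending) and keeps the top
#' `round(s * C(C-1)/2)`. Only positive relationships enter the graph; if
#' fewer positive edges exist than requested, all of them are kept and the
#' achieved sparsity is recorded (with a warning). Ties are broken by
#' lexicographic (i, j) edge index, so thresholding is deterministic across
#' platforms.
#'
#' @param conn a `conn_matrix` (any scale) or a plain symmetric matrix; the
#'   diagonal is ignored.
#' @param s target sparsity in (0, 1): the fraction of all possible edges
#'   to retain.
#' @return object of class `binary_graph`: `adjacency` (0/1 symmetric, zero
#'   diagonal), `sparsity` (requested), `achieved_sparsity`, `n_edges`.
#' @export
binarize_at_sparsity <- function(conn, s) {
  stopifnot(s > 0, s < 1)
  values <- if (inherits(conn, "conn_matrix")) conn$values else conn
  n_comp <- nrow(values)
  w <- upper_vec(values)
  n_total <- length(w)
  n_keep <- round(s * n_total)
  pos <- which(w > 0)
  if (length(pos) < n_keep) {
    warning("only ", length(pos), " positive edges available for requested ",
            n_keep, "; keeping all positive edges")
  }
  ord <- pos[order(-w[pos], pos)]
  keep <- ord[seq_len(min(n_keep, length(ord)))]
  v <- numeric(n_total)
  v[keep] <- 1
  adj <- sym_from_vec(v, n_comp, dimnames(values))
  structure(list(adjacency = adj, sparsity = s,
                 achieved_sparsity = length(keep) / n_total,
                 n_edges = length(keep)),
            class = "binary_graph")
}

as_adjacency <- function(g) {
  if (inherits(g, "binary_graph")) g$adjacency
  else if (igraph::is_igraph(g)) igraph::as_adjacency_matrix(g, sparse = FALSE)
  else as.matrix(g)
}

as_igraph <- function(g) {
  if (igraph::is_igraph(g)) g
  else igraph::graph_from_adjacency_matrix(as_adjacency(g) > 0,
                                           mode = "undirected")
}

#' Clustering coefficient of a binary graph
#'
#' Per node, `2 * triangles / (deg * (deg - 1))`; nodes with degree below 2
#' contribute 0.
#'
#' @param g a `binary_graph`, adjacency matrix, or igraph object.
#' @return list with `per_node` and `mean`.
#' @export
clustering_coefficient <- function(g) {
  ig <- as_igraph(g)
  deg <- igraph::degree(ig)
  tri <- igraph::count_triangles(ig)
  ci <- ifelse(deg >= 2, 2 * tri / (deg * (deg - 1)), 0)
  list(per_node = ci, mean = mean(ci))
}

#' Characteristic path length over connected pairs
#'
#' Mean shortest-path length over all connected ordered node pairs;
#' disconnected pairs are excluded and their fraction reported (low
#' sparsity thresholds routinely disconnect brain graphs).
#'
#' @param g a `binary_graph`, adjacency matrix, or igraph object.
#' @return list with `L` (NA if no pair is connected) and `frac_excluded`.
#' @export
char_path_length <- function(g) {
  d <- igraph::distances(as_igraph(g), algorithm = "unweighted")
  off <- !diag(nrow(d))
  conn <- is.finite(d) & off
  list(L = if (any(conn)) mean(d[conn]) else NA_real_,
       frac_excluded = 1 - sum(conn) / sum(off))
}

#' Global efficiency
#'
#' Mean inverse shortest-path length over all ordered node pairs, with
#' `1/d = 0` for unreachable pairs, so disconnected graphs are handled
#' gracefully.
#'
#' @param g a `binary_graph`, adjacency matrix, or igraph object.
#' @return scalar efficiency in `[0, 1]`.
#' @export
global_efficiency <- function(g) {
  d <- igraph::distances(as_igraph(g), algorithm = "unweighted")
  n <- nrow(d)
  if (n < 2) return(0)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Local efficiency
#'
#' Mean, over nodes, of the global efficiency of the subgraph induced by
#' each node's neighbours; nodes with fewer than two neighbours contribute
#' 0.
#'
#' @param g a `binary_graph`, adjacency matrix, or igraph object.
#' @return scalar local efficiency.
#' @export
local_efficiency <- function(g) {
  adj <- as_adjacency(g)
  n <- nrow(adj)
  contrib <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0)
    if (length(nb) < 2) return(0)
    global_efficiency(adj[nb, nb, drop = FALSE])
  }, numeric(1))
  mean(contrib)
}

#' Degree-preserving random reference graph
#'
#' Rewires the input by repeated double-edge swaps (degree sequence kept
#' exactly); connectedness is not enforced. Used to normalize clustering
#' coefficient and path length in the small-world computation.
#'
#' @param g a `binary_graph`, adjacency matrix, or igraph object.
#' @param n_swaps_per_edge rewiring intensity (total swap attempts =
#'   `n_swaps_per_edge * |E|`).
#' @param seed optional RNG seed.
#' @return igraph object with the same degree sequence.
#' @export
random_reference <- function(g, n_swaps_per_edge = 10, seed = NULL) {
  ig <- as_igraph(g)
  if (!is.null(seed)) set.seed(seed)
  m <- igraph::ecount(ig)
  if (m < 2) return(ig)
  out <- igraph::rewire(ig, igraph::keeping_degseq(
    niter = max(1L, as.integer(n_swaps_per_edge * m))))
  stopifnot(identical(sort(igraph::degree(out)), sort(igraph::degree(ig))))
  out
}

#' Small-world properties
#'
#' Normalized clustering coefficient `gamma = C / <C_rand>`, normalized
#' characteristic path length `lambda = L / <L_rand>`, and small-worldness
#' `sigma = gamma / lambda`, with averages over `n_rand` degree-preserving
#' random references. If the random references carry no triangles
#' (`<C_rand> = 0`) the values are undefined and returned as NA.
#'
#' @param g a `binary_graph`, adjacency matrix, or igraph object.
#' @param n_rand number of random reference graphs.
#' @param seed RNG seed for the rewiring stream.
#' @return list with `gamma`, `lambda`, `sigma`, `C`, `L`, `C_rand`,
#'   `L_rand`.
#' @export
small_world <- function(g, n_rand = 100, seed = NULL) {
  ig <- as_igraph(g)
  if (!is.null(seed)) set.seed(seed)
  C_ <- clustering_coefficient(ig)$mean
  L_ <- char_path_length(ig)$L
  cr <- numeric(n_rand)
  lr <- numeric(n_rand)
  for (i in seq_len(n_rand)) {
    r <- random_reference(ig)
    cr[i] <- clustering_coefficient(r)$mean
    lr[i] <- char_path_length(r)$L
  }
  c_rand <- mean(cr)
  l_rand <- mean(lr, na.rm = TRUE)
  gamma <- if (is.na(c_rand) || c_rand == 0) NA_real_ else C_ / c_rand
  lambda <- if (is.na(l_rand) || l_rand == 0 || is.na(L_)) NA_real_
            else L_ / l_rand
  sigma <- if (is.na(gamma) || is.na(lambda) || lambda == 0) NA_real_
           else gamma / lambda
  list(gamma = gamma, lambda = lambda, sigma = sigma, C = C_, L = L_,
       C_rand = c_rand, L_rand = l_rand)
}

#' Default sparsity grid
#'
#' 0.08 to 0.48 in steps of 0.01 (41 thresholds), spanning the range where
#' brain graphs go from sparse-but-connected to densely wired.
#'
#' @export
sparsity_grid <- function() seq(0.08, 0.48, by = 0.01)

#' Trapezoid-rule area under a metric curve
#'
#' @param x grid (strictly increasing).
#' @param y metric values on the grid (NAs treated as 0 after a warning).
#' @return scalar AUC.
#' @export
auc_trapz <- function(x, y) {
  stopifnot(length(x) == length(y), all(diff(x) > 0))
  if (anyNA(y)) {
    warning("NA metric values treated as 0 in AUC")
    y[is.na(y)] <- 0
  }
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Graph-metric curves over the sparsity sweep
#'
#' Thresholds the connectivity matrix at every sparsity in `grid`,
#' computes the requested global metrics on each binary graph, and
#' integrates each metric over the grid by the trapezoid rule. Random
#' references (needed only for gamma/lambda/sigma) are seeded per threshold
#' from a recorded seed stream so results are reproducible threshold by
#' threshold.
#'
#' @param conn a `conn_matrix` or symmetric matrix of edge weights.
#' @param grid sparsity thresholds (default [sparsity_grid()]).
#' @param n_rand random references per threshold.
#' @param seed RNG seed.
#' @param metrics subset of `c("gamma", "lambda", "sigma", "eg", "eloc")`.
#' @return object of class `metric_curves`: `grid`, `values` (matrix
#'   length(grid) x metrics), `auc` (named), `n_rand`.
#' @export
metric_curves <- function(conn, grid = sparsity_grid(), n_rand = 100,
                          seed = NULL,
                          metrics = c("gamma", "lambda", "sigma", "eg",
                                      "eloc")) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  need_rand <- any(metrics %in% c("gamma", "lambda", "sigma"))
  if (!is.null(seed)) set.seed(seed)
  thr_seeds <- sample.int(.Machine$integer.max - 1L, length(grid))
  values <- matrix(NA_real_, length(grid), length(metrics),
                   dimnames = list(NULL, metrics))
  for (i in seq_along(grid)) {
    bg <- binarize_at_sparsity(conn, grid[i])
    if (need_rand) {
      sw <- small_world(bg, n_rand = n_rand, seed = thr_seeds[i])
      if ("gamma" %in% metrics) values[i, "gamma"] <- sw$gamma
      if ("lambda" %in% metrics) values[i, "lambda"] <- sw$lambda
      if ("sigma" %in% metrics) values[i, "sigma"] <- sw$sigma
    }
    if ("eg" %in% metrics) values[i, "eg"] <- global_efficiency(bg)
    if ("eloc" %in% metrics) values[i, "eloc"] <- local_efficiency(bg)
  }
  auc <- vapply(metrics, function(m) {
    suppressWarnings(auc_trapz(grid, values[, m]))
  }, numeric(1))
  structure(list(grid = grid, values = values, auc = auc, n_rand = n_rand),
            class = "metric_curves")
}

#' @export
print.metric_curves <- function(x, ...) {
  cat("<metric_curves> ", length(x$grid), " thresholds [",
      min(x$grid), ", ", max(x$grid), "], AUC: ",
      paste(sprintf("%s=%.3f", names(x$auc), x$auc), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Across-window variance of graph-metric AUCs
#'
#' Computes the sparsity-swept metric curves and their AUC for every
#' windowed connectivity matrix of one subject, then returns the sample
#' variance of each metric's AUC across windows — the dynamic counterpart
#' of the static topology analysis.
#'
#' @param stack a [windowed_fc()] stack (W >= 2).
#' @param grid sparsity grid.
#' @param n_rand random references per threshold per window (kept small by
#'   default for tractability).
#' @param seed RNG seed.
#' @param metrics metrics to track (defaults to all five).
#' @return list with `variance` (named per metric) and `per_window_auc`
#'   (W x metrics matrix).
#' @export
dynamic_metric_variance <- function(stack, grid = sparsity_grid(),
                                    n_rand = 20, seed = NULL,
                                    metrics = c("gamma", "lambda", "sigma",
                                                "eg", "eloc")) {
  W <- dim(stack$windows)[1]
  if (W < 2) stop("need at least 2 windows")
  per_window <- matrix(NA_real_, W, length(metrics),
                       dimnames = list(NULL, metrics))
  # every window shares one reference seed stream: identical windows then
  # yield identical AUCs (zero variance) and the result stays deterministic
  for (wi in seq_len(W)) {
    mc <- metric_curves(stack$windows[wi, , ], grid = grid, n_rand = n_rand,
                        seed = seed, metrics = metrics)
    per_window[wi, ] <- mc$auc[metrics]
  }
  list(variance = apply(per_window, 2, var),
       per_window_auc = per_window)
}
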