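#' Plot graph-metric curves over the sparsity sweep
#'
#' Group-mean metric value per sparsity threshold, one panel per metric —
#' the standard way to show small-world and efficiency profiles before the
#' AUC summary. Requires ggplot2.
#'
#' @param curves long data.frame with columns `subject_id`, `metric`,
#'   `sparsity`, `value` (as written by the graphs stage).
#' @param groups optional named vector mapping subject ids to group labels.
#' @return a ggplot object.
#' @export
plot_metric_curves <- function(curves, groups = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  curves$group <- if (is.null(groups)) "all"
                  else groups[curves$subject_id]
  agg <- aggregate(value ~ metric + sparsity + group, curves, mean)
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$sparsity, y = .data$value,
                                    colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "sparsity threshold", y = "metric value") +
    ggplot2::theme_minimal()
}
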