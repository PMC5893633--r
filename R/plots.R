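#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the AUC distribution of a report
#'
#' Histogram of the per-unit membership AUCs with the median marked and
#' the 0.5 null reference line, the standard way prediction benchmarks of
#' co-expression data are displayed.
#'
#' @param object An `auc_report`.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.auc_report <- function(object, bins = 30, ...) {
  df <- object$values
  ggplot2::ggplot(df, ggplot2::aes(x = .data$auc)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35", colour = "white") +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = median(df$auc), colour = "firebrick") +
    ggplot2::coord_cartesian(xlim = c(0, 1)) +
    ggplot2::labs(
      x = sprintf("membership AUC per %s", object$direction),
      y = "count",
      title = sprintf("median AUC %.3f over %d %ss (%d excluded)",
                      median(df$auc), nrow(df), object$direction,
                      object$n_excluded)
    )
}

#' Plot ranked signature-search hits
#'
#' Bar chart of similarity scores for the returned hits, best first.
#'
#' @param hits A tibble from [search_signature()] or [search_index()].
#' @return A ggplot object.
#' @export
plot_search_hits <- function(hits) {
  stopifnot(all(c("rank", "sample_id", "score") %in% names(hits)))
  hits$sample_id <- factor(hits$sample_id, levels = rev(hits$sample_id))
  ggplot2::ggplot(hits, ggplot2::aes(x = .data$score, y = .data$sample_id)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "projected-space correlation", y = NULL,
                  title = "signature search hits")
}

#' Plot projection fidelity against subspace dimension
#'
#' Convenience sweep: evaluates [evaluate_fidelity()] for several target
#' dimensions `k` (optionally over several projection seeds) and plots the
#' mean preservation of the sample-correlation structure, the curve used
#' to choose a working subspace size.
#'
#' @param m Numeric matrix, genes x samples.
#' @param k_values Integer vector of subspace dimensions.
#' @param seeds Integer vector of projection seeds (default 1:3).
#' @return A ggplot object; the underlying tibble is in the `data` slot.
#' @export
plot_fidelity_curve <- function(m, k_values = c(10, 100, 1000), seeds = 1:3) {
  rows <- list()
  for (k in k_values) {
    for (s in seeds) {
      p <- build_projection(nrow(m), k = k, seed = s)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        k = k, seed = s, fidelity = evaluate_fidelity(m, p)
      )
    }
  }
  df <- do.call(rbind, rows)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$fidelity)) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "subspace dimension k",
                  y = "correlation-structure fidelity")
}
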