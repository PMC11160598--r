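# ggplot2 helpers for the main result types.

#' Plot precision-recall curves from a feature sweep
#'
#' @param sweep Result of [evaluate_feature_sweep()].
#' @return A ggplot object.
#' @export
plot_feature_sweep <- function(sweep) {
  curves <- sweep |>
    dplyr::mutate(n_features = factor(.data$n_features)) |>
    tidyr::unnest("pr")
  ggplot2::ggplot(curves,
                  ggplot2::aes(.data$recall, .data$precision,
                               colour = .data$n_features)) +
    ggplot2::geom_path() +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision",
                  colour = "Ranked\nfeatures") +
    ggplot2::theme_minimal()
}

#' Plot the precision/recall trade-off across hierarchy levels
#'
#' @param level_summary Result of [hierarchy_level_summary()].
#' @return A ggplot object.
#' @export
plot_hierarchy_tradeoff <- function(level_summary) {
  long <- tidyr::pivot_longer(level_summary,
                              c("mean_precision", "mean_recall"),
                              names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(.data$level, .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_clusters)) +
    ggplot2::scale_size_continuous(range = c(1.5, 4)) +
    ggplot2::labs(x = "Hierarchy level", y = "Node-weighted mean",
                  size = "Clusters", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot disease versus random guilt-by-association AUROC distributions
#'
#' @param gba Tibble of per-disease results with an `auroc` column (e.g.
#'   `rank_candidates(...)$diseases`).
#' @param baseline Numeric vector of random-set AUROCs from
#'   [random_baseline()].
#' @param threshold AUROC flag threshold drawn as a reference line.
#' @return A ggplot object.
#' @export
plot_auroc_distribution <- function(gba, baseline = NULL, threshold = 0.7) {
  df <- dplyr::bind_rows(
    tibble(auroc = gba$auroc, set = "disease"),
    if (!is.null(baseline)) tibble(auroc = baseline, set = "random")
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$auroc, fill = .data$set)) +
    ggplot2::geom_histogram(binwidth = 0.05, position = "identity",
                            alpha = 0.6, boundary = 0) +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "Leave-one-out AUROC", y = "Gene sets",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an FDR calibration curve
#'
#' @param object An `"fdr_calibration"`.
#' @param ... Unused.
#' @return A ggplot object showing q-value versus score threshold with
#'   the chosen operating point.
#' @export
autoplot.fdr_calibration <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(.data$threshold, .data$q_value)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = object$target_fdr,
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$threshold,
                        linetype = "dotted") +
    ggplot2::labs(x = "Score threshold", y = "q-value") +
    ggplot2::theme_minimal()
}
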