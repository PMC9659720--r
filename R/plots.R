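#' Heatmap of the site-by-site mean coverage matrix
#'
#' @param object An `hs_coverage_matrix`.
#' @param ... Unused.
#' @return A ggplot: rows are the query site (whose points are being
#'   covered), columns the hull site.
#' @export
autoplot.hs_coverage_matrix <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$hull_site, y = .data$query_site,
                                   fill = .data$mean_coverage)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$mean_coverage)),
                       size = 3) +
    ggplot2::scale_fill_gradient(limits = c(0, 1), low = "#fff5eb", high = "#d94801",
                                 name = "mean CH\ncoverage") +
    ggplot2::scale_y_discrete(limits = rev(object$sites)) +
    ggplot2::labs(x = "hull site (training data)", y = "query site (covered data)",
                  title = "Mean convex-hull coverage over features") +
    ggplot2::theme_minimal()
}

#' Heatmap of the cross-prediction ROC AUC matrix
#'
#' @param object An `hs_cross_prediction`.
#' @param ... Unused.
#' @return A ggplot: rows are the training site, columns the evaluation site;
#'   the diagonal is internal held-out performance.
#' @export
autoplot.hs_cross_prediction <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$test_site, y = .data$train_site,
                                   fill = .data$auc)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$auc)), size = 3) +
    ggplot2::scale_fill_gradient(limits = c(0.4, 1), low = "#deebf7", high = "#08519c",
                                 name = "ROC AUC") +
    ggplot2::scale_y_discrete(limits = rev(object$sites)) +
    ggplot2::labs(x = "evaluation site", y = "training site",
                  title = "Endpoint cross-prediction matrix") +
    ggplot2::theme_minimal()
}

#' Per-feature coverage distribution with the flagging threshold
#'
#' @param per_feature Per-feature coverage tibble from [feature_coverage()]
#'   or the `per_feature` element of a coverage matrix (one ordered site
#'   pair).
#' @return A ggplot dot plot of per-feature median coverages; the dashed line
#'   is the Q1 - 1.5 IQR threshold and flagged features are highlighted.
#' @export
plot_feature_coverage <- function(per_feature) {
  pf <- as_tibble(per_feature)
  if (length(unique(paste(pf$query_site, pf$hull_site))) > 1) {
    abort("supply per-feature coverages for a single ordered site pair")
  }
  ggplot2::ggplot(pf, ggplot2::aes(x = stats::reorder(.data$feature, .data$coverage),
                                   y = .data$coverage, color = .data$flagged)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$threshold), linetype = "dashed") +
    ggplot2::scale_color_manual(values = c("FALSE" = "grey30", "TRUE" = "#d7301f"),
                                name = "low coverage") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "median pairwise CH coverage",
                  title = paste0("Coverage of ", pf$query_site[1], " by the hull of ",
                                 pf$hull_site[1])) +
    ggplot2::theme_minimal()
}
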