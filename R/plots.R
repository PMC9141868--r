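#' Heatmap of taxon-specific cluster enrichment
#'
#' Tiles clusters by taxa, filled by the log2 sequence-to-species
#' enrichment; taxa absent from a cluster are drawn in grey.
#'
#' @param object An [taxon_enrichment()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.or_enrichment <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$taxon_code, y = .data$cluster_id, fill = .data$enrichment
  )) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_gradient2(
      low = "#2166AC", mid = "#F7F7F7", high = "#B2182B",
      midpoint = 0, na.value = "grey85", name = "log2 seqs/species"
    ) +
    ggplot2::labs(x = "taxon", y = "cluster") +
    ggplot2::theme_minimal()
}

#' Predictive versus background conservation scatter
#'
#' One point per cluster; the diagonal marks binding sites exactly as
#' conserved as the background. Pass a `groups` vector (named by
#' cluster_id, or parallel to the rows) to colour cluster groups.
#'
#' @param object A [cluster_conservation()] result.
#' @param groups Optional grouping vector for colouring.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.or_conservation <- function(object, groups = NULL, ...) {
  d <- as_tibble(object)
  if (!is.null(groups)) {
    d$group <- if (!is.null(names(groups))) groups[d$cluster_id] else groups
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$c_bg, y = .data$c_pred)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "background conservation", y = "predictive-position conservation") +
    ggplot2::theme_minimal()
  if (is.null(groups)) {
    p + ggplot2::geom_point(alpha = 0.8)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), alpha = 0.8)
  }
}

#' Boxplot of conservation ratios for a median split
#'
#' Visualises [median_split_test()]: conservation ratios of clusters above
#' versus at-or-below the criterion median.
#'
#' @param annotations An [annotate_clusters()] result.
#' @param criterion `"social"`, `"expansion"` or `"both"`.
#' @return A ggplot object.
#' @export
plot_median_split <- function(annotations, criterion = c("social", "expansion", "both")) {
  criterion <- match.arg(criterion)
  ann <- annotations[!is.na(annotations$ratio), ]
  med_social <- median(ann$social_fraction)
  med_exp <- median(ann$expansion)
  high <- switch(criterion,
    social = ann$social_fraction > med_social,
    expansion = ann$expansion > med_exp,
    both = ann$social_fraction > med_social & ann$expansion > med_exp
  )
  d <- mutate(as_tibble(ann), group = if_else(high, "above median", "rest"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$ratio, fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = 21, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(
      x = sprintf("split by %s", criterion),
      y = "predictive / background conservation"
    ) +
    ggplot2::theme_minimal()
}

#' Cross-validated performance of the importance models
#'
#' Bar chart of best-class AUC per (dataset, chemical) model, with the 0.5
#' chance line and the feature-selection AUC gate.
#'
#' @param object An `or_importance_set` from [run_all_pairs()].
#' @param auc_min AUC gate to draw (default 0.7).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.or_importance_set <- function(object, auc_min = 0.7, ...) {
  d <- glance(object)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$chemical_id, y = .data$auc, fill = .data$dataset_id
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::geom_hline(yintercept = auc_min, linetype = "dashed", colour = "grey40") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "chemical", y = "cross-validated AUC (best class)", fill = "dataset") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
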