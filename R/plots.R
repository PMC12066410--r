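#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_hline
#'   geom_vline geom_errorbar labs theme_minimal facet_wrap
NULL

#' Stacked composition plot of a biomass profile
#'
#' @param object A `biomass_profile`.
#' @param ... Unused.
#' @return A ggplot: species percent of microbial biomass per sample.
#' @method autoplot biomass_profile
#' @export
autoplot.biomass_profile <- function(object, ...) {
  ggplot(object$percent, aes(x = .data$sample_id, y = .data$percent,
                             fill = .data$species)) +
    geom_col() +
    labs(x = NULL, y = "% of microbial species biomass", fill = "Species") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Variance-explained plot of a PERMANOVA
#'
#' @param object A [permanova()] result.
#' @param ... Unused.
#' @return A ggplot of per-factor R-squared.
#' @method autoplot permanova
#' @export
autoplot.permanova <- function(object, ...) {
  tab <- dplyr::filter(object$table, !.data$term %in% c("Total"))
  ggplot(tab, aes(x = stats::reorder(.data$term, -.data$R2), y = .data$R2)) +
    geom_col(fill = "grey35") +
    labs(x = NULL, y = expression(R^2)) +
    theme_minimal()
}

#' Ordination plot of a CLR PCA
#'
#' @param object A [clr_pca()] result.
#' @param colour Optional vector (length = samples) used for point colour.
#' @param ... Unused.
#' @return A ggplot of the first two principal components.
#' @method autoplot clr_pca
#' @export
autoplot.clr_pca <- function(object, colour = NULL, ...) {
  df <- object$scores
  pct <- 100 * object$sdev^2 / sum(object$sdev^2)
  p <- if (is.null(colour)) {
    ggplot(df, aes(x = .data$PC1, y = .data$PC2))
  } else {
    ggplot(dplyr::mutate(df, colour = colour),
           aes(x = .data$PC1, y = .data$PC2, colour = .data$colour))
  }
  p + geom_point(size = 2) +
    labs(x = sprintf("PC1 (%.1f%%)", pct[1]), y = sprintf("PC2 (%.1f%%)", pct[2])) +
    theme_minimal()
}

#' Volcano plot of differential features
#'
#' @param diff A [differential_features()] result.
#' @param q_threshold Significance line (default 0.05).
#' @return A ggplot of log2 fold-change versus -log10 p, significant
#'   features highlighted.
#' @export
plot_volcano <- function(diff, q_threshold = 0.05) {
  ggplot(diff, aes(x = .data$log2fc, y = -log10(.data$p),
                   colour = .data$significant)) +
    geom_point(alpha = 0.7) +
    geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey60")) +
    labs(x = expression(log[2] ~ "fold-change"),
         y = expression(-log[10] ~ italic(p)),
         colour = sprintf("q <= %.2g", q_threshold)) +
    theme_minimal()
}

#' Marginal-means plot for per-feature mixed models
#'
#' @param x A [fit_feature_lmm()] result.
#' @param features Optional subset of features to show.
#' @return A ggplot of per-diet marginal means with 95% confidence
#'   intervals, faceted by feature.
#' @export
plot_emmeans <- function(x, features = NULL) {
  stopifnot(inherits(x, "feature_lmm"))
  df <- x$emmeans
  if (!is.null(features)) df <- dplyr::filter(df, .data$feature %in% features)
  ggplot(df, aes(x = .data$diet, y = .data$emmean)) +
    geom_point() +
    geom_errorbar(aes(ymin = .data$lower, ymax = .data$upper), width = 0.2) +
    facet_wrap(~feature, scales = "free_y") +
    labs(x = NULL, y = "Marginal mean (95% CI)") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
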