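# ggplot2 methods for the main result objects

#' @describeIn mds_screen Autoplot: samples on the first two MDS axes,
#'   colored by a metadata factor when `colour` is supplied.
#' @param object An `mds_screen` object.
#' @param colour Optional vector (aligned with the samples) used for color.
#' @param ... Unused.
#' @export
autoplot.mds_screen <- function(object, colour = NULL, ...) {
  df <- object$coords
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data$dim2))
  if (!is.null(colour)) {
    df$colour <- colour
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data$dim2,
                                          colour = .data$colour))
  }
  p + ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "MDS dim 1", y = "MDS dim 2", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_pca Autoplot: sample scores on the first two axes.
#' @param object A `pca_model`.
#' @param colour Optional vector for point color.
#' @param ... Unused.
#' @export
autoplot.pca_model <- function(object, colour = NULL, ...) {
  df <- as_tibble(object$scores[, 1:2, drop = FALSE],
                  rownames = "sample_id")
  if (!is.null(colour)) df$colour <- colour
  pct <- round(100 * object$explained[1:2], 1)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  if (!is.null(colour)) {
    p <- p + ggplot2::aes(colour = .data$colour)
  }
  p + ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", pct[1]),
                  y = sprintf("PC2 (%.1f%%)", pct[2]), colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a candidate panel's axis correlations
#'
#' Stressor-axis correlation against confounder-axis correlation for every
#' ranked candidate, marking excluded and selected genes.
#'
#' @param candidates Tibble from [rank_candidates()].
#' @param panel Optional tibble from [select_panel()]; its genes are
#'   highlighted.
#' @return A ggplot object.
#' @export
plot_candidate_panel <- function(candidates, panel = NULL) {
  df <- candidates
  df$status <- ifelse(df$excluded, "excluded", "retained")
  if (!is.null(panel)) {
    df$status[df$gene_id %in% panel$gene_id] <- "selected"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r_axis,
                                   y = .data$r_confounder,
                                   colour = .data$status,
                                   shape = .data$direction)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::labs(x = "r with stressor axis", y = "r with confounder axis",
                  colour = NULL, shape = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a train-fit / test-projected PCA
#'
#' @param projection Result of [pca_project()].
#' @return A ggplot object, faceted by train/test set.
#' @export
plot_pca_projection <- function(projection) {
  df <- projection$scores
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  if ("label" %in% names(df)) {
    p <- p + ggplot2::aes(colour = .data$label)
  }
  p <- p + ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~set) +
    ggplot2::theme_minimal() +
    ggplot2::labs(colour = NULL)
  if (!is.null(projection$centroids)) {
    p <- p + ggplot2::geom_point(
      data = projection$centroids,
      ggplot2::aes(x = .data$PC1, y = .data$PC2, colour = .data$label),
      size = 5, shape = 18, inherit.aes = FALSE
    )
  }
  p
}
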