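# broom-style tidy()/glance() methods for fitted objects

#' Tidy an NSC model
#'
#' One row per retained gene and class: the raw and shrunken standardized
#' centroid deviations and the shrunken centroid.
#'
#' @param x An [nsc_fit()] model.
#' @param ... Unused.
#' @return A tibble: gene_id, class, d, d_shrunk, shrunken_centroid.
#' @export
tidy.nsc_model <- function(x, ...) {
  df <- tidyr::expand_grid(gene_id = rownames(x$d), class = x$classes)
  df$d <- as.vector(t(x$d))
  df$d_shrunk <- as.vector(t(x$dprime))
  df$shrunken_centroid <- as.vector(t(x$shrunk_centroids))
  dplyr::filter(df, .data$gene_id %in% x$genes)
}

#' @rdname tidy.nsc_model
#' @export
glance.nsc_model <- function(x, ...) {
  tibble(
    n_genes = nrow(x$d), n_selected = length(x$genes),
    delta = x$delta, cv_folds = x$cv_folds,
    min_cv_errors = min(x$cv_errors), s0 = x$s0
  )
}

#' Tidy an LDA model
#'
#' @param x An [lda_fit()] model.
#' @param ... Unused.
#' @return A tibble: gene_id, the two class means, and the discriminant
#'   coefficient (direction of class 2 minus class 1).
#' @export
tidy.lda_model <- function(x, ...) {
  tibble(
    gene_id = x$genes,
    mean_1 = x$means[, 1], mean_2 = x$means[, 2],
    coefficient = x$direction
  )
}

#' @rdname tidy.lda_model
#' @export
glance.lda_model <- function(x, ...) {
  tibble(n_genes = length(x$genes), gamma = x$gamma,
         prior_1 = x$priors[1], prior_2 = x$priors[2])
}

#' Tidy a PCA model
#'
#' @param x A [fit_pca()] model.
#' @param ... Unused.
#' @return Long tibble of sample scores: sample_id, axis, score.
#' @export
tidy.pca_model <- function(x, ...) {
  as_tibble(x$scores, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "axis",
                        values_to = "score")
}

#' @rdname tidy.pca_model
#' @export
glance.pca_model <- function(x, ...) {
  tibble(n_genes = nrow(x$loadings), n_samples = nrow(x$scores),
         n_axes = ncol(x$scores), var_pc1 = x$explained[1],
         var_pc2 = if (length(x$explained) > 1) x$explained[2] else NA_real_)
}

#' Tidy a split report
#'
#' @param x An [evaluate_split()] report.
#' @param ... Unused.
#' @return Tibble of per-class accuracies plus the unweighted average row.
#' @export
tidy.split_report <- function(x, ...) {
  dplyr::bind_rows(
    x$class_accuracy,
    tibble(class = "average", accuracy = x$average_accuracy)
  )
}

#' @rdname tidy.split_report
#' @export
glance.split_report <- function(x, ...) {
  tibble(n_train = x$n_train, n_test = x$n_test,
         n_genes_selected = length(x$genes),
         average_accuracy = x$average_accuracy)
}
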