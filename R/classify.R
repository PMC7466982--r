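# Panel validation: stratified train/test splits, nearest-shrunken-centroid
# gene selection with internal cross-validation, regularized two-class LDA,
# train-fit/test-project PCA, and cross-platform fold-change correlation.

#' Stratified train/test split
#'
#' Splits samples into a training and a testing set, preserving class
#' proportions: each class contributes `round(train_fraction * n_k)`
#' samples to training (at least one sample per class on each side).
#'
#' @param sample_ids Character vector of sample ids.
#' @param labels Class label per sample.
#' @param train_fraction Fraction assigned to training (default 2/3).
#' @param seed Integer seed.
#' @return List with `train` and `test` id vectors (disjoint, exhaustive).
#' @export
stratified_split <- function(sample_ids, labels, train_fraction = 2 / 3,
                             seed = 1L) {
  if (length(sample_ids) != length(labels)) {
    abort("`sample_ids` and `labels` lengths differ.")
  }
  tab <- table(labels)
  if (any(tab < 2)) {
    abort(sprintf("class '%s' has fewer than 2 samples.",
                  names(tab)[which.min(tab)]))
  }
  set.seed(seed)
  train <- character(0)
  for (cl in names(tab)) {
    ids <- sample_ids[labels == cl]
    n_tr <- round(train_fraction * length(ids))
    n_tr <- min(max(n_tr, 1), length(ids) - 1)
    train <- c(train, sample(ids, n_tr))
  }
  list(train = train, test = setdiff(sample_ids, train))
}

# core NSC statistics for a genes x samples matrix
nsc_stats <- function(x, labels, s0 = NULL,
                      size_factor = c("minus", "plus")) {
  size_factor <- match.arg(size_factor)
  classes <- sort(unique(labels))
  n <- ncol(x)
  K <- length(classes)
  nk <- vapply(classes, function(k) sum(labels == k), numeric(1))
  xbar <- rowMeans(x, na.rm = TRUE)
  centroids <- matrix(
    vapply(classes, function(k) {
      rowMeans(x[, labels == k, drop = FALSE], na.rm = TRUE)
    }, numeric(nrow(x))),
    nrow = nrow(x), dimnames = list(rownames(x), classes)
  )
  ss <- 0
  for (k in seq_along(classes)) {
    xk <- x[, labels == classes[k], drop = FALSE]
    ss <- ss + rowSums((xk - centroids[, k])^2, na.rm = TRUE)
  }
  n_obs <- rowSums(!is.na(x))
  s <- sqrt(ss / pmax(n_obs - K, 1))
  if (is.null(s0)) s0 <- median(s)
  mk <- if (size_factor == "minus") sqrt(1 / nk - 1 / n) else sqrt(1 / nk + 1 / n)
  d <- sweep(centroids - xbar, 1, s + s0, "/")
  d <- sweep(d, 2, mk, "/")
  list(classes = classes, n = n, nk = nk, priors = nk / n, xbar = xbar,
       centroids = centroids, s = s, s0 = s0, mk = mk, d = d)
}

# soft-threshold the statistics at delta, yielding shrunken centroids
nsc_shrink <- function(st, delta) {
  dprime <- sign(st$d) * pmax(abs(st$d) - delta, 0)
  shrunk <- st$xbar + sweep(sweep(dprime, 2, st$mk, "*"), 1,
                            st$s + st$s0, "*")
  list(dprime = dprime, shrunk_centroids = shrunk,
       genes = rownames(st$d)[rowSums(dprime != 0) > 0])
}

# predict labels for a fitted set of shrunken centroids
nsc_score <- function(newx, st, shrunk) {
  w <- (st$s + st$s0)^2
  scores <- vapply(seq_along(st$classes), function(k) {
    diff2 <- (newx - shrunk$shrunk_centroids[, k])^2 / w
    colSums(diff2, na.rm = TRUE) - 2 * log(st$priors[k])
  }, numeric(ncol(newx)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = ncol(newx))
  colnames(scores) <- st$classes
  rownames(scores) <- colnames(newx)
  scores
}

#' Fit a nearest-shrunken-centroid classifier
#'
#' Standardized class-centroid deviations
#' `d_ik = (xbar_ik - xbar_i) / (m_k (s_i + s0))` are soft-thresholded at
#' `Delta`, zeroing uninformative genes; `Delta` is chosen by stratified
#' internal cross-validation over a grid from 0 to `max|d_ik|`, taking the
#' largest threshold (fewest genes) among the error minimizers. Here `s_i`
#' is the pooled within-class SD, `s0` the median of the `s_i`, and
#' `m_k = sqrt(1/n_k - 1/n)` (the exact variance factor for a class
#' centroid minus the overall centroid; `sqrt(1/n_k + 1/n)` is available
#' via `size_factor = "plus"`).
#'
#' @param x Genes x samples expression matrix (training set).
#' @param labels Class label per training sample.
#' @param cv_folds Cross-validation folds (default 5; reduced with a
#'   warning if a class is smaller).
#' @param n_thresholds Size of the threshold grid (default 30).
#' @param seed Seed for fold assignment.
#' @param size_factor `"minus"` (default) or `"plus"` class-size constant.
#' @return Object of class `nsc_model`, including the chosen `delta`,
#'   selected `genes`, the threshold/CV-error grid, and all centroid
#'   statistics.
#' @export
nsc_fit <- function(x, labels, cv_folds = 5, n_thresholds = 30, seed = 1L,
                    size_factor = c("minus", "plus")) {
  size_factor <- match.arg(size_factor)
  if (length(labels) != ncol(x)) abort("`labels` must match the samples.")
  tab <- table(labels)
  if (length(tab) < 2 || any(tab < 2)) {
    abort("need >= 2 classes with >= 2 samples each.")
  }
  if (cv_folds > min(tab)) {
    warn(sprintf("reducing cv_folds from %d to smallest class size %d.",
                 cv_folds, min(tab)))
    cv_folds <- min(tab)
  }
  st <- nsc_stats(x, labels, size_factor = size_factor)
  grid <- seq(0, max(abs(st$d)), length.out = n_thresholds)

  set.seed(seed)
  fold <- integer(ncol(x))
  for (cl in names(tab)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(cv_folds), length(idx)))
  }
  cv_err <- numeric(length(grid))
  for (f in seq_len(cv_folds)) {
    tr <- fold != f
    st_f <- nsc_stats(x[, tr, drop = FALSE], labels[tr],
                      size_factor = size_factor)
    for (j in seq_along(grid)) {
      shr <- nsc_shrink(st_f, grid[j])
      sc <- nsc_score(x[, !tr, drop = FALSE], st_f, shr)
      pred <- st_f$classes[apply(sc, 1, which.min)]
      cv_err[j] <- cv_err[j] + sum(pred != labels[!tr])
    }
  }
  best <- which(cv_err == min(cv_err))
  delta <- grid[max(best)]
  shr <- nsc_shrink(st, delta)
  structure(
    c(st, shr,
      list(delta = delta, grid = grid, cv_errors = cv_err,
           cv_folds = cv_folds, size_factor = size_factor)),
    class = "nsc_model"
  )
}

#' @export
print.nsc_model <- function(x, ...) {
  cat("Nearest shrunken centroid:", length(x$classes), "classes,",
      nrow(x$d), "genes; Delta =", signif(x$delta, 4), "->",
      length(x$genes), "selected gene(s)\n")
  invisible(x)
}

#' Predict classes with a fitted NSC model
#'
#' Assigns each sample to the class minimizing the standardized distance
#' to the shrunken centroid penalized by the prior,
#' `sum_i (x_i - xbar'_ik)^2 / (s_i + s0)^2 - 2 log pi_k`. Ties break to
#' the lexicographically first class; missing gene values are dropped from
#' that sample's score with a warning.
#'
#' @param model An [nsc_fit()] model.
#' @param newx Genes x samples matrix with the model's genes as rows.
#' @return List: `class` (predicted label per sample) and `scores`
#'   (samples x classes discriminant matrix).
#' @export
nsc_predict <- function(model, newx) {
  stopifnot(inherits(model, "nsc_model"))
  if (is.null(dim(newx))) newx <- matrix(newx, ncol = 1,
                                         dimnames = list(names(newx), "s1"))
  missing_genes <- setdiff(rownames(model$d), rownames(newx))
  if (length(missing_genes) > 0) {
    abort("`newx` lacks genes present in the model.")
  }
  newx <- newx[rownames(model$d), , drop = FALSE]
  if (anyNA(newx)) {
    warn("missing expression values dropped from the discriminant score.")
  }
  scores <- nsc_score(newx, model, model)
  pred <- model$classes[apply(scores, 1, which.min)]
  list(class = setNames(pred, colnames(newx)), scores = scores)
}

#' Fit / predict a regularized two-class linear discriminant
#'
#' Fisher LDA on the selected genes: class means, pooled within-class
#' covariance regularized as `S + gamma I` (default
#' `gamma = 1e-6 * trace(S) / p`), priors equal to class proportions.
#'
#' @param x Genes x samples training matrix.
#' @param labels Class label per training sample.
#' @param gamma Ridge added to the pooled covariance diagonal; `NULL` for
#'   the default.
#' @return Object of class `lda_model` with means, inverse covariance,
#'   discriminant vector (class 2 minus class 1) and priors.
#' @export
lda_fit <- function(x, labels, gamma = NULL) {
  if (length(labels) != ncol(x)) abort("`labels` must match the samples.")
  classes <- sort(unique(labels))
  if (length(classes) != 2) abort("two-class LDA requires exactly 2 classes.")
  nk <- vapply(classes, function(k) sum(labels == k), numeric(1))
  if (any(nk < 2)) abort("each class needs >= 2 training samples.")
  p <- nrow(x)
  means <- matrix(
    vapply(classes, function(k) {
      rowMeans(x[, labels == k, drop = FALSE])
    }, numeric(p)),
    nrow = p, dimnames = list(rownames(x), classes)
  )
  scatter <- matrix(0, p, p)
  for (k in seq_along(classes)) {
    xk <- x[, labels == classes[k], drop = FALSE] - means[, k]
    scatter <- scatter + tcrossprod(xk)
  }
  S <- scatter / (ncol(x) - 2)
  if (is.null(gamma)) gamma <- 1e-6 * sum(diag(S)) / p
  Sreg <- S + diag(gamma, p)
  Sinv <- tryCatch(solve(Sreg), error = function(e) {
    abort("pooled covariance is singular; increase `gamma`.")
  })
  structure(
    list(classes = classes, means = means, Sinv = Sinv, gamma = gamma,
         priors = nk / sum(nk),
         direction = as.vector(Sinv %*% (means[, 2] - means[, 1])),
         genes = rownames(x)),
    class = "lda_model"
  )
}

#' @rdname lda_fit
#' @param model An `lda_model`.
#' @param newx Genes x samples matrix.
#' @export
lda_predict <- function(model, newx) {
  stopifnot(inherits(model, "lda_model"))
  if (is.null(dim(newx))) newx <- matrix(newx, ncol = 1)
  newx <- newx[model$genes, , drop = FALSE]
  scores <- vapply(seq_along(model$classes), function(k) {
    mu <- model$means[, k]
    a <- model$Sinv %*% mu
    as.vector(crossprod(newx, a)) - 0.5 * sum(mu * a) + log(model$priors[k])
  }, numeric(ncol(newx)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = ncol(newx))
  colnames(scores) <- model$classes
  pred <- model$classes[apply(scores, 1, which.max)]
  list(class = setNames(pred, colnames(newx)), scores = scores)
}

#' Evaluate a biomarker panel on one train/test split
#'
#' Runs the two-stage validation used for small qPCR panels: NSC gene
#' selection (with internal CV) on the training set, LDA on the selected
#' genes, prediction of the held-out test set, and a report of the
#' confusion table, per-class accuracies and their unweighted average.
#' If NSC shrinks every gene away, all genes are used for the LDA with a
#' warning.
#'
#' @param expr Genes x samples expression matrix.
#' @param labels Named class labels (names = sample ids) or a vector
#'   aligned with `colnames(expr)`.
#' @param split List with `train`/`test` ids (see [stratified_split()]).
#' @param cv_folds,n_thresholds,seed Passed to [nsc_fit()].
#' @param gamma Passed to [lda_fit()].
#' @return Object of class `split_report`: `confusion` (rows = real,
#'   columns = predicted), `class_accuracy` tibble (with `average` as the
#'   unweighted mean of per-class accuracies, in percent), `genes`
#'   (NSC-selected), and the fitted models.
#' @export
evaluate_split <- function(expr, labels, split, cv_folds = 5,
                           n_thresholds = 30, seed = 1L, gamma = NULL) {
  if (is.null(names(labels))) names(labels) <- colnames(expr)
  tr_x <- expr[, split$train, drop = FALSE]
  te_x <- expr[, split$test, drop = FALSE]
  tr_y <- labels[split$train]
  te_y <- labels[split$test]
  nsc <- nsc_fit(tr_x, tr_y, cv_folds = cv_folds,
                 n_thresholds = n_thresholds, seed = seed)
  genes <- nsc$genes
  if (length(genes) == 0) {
    warn("NSC selected no genes; using the full panel for the LDA.")
    genes <- rownames(expr)
  }
  tr_sel <- tr_x[genes, , drop = FALSE]
  te_sel <- te_x[genes, , drop = FALSE]
  if (anyNA(tr_sel) || anyNA(te_sel)) {
    warn("imputing missing expression values with training gene means.")
    fill <- rowMeans(tr_sel, na.rm = TRUE)
    tr_sel[is.na(tr_sel)] <- fill[row(tr_sel)[is.na(tr_sel)]]
    te_sel[is.na(te_sel)] <- fill[row(te_sel)[is.na(te_sel)]]
  }
  lda <- lda_fit(tr_sel, tr_y, gamma = gamma)
  pred <- lda_predict(lda, te_sel)$class
  classes <- sort(unique(labels))
  confusion <- table(
    real = factor(te_y, levels = classes),
    predicted = factor(pred, levels = classes)
  )
  per_class <- 100 * diag(confusion) / rowSums(confusion)
  empty <- rowSums(confusion) == 0
  if (any(empty)) {
    warn(sprintf("test set has no '%s' samples; accuracy undefined.",
                 paste(classes[empty], collapse = ", ")))
  }
  structure(
    list(
      confusion = confusion,
      class_accuracy = tibble(class = classes,
                              accuracy = unname(per_class)),
      average_accuracy = mean(per_class[!empty]),
      genes = genes, nsc = nsc, lda = lda,
      n_train = length(split$train), n_test = length(split$test)
    ),
    class = "split_report"
  )
}

#' @export
print.split_report <- function(x, ...) {
  cat("Split report:", x$n_train, "train /", x$n_test, "test;",
      length(x$genes), "gene(s) selected\n")
  print(x$confusion)
  cat("per-class accuracy (%):",
      paste(sprintf("%s %.1f", x$class_accuracy$class,
                    x$class_accuracy$accuracy), collapse = ", "),
      "| average", sprintf("%.1f", x$average_accuracy), "\n")
  invisible(x)
}

#' PCA fitted on training samples and projected onto test samples
#'
#' Centers and unit-scales each gene using training statistics only, fits
#' the PCA on the training samples, and projects the test samples with the
#' training loadings — the standard guard against information leaking from
#' test to train in validation figures.
#'
#' @param train_expr,test_expr Genes x samples matrices sharing gene rows.
#' @param genes Optional subset of genes (e.g. NSC-selected).
#' @param labels Optional named class labels; adds group centroids.
#' @return List: `scores` tibble (sample_id, set = train/test, PC1, PC2),
#'   `centroids` tibble (or NULL), `explained`, and the `pca_model`.
#' @export
pca_project <- function(train_expr, test_expr, genes = NULL, labels = NULL) {
  if (!is.null(genes)) {
    train_expr <- train_expr[genes, , drop = FALSE]
    test_expr <- test_expr[genes, , drop = FALSE]
  }
  scl <- apply(train_expr, 1, sd)
  keep <- scl > 0
  if (!all(keep)) {
    warn(sprintf("dropping %d constant gene(s) from the projection.",
                 sum(!keep)))
    train_expr <- train_expr[keep, , drop = FALSE]
    test_expr <- test_expr[keep, , drop = FALSE]
  }
  model <- fit_pca(train_expr)
  z_test <- (test_expr[rownames(model$loadings), , drop = FALSE] -
               model$center) / model$scale
  test_scores <- t(z_test) %*% model$loadings
  k <- min(2, ncol(model$scores))
  mk_tbl <- function(sc, set) {
    out <- tibble(sample_id = rownames(sc), set = set)
    for (j in seq_len(k)) out[[paste0("PC", j)]] <- sc[, j]
    out
  }
  scores <- dplyr::bind_rows(mk_tbl(model$scores, "train"),
                             mk_tbl(test_scores, "test"))
  centroids <- NULL
  if (!is.null(labels)) {
    scores$label <- labels[scores$sample_id]
    centroids <- dplyr::summarise(
      dplyr::group_by(scores, .data$set, .data$label),
      dplyr::across(dplyr::starts_with("PC"), mean), .groups = "drop"
    )
  }
  list(scores = scores, centroids = centroids,
       explained = model$explained[seq_len(k)], model = model)
}

#' Correlation between RNA-seq and qPCR expression values
#'
#' Pools gene-sample pairs across platforms for an overall Pearson
#' correlation, and computes a per-gene correlation across samples; genes
#' with per-gene `p < alpha` are flagged concordant.
#'
#' @param rnaseq,qpcr Genes x samples matrices with matching dimnames
#'   (e.g. per-sample log2 fold changes on each platform).
#' @param alpha Per-gene concordance threshold (default 0.05).
#' @return List: `overall` tibble (r, p, n) and `per_gene` tibble
#'   (gene_id, r, p, n, concordant).
#' @export
cross_platform_correlation <- function(rnaseq, qpcr, alpha = 0.05) {
  genes <- intersect(rownames(rnaseq), rownames(qpcr))
  samples <- intersect(colnames(rnaseq), colnames(qpcr))
  if (length(genes) == 0 || length(samples) < 3) {
    abort("need shared genes and >= 3 shared samples.")
  }
  x <- rnaseq[genes, samples, drop = FALSE]
  y <- qpcr[genes, samples, drop = FALSE]
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) abort("fewer than 3 finite paired observations.")
  ct <- stats::cor.test(x[ok], y[ok])
  per_gene <- purrr::map_dfr(genes, function(g) {
    gi <- ok[g, ]
    n <- sum(gi)
    if (n < 3 || sd(x[g, gi]) == 0 || sd(y[g, gi]) == 0) {
      return(tibble(gene_id = g, r = NA_real_, p = NA_real_, n = n,
                    concordant = NA))
    }
    gt <- stats::cor.test(x[g, gi], y[g, gi])
    tibble(gene_id = g, r = unname(gt$estimate), p = gt$p.value, n = n,
           concordant = gt$p.value < alpha)
  })
  list(
    overall = tibble(r = unname(ct$estimate), p = ct$p.value, n = sum(ok)),
    per_gene = per_gene
  )
}
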