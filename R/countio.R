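#' Read / write a gene-by-sample count matrix
#'
#' The on-disk format is a TSV whose first column is `gene_id` and whose
#' remaining columns are samples. Reading validates the matrix: ids must be
#' unique, entries numeric and nonnegative, rows rectangular.
#'
#' @param path File path.
#' @return `read_counts()` returns an integer-valued numeric matrix with gene
#'   rownames and sample colnames.
#' @export
read_counts <- function(path) {
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  if (anyDuplicated(header)) abort("duplicate sample ids in count file.")
  df <- suppressWarnings(readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE))
  if (!"gene_id" %in% names(df) || ncol(df) < 2) {
    abort("count file must have a `gene_id` column followed by sample columns.")
  }
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(sprintf("malformed count file: %d parsing problem(s), first at row %d.",
                  nrow(probs), probs$row[1]))
  }
  if (anyDuplicated(df$gene_id)) abort("duplicate gene ids in count file.")
  if (anyDuplicated(names(df))) abort("duplicate sample ids in count file.")
  m <- as.matrix(df[, -1])
  rownames(m) <- df$gene_id
  check_count_matrix(m, arg = path)
  m
}

#' @rdname read_counts
#' @param m Count matrix.
#' @export
write_counts <- function(m, path) {
  check_count_matrix(m)
  df <- tibble::as_tibble(m, rownames = "gene_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Counts per million
#'
#' Scales each count by its sample's effective library size (library size
#' times normalization factor) and multiplies by one million.
#'
#' @param m Count matrix.
#' @param factors Optional normalization factors ([tmm_factors()] tibble or a
#'   named vector); `NULL` means unit factors.
#' @param log If `TRUE`, return log2(cpm) with a prior count (delegated to
#'   [edgeR::cpm()] for the standard moderated log).
#' @param prior_count Prior count used when `log = TRUE`.
#' @return Real matrix, same shape as `m`.
#' @export
cpm <- function(m, factors = NULL, log = FALSE, prior_count = 2) {
  check_count_matrix(m)
  eff <- effective_lib_sizes(m, factors)
  if (any(eff <= 0)) abort("zero library size.")
  if (log) {
    f <- resolve_factors(m, factors)
    return(edgeR::cpm(m, lib.size = lib_sizes(m) * f, log = TRUE,
                      prior.count = prior_count))
  }
  sweep(m, 2, eff, "/") * 1e6
}

#' Filter genes with low expression
#'
#' Removes a gene when its cpm is below `cpm_threshold` in at least
#' `min_samples` samples. The default threshold corresponds to 5 reads in
#' the sample with the smallest library (0.4 cpm at a 12.5-million-read
#' minimum depth) and the default `min_samples` is half the samples,
#' rounded up.
#'
#' @param m Count matrix.
#' @param cpm_threshold Cpm below which a gene is "not expressed" in a
#'   sample; default `1e6 * 5 / min(lib_sizes(m))`.
#' @param min_samples Number of below-threshold samples at which a gene is
#'   removed; default `ceiling(ncol(m) / 2)`.
#' @return The filtered count matrix.
#' @export
filter_low_expression <- function(m, cpm_threshold = NULL, min_samples = NULL) {
  check_count_matrix(m)
  n <- ncol(m)
  if (is.null(cpm_threshold)) cpm_threshold <- 1e6 * 5 / min(lib_sizes(m))
  if (is.null(min_samples)) min_samples <- ceiling(n / 2)
  if (min_samples <= 0 || min_samples > n) {
    abort("`min_samples` must be in 1..n_samples.")
  }
  below <- rowSums(cpm(m) < cpm_threshold)
  keep <- below < min_samples
  if (!any(keep)) warn("all genes removed by the expression filter.")
  m[keep, , drop = FALSE]
}

#' Trimmed-mean-of-M-values normalization factors
#'
#' Composition-bias normalization: each sample's factor is a weighted mean of
#' gene-wise log2 ratios to a reference sample, after trimming the most
#' extreme 30% of log-ratios and 5% of average abundances; factors are
#' rescaled to geometric mean 1. The reference is the sample whose
#' upper-quartile cpm is closest to the mean upper-quartile. Computation is
#' delegated to [edgeR::calcNormFactors()].
#'
#' @param m Count matrix with at least two samples.
#' @return Tibble with `sample_id`, `lib_size`, `norm_factor`,
#'   `effective_lib_size`.
#' @export
tmm_factors <- function(m) {
  check_count_matrix(m)
  if (ncol(m) < 2) abort("TMM needs at least two samples.")
  if (any(colSums(m) == 0)) abort("sample with no nonzero gene.")
  f <- edgeR::calcNormFactors(m, method = "TMM")
  tibble(
    sample_id = colnames(m),
    lib_size = lib_sizes(m),
    norm_factor = unname(f),
    effective_lib_size = lib_sizes(m) * unname(f)
  )
}

#' Multi-dimensional scaling screen of sample factors
#'
#' Embeds samples by classical metric MDS of pairwise expression distances
#' and reports how strongly each metadata factor associates with each axis,
#' to screen which factors dominate overall expression. The distance between
#' two samples is the root-mean-square of the `top_genes` largest absolute
#' log2-cpm differences for that pair (the leading-fold-change convention).
#'
#' @param m Count matrix (typically filtered).
#' @param meta Sample metadata tibble with a `sample_id` column matching
#'   `colnames(m)`; every other column is screened as a factor.
#' @param top_genes Genes per pair entering the distance (default 500).
#' @param n_dims Number of MDS axes (default 2).
#' @param factors Optional normalization factors for the cpm.
#' @return Object of class `mds_screen`: list with `coords` (tibble
#'   sample_id, dim1..), `associations` (tibble factor, axis, association),
#'   `dist` (the distance matrix), `eig` (MDS eigenvalues).
#' @export
mds_screen <- function(m, meta, top_genes = 500, n_dims = 2, factors = NULL) {
  check_count_matrix(m)
  n <- ncol(m)
  if (n < 3) abort("MDS screen needs at least 3 samples.")
  if (!all(colnames(m) %in% meta$sample_id)) {
    abort("`meta` is missing samples present in the count matrix.")
  }
  meta <- meta[match(colnames(m), meta$sample_id), ]
  if (top_genes > nrow(m)) {
    warn("`top_genes` exceeds the number of genes; using all genes.")
    top_genes <- nrow(m)
  }
  lcpm <- cpm(m, factors = factors, log = TRUE)
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dd <- sort((lcpm[, i] - lcpm[, j])^2, decreasing = TRUE)[seq_len(top_genes)]
      d[i, j] <- d[j, i] <- sqrt(mean(dd))
    }
  }
  n_dims <- min(n_dims, n - 1)
  fit <- cmdscale(stats::as.dist(d), k = n_dims, eig = TRUE)
  coords <- fit$points
  colnames(coords) <- paste0("dim", seq_len(ncol(coords)))
  factor_cols <- setdiff(names(meta), "sample_id")
  assoc <- tidyr::expand_grid(factor = factor_cols, axis = seq_len(ncol(coords)))
  assoc$association <- purrr::map2_dbl(
    assoc$factor, assoc$axis,
    function(f, a) axis_association(coords[, a], meta[[f]])
  )
  structure(
    list(
      coords = dplyr::bind_cols(tibble(sample_id = colnames(m)),
                                as_tibble(coords)),
      associations = as_tibble(assoc),
      dist = d,
      eig = fit$eig
    ),
    class = "mds_screen"
  )
}

#' @export
print.mds_screen <- function(x, ...) {
  cat("MDS screen:", nrow(x$coords), "samples,",
      ncol(x$coords) - 1, "axes\n")
  top <- dplyr::slice_max(
    dplyr::group_by(x$associations, .data$factor),
    .data$association, n = 1, with_ties = FALSE
  )
  print(as_tibble(top), n = Inf)
  invisible(x)
}
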