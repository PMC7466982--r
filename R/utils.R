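# internal helpers shared across modules

# counts must be a numeric matrix with unique gene/sample dimnames
check_count_matrix <- function(m, arg = "m") {
  if (!is.matrix(m) || !is.numeric(m)) {
    abort(sprintf("`%s` must be a numeric gene-by-sample matrix.", arg))
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    abort(sprintf("`%s` must have gene rownames and sample colnames.", arg))
  }
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    abort(sprintf("`%s` has duplicated gene or sample ids.", arg))
  }
  if (anyNA(m)) abort(sprintf("`%s` contains missing values.", arg))
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "negative count for gene '%s' in sample '%s'.",
      rownames(m)[bad[1]], colnames(m)[bad[2]]
    ))
  }
  invisible(m)
}

#' Library sizes of a count matrix
#'
#' Per-sample total counts (column sums).
#'
#' @param m Numeric gene-by-sample count matrix.
#' @return Named numeric vector of library sizes.
#' @export
lib_sizes <- function(m) {
  check_count_matrix(m)
  colSums(m)
}

# resolve norm factors given either NULL, a named vector, or the tibble
# returned by tmm_factors(); returns a vector aligned with colnames(m)
resolve_factors <- function(m, factors) {
  samples <- colnames(m)
  if (is.null(factors)) {
    return(setNames(rep(1, length(samples)), samples))
  }
  if (is.data.frame(factors)) {
    f <- setNames(factors$norm_factor, factors$sample_id)
  } else {
    f <- factors
  }
  if (is.null(names(f)) && length(f) == length(samples)) names(f) <- samples
  if (!all(samples %in% names(f))) {
    abort("normalization factors do not cover every sample in `m`.")
  }
  f <- f[samples]
  if (any(!is.finite(f)) || any(f <= 0)) abort("normalization factors must be positive.")
  f
}

# effective library sizes = lib size * norm factor
effective_lib_sizes <- function(m, factors = NULL) {
  lib_sizes(m) * resolve_factors(m, factors)
}

# Pearson correlation of each row of x with vector y, plus two-sided p
# from the t distribution (n - 2 df); vectorized
row_cor_test <- function(x, y) {
  n <- length(y)
  xc <- x - rowMeans(x)
  yc <- y - mean(y)
  sx <- sqrt(rowSums(xc^2))
  sy <- sqrt(sum(yc^2))
  r <- as.vector(xc %*% yc) / (sx * sy)
  r <- pmin(1, pmax(-1, r))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  tibble(r = r, p = p)
}

# sqrt of lm R-squared of axis ~ factor: |point-biserial| for 2-level
# factors, multiple-correlation ratio for >2 levels
axis_association <- function(scores, f) {
  f <- as.factor(f)
  if (nlevels(f) < 2 || var(scores) == 0) return(0)
  fit <- lm(scores ~ f)
  r2 <- summary(fit)$r.squared
  sqrt(max(0, r2))
}
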