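# qPCR quantification: amplification efficiency from serial dilutions,
# reference-gene stability (NormFinder-style variance decomposition) and
# delta-delta-Ct relative expression.

#' Construct a Ct matrix object
#'
#' Bundles an assay-by-sample Ct matrix with its designated housekeeping
#' assay and inter-array calibrator sample. Ct values at or above the
#' instrument ceiling are treated as missing (non-amplification is not a
#' measurement).
#'
#' @param ct Numeric matrix, assays x samples; `NA` allowed.
#' @param housekeeping Row id of the housekeeping assay.
#' @param calibrator Column id of the calibrator sample.
#' @param ceiling Ct at or above which values are set missing (default 40).
#' @return Object of class `ct_matrix`.
#' @export
ct_matrix <- function(ct, housekeeping, calibrator, ceiling = 40) {
  if (!is.matrix(ct) || is.null(rownames(ct)) || is.null(colnames(ct))) {
    abort("`ct` must be a matrix with assay rownames and sample colnames.")
  }
  if (!housekeeping %in% rownames(ct)) {
    abort("housekeeping assay not found in the Ct matrix.")
  }
  if (!calibrator %in% colnames(ct)) {
    abort("calibrator sample not found in the Ct matrix.")
  }
  if (any(ct <= 0, na.rm = TRUE)) abort("Ct values must be positive.")
  ct[!is.na(ct) & ct >= ceiling] <- NA_real_
  structure(list(ct = ct, housekeeping = housekeeping,
                 calibrator = calibrator),
            class = "ct_matrix")
}

#' @export
print.ct_matrix <- function(x, ...) {
  cat("Ct matrix:", nrow(x$ct), "assays x", ncol(x$ct), "samples;",
      "housekeeping =", x$housekeeping, "; calibrator =", x$calibrator, "\n")
  invisible(x)
}

#' Read / write a Ct matrix as CSV
#'
#' CSV with assays as rows (first column `assay_id`); the housekeeping
#' assay and calibrator sample are recorded in `#`-prefixed header comment
#' lines so the file is self-describing.
#'
#' @param path File path.
#' @return `read_ct()` returns a [ct_matrix()].
#' @export
read_ct <- function(path) {
  lines <- readLines(path, n = 10)
  grab <- function(key) {
    hit <- grep(paste0("^#\\s*", key, ":"), lines, value = TRUE)
    if (length(hit) == 0) abort(sprintf("Ct file lacks a '# %s:' header.", key))
    trimws(sub(paste0("^#\\s*", key, ":"), "", hit[1]))
  }
  hk <- grab("housekeeping")
  cal <- grab("calibrator")
  df <- readr::read_csv(path, comment = "#", col_types = readr::cols(
    assay_id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$assay_id
  ct_matrix(m, housekeeping = hk, calibrator = cal)
}

#' @rdname read_ct
#' @param x A [ct_matrix()].
#' @export
write_ct <- function(x, path) {
  stopifnot(inherits(x, "ct_matrix"))
  df <- tibble::as_tibble(x$ct, rownames = "assay_id")
  body <- strsplit(readr::format_csv(df), "\n", fixed = TRUE)[[1]]
  writeLines(c(
    paste("# housekeeping:", x$housekeeping),
    paste("# calibrator:", x$calibrator),
    body
  ), path)
  invisible(path)
}

#' Amplification efficiency from a serial-dilution standard curve
#'
#' Ordinary least squares of Ct on log10(dilution); the per-cycle
#' amplification efficiency is `E = 10^(-1/slope) - 1`, so a perfect
#' doubling gives slope -3.3219 and E = 1 (100%). The slope must be
#' negative (Ct rises as template dilutes); otherwise the fit is flagged
#' invalid.
#'
#' @param dilution Positive relative template amounts (e.g. `5^-(1:5)` for
#'   a 1/5 ... 1/625 series).
#' @param ct Observed Ct per dilution.
#' @return Tibble: slope, efficiency, r_squared, n, valid.
#' @export
pcr_efficiency <- function(dilution, ct) {
  if (length(dilution) != length(ct)) abort("`dilution` and `ct` lengths differ.")
  ok <- !is.na(dilution) & !is.na(ct)
  dilution <- dilution[ok]
  ct <- ct[ok]
  if (length(ct) < 3) abort("need at least 3 dilution points.")
  if (any(dilution <= 0)) abort("dilutions must be positive.")
  fit <- lm(ct ~ log10(dilution))
  slope <- unname(stats::coef(fit)[2])
  valid <- is.finite(slope) && slope < 0
  # a perfect standard curve triggers lm's perfect-fit warning; that is a
  # legitimate input here, not a problem
  r2 <- suppressWarnings(summary(fit)$r.squared)
  tibble(
    slope = slope,
    efficiency = if (valid) 10^(-1 / slope) - 1 else NA_real_,
    r_squared = r2,
    n = length(ct),
    valid = valid
  )
}

#' Reference-gene stability by variance decomposition
#'
#' For each candidate reference assay, decomposes its Ct values into
#' inter-group bias and intra-group variance: with group means deviating by
#' `delta_k` from the candidate's grand mean and within-group variance
#' `sigma2_k` over `n_k` samples, the stability value is
#' `mean_k(|delta_k| + sqrt(sigma2_k / n_k))`. Lower is more stable; the
#' minimum-stability candidate is flagged as the recommended reference.
#' Candidates missing in more than half of any group are excluded.
#'
#' @param x A [ct_matrix()].
#' @param groups Group label per sample (calibrator column ignored).
#' @param candidates Assay ids to evaluate (default: all assays).
#' @return Tibble: assay_id, stability, recommended — ascending stability.
#' @export
reference_stability <- function(x, groups, candidates = NULL) {
  stopifnot(inherits(x, "ct_matrix"))
  ct <- x$ct[, setdiff(colnames(x$ct), x$calibrator), drop = FALSE]
  if (length(groups) != ncol(ct)) {
    abort("`groups` must label every non-calibrator sample.")
  }
  if (is.null(candidates)) candidates <- rownames(ct)
  glev <- unique(groups)
  if (length(glev) < 2 || any(table(groups) < 2)) {
    abort("need >= 2 groups with >= 2 samples each.")
  }
  one <- function(a) {
    y <- ct[a, ]
    miss_by_group <- vapply(glev, function(g) mean(is.na(y[groups == g])),
                            numeric(1))
    if (any(miss_by_group > 0.5)) return(NA_real_)
    grand <- mean(y, na.rm = TRUE)
    per_group <- vapply(glev, function(g) {
      yg <- y[groups == g]
      yg <- yg[!is.na(yg)]
      delta <- mean(yg) - grand
      s2 <- if (length(yg) > 1) var(yg) else 0
      abs(delta) + sqrt(s2 / length(yg))
    }, numeric(1))
    mean(per_group)
  }
  stab <- vapply(candidates, one, numeric(1))
  excluded <- is.na(stab)
  if (any(excluded)) {
    warn(sprintf("excluded %d candidate(s) with >50%% missing Ct in a group.",
                 sum(excluded)))
  }
  out <- tibble(assay_id = candidates, stability = unname(stab))
  out <- dplyr::filter(out, !is.na(.data$stability))
  out <- dplyr::arrange(out, .data$stability)
  out$recommended <- seq_len(nrow(out)) == 1
  out
}

#' Relative expression by the delta-delta-Ct method
#'
#' Normalizes each assay's Ct to the housekeeping assay within sample
#' (`dCt = Ct_assay - Ct_housekeeping`), references it to the inter-array
#' calibrator (`ddCt = dCt - dCt_calibrator`), and reports log2 relative
#' expression `-ddCt` (one Ct equals one log2 unit at 100% efficiency, and
#' efficiency is deliberately not used as a correction here). Samples with
#' a missing housekeeping Ct are dropped with a warning, as are assays
#' whose calibrator dCt is missing; missing target Ct values propagate as
#' missing expression.
#'
#' @param x A [ct_matrix()].
#' @return Numeric matrix (assays x samples) of log2 relative expression;
#'   the calibrator column is zero by construction. The housekeeping row is
#'   omitted.
#' @export
delta_delta_ct <- function(x) {
  stopifnot(inherits(x, "ct_matrix"))
  ct <- x$ct
  hk <- ct[x$housekeeping, ]
  drop_samples <- is.na(hk)
  if (any(drop_samples)) {
    warn(sprintf("dropping %d sample(s) with missing housekeeping Ct: %s",
                 sum(drop_samples),
                 paste(colnames(ct)[drop_samples], collapse = ", ")))
    ct <- ct[, !drop_samples, drop = FALSE]
    hk <- hk[!drop_samples]
  }
  if (!x$calibrator %in% colnames(ct)) {
    abort("the calibrator sample has no housekeeping Ct.")
  }
  targets <- setdiff(rownames(ct), x$housekeeping)
  dct <- sweep(ct[targets, , drop = FALSE], 2, hk, "-")
  cal_dct <- dct[, x$calibrator]
  bad_assay <- is.na(cal_dct)
  if (any(bad_assay)) {
    warn(sprintf("dropping %d assay(s) with missing calibrator Ct: %s",
                 sum(bad_assay), paste(targets[bad_assay], collapse = ", ")))
    dct <- dct[!bad_assay, , drop = FALSE]
    cal_dct <- cal_dct[!bad_assay]
  }
  -(dct - cal_dct)
}
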