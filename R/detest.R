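# Negative-binomial group-mean fitting, dispersion estimation and
# likelihood-ratio contrast tests for the four-group (DO x temperature)
# design. All fits use the NB parameterization variance = mu + phi mu^2
# with per-sample offsets log(effective library size), so the fitted
# parameter is a rate per unit of effective depth.

# Vectorized Fisher-scoring fit of one rate per gene for one sample group.
# Y: genes x samples counts; N: effective library sizes; phi: scalar or
# per-gene dispersion. Returns list(rate, loglik, info) where info is the
# Fisher information of log(rate) at the optimum (used for the Cox-Reid
# adjustment).
nb_fit_group <- function(Y, N, phi, eta_start = NULL) {
  G <- nrow(Y)
  tot <- rowSums(Y)
  zero <- tot == 0
  eta <- if (is.null(eta_start)) log((tot + 0.5) / sum(N)) else eta_start
  active <- !zero
  if (any(active)) {
    Ya <- Y[active, , drop = FALSE]
    phia <- if (length(phi) > 1) phi[active] else phi
    ea <- eta[active]
    for (it in 1:50) {
      mu <- exp(ea) %o% N
      w <- 1 + phia * mu
      score <- rowSums((Ya - mu) / w)
      info <- rowSums(mu / w)
      step <- score / info
      step <- pmin(5, pmax(-5, step))
      ea <- ea + step
      if (max(abs(step)) < 1e-10) break
    }
    eta[active] <- ea
  }
  rate <- exp(eta)
  rate[zero] <- 0
  mu <- rate %o% N
  size <- 1 / phi
  ll <- rowSums(dnbinom_mat(Y, mu, phi))
  info <- rowSums(mu / (1 + phi * mu))
  list(rate = rate, loglik = ll, info = info, eta = eta)
}

# NB log density genes x samples, phi scalar or per-gene (recycled down
# columns, i.e. per gene)
dnbinom_mat <- function(Y, mu, phi) {
  suppressWarnings(stats::dnbinom(Y, size = 1 / phi, mu = mu, log = TRUE))
}

# group labels as used throughout: "<do_group>.<temperature>"
make_groups <- function(meta) {
  paste(meta$do_group, meta$temperature, sep = ".")
}

#' Per-gene NB group means for the four-treatment design
#'
#' Maximum-likelihood negative-binomial mean per treatment group for every
#' gene, with `log(effective library size)` offsets and a fixed dispersion.
#' The reported mean is the fitted rate scaled to the average effective
#' library size, so with equal library sizes it equals the ML mean of the
#' group's counts.
#'
#' @param m Count matrix.
#' @param factors Normalization factors (see [tmm_factors()]), or `NULL`.
#' @param groups Character vector of group labels, one per sample.
#' @param dispersion NB dispersion phi: scalar or per-gene vector.
#' @return Tibble: `gene_id`, one column per group (fitted mean), and
#'   `degenerate` flagging genes with at least one all-zero group.
#' @export
fit_group_means <- function(m, factors = NULL, groups, dispersion = 0.1) {
  check_count_matrix(m)
  if (length(groups) != ncol(m)) abort("`groups` must match the samples.")
  if (any(dispersion <= 0)) abort("`dispersion` must be positive.")
  if (any(table(groups) < 2)) abort("every group needs at least 2 samples.")
  N <- effective_lib_sizes(m, factors)
  Nbar <- mean(N)
  lev <- sort(unique(groups))
  fits <- lapply(lev, function(g) {
    idx <- which(groups == g)
    nb_fit_group(m[, idx, drop = FALSE], N[idx], dispersion)
  })
  means <- matrix(vapply(fits, function(f) f$rate * Nbar,
                         numeric(nrow(m))),
                  nrow = nrow(m), dimnames = list(rownames(m), lev))
  degenerate <- rowSums(means == 0) > 0
  dplyr::bind_cols(tibble(gene_id = rownames(m)), as_tibble(means),
                   tibble(degenerate = degenerate))
}

#' Estimate per-gene NB dispersions with empirical shrinkage
#'
#' Maximizes the Cox-Reid adjusted profile likelihood of the four-group
#' model on a log-spaced dispersion grid, per gene and (summed over genes)
#' for a common dispersion, then shrinks each gene's estimate toward the
#' common value on the log scale with prior weight `d0`:
#' `phi_tilde = exp((d0 log phi0 + d_res log phi_hat) / (d0 + d_res))`.
#'
#' @inheritParams fit_group_means
#' @param d0 Prior degrees of freedom for shrinkage (default 10).
#' @param grid Dispersion grid; default 61 log-spaced points in
#'   `[1e-4, 10]`.
#' @return A list of class `dispersion_fit`: `table` (tibble gene_id,
#'   phi_raw, phi_shrunk) and `common` (the common dispersion phi0).
#' @export
estimate_dispersion <- function(m, factors = NULL, groups,
                                d0 = 10,
                                grid = exp(seq(log(1e-4), log(10),
                                               length.out = 61))) {
  check_count_matrix(m)
  if (length(groups) != ncol(m)) abort("`groups` must match the samples.")
  N <- effective_lib_sizes(m, factors)
  lev <- sort(unique(groups))
  n_res <- ncol(m) - length(lev)
  if (n_res < 2) abort("need at least 2 residual degrees of freedom.")
  G <- nrow(m)
  apl <- matrix(-Inf, G, length(grid))
  idx_by_group <- lapply(lev, function(g) which(groups == g))
  eta_warm <- vector("list", length(lev))
  for (j in seq_along(grid)) {
    phi <- grid[j]
    ll <- numeric(G)
    cr <- numeric(G)
    for (k in seq_along(lev)) {
      idx <- idx_by_group[[k]]
      fit <- nb_fit_group(m[, idx, drop = FALSE], N[idx], phi,
                          eta_start = eta_warm[[k]])
      eta_warm[[k]] <- fit$eta
      ll <- ll + fit$loglik
      cr <- cr + 0.5 * log(pmax(fit$info, 1e-10))
    }
    apl[, j] <- ll - cr
  }
  informative <- rowSums(m) > 0
  phi_hat <- grid[max.col(apl, ties.method = "first")]
  common_curve <- colSums(apl[informative, , drop = FALSE])
  # refine the common dispersion off-grid: the grid spacing (~20% between
  # points) is coarse enough to bias the shrinkage target
  total_apl <- function(phi) {
    ll <- numeric(G)
    cr <- numeric(G)
    for (k in seq_along(lev)) {
      idx <- idx_by_group[[k]]
      fit <- nb_fit_group(m[, idx, drop = FALSE], N[idx], phi,
                          eta_start = eta_warm[[k]])
      ll <- ll + fit$loglik
      cr <- cr + 0.5 * log(pmax(fit$info, 1e-10))
    }
    sum((ll - cr)[informative])
  }
  j0 <- which.max(common_curve)
  lo <- grid[max(1, j0 - 1)]
  hi <- grid[min(length(grid), j0 + 1)]
  phi0 <- stats::optimize(total_apl, c(lo, hi), maximum = TRUE,
                          tol = 1e-4)$maximum
  phi_shrunk <- exp((d0 * log(phi0) + n_res * log(phi_hat)) / (d0 + n_res))
  phi_shrunk[!informative] <- phi0
  structure(
    list(
      table = tibble(gene_id = rownames(m),
                     phi_raw = ifelse(informative, phi_hat, NA_real_),
                     phi_shrunk = phi_shrunk),
      common = phi0
    ),
    class = "dispersion_fit"
  )
}

#' @export
print.dispersion_fit <- function(x, ...) {
  cat("NB dispersion fit:", nrow(x$table), "genes; common dispersion",
      signif(x$common, 3), "\n")
  invisible(x)
}

#' Likelihood-ratio contrast test between two treatment groups
#'
#' Per gene, tests whether the two contrasted groups share an NB mean:
#' the full model fits one rate per group, the reduced model one pooled
#' rate, and the statistic `2 * (ll_full - ll_reduced)` is referred to a
#' chi-squared distribution with 1 df using the (shrunken) dispersion.
#' The log2 fold change is `log2((rate_1 + r0) / (rate_2 + r0))` for
#' `contrast = c(group1, group2)`, with a prior rate `r0` equivalent to
#' `prior_count` reads at the average effective library size.
#'
#' @inheritParams fit_group_means
#' @param contrast Character pair `c(numerator_group, denominator_group)`;
#'   for a hypoxia-minus-normoxia fold change put the hypoxia group first.
#' @param prior_count Prior count stabilizing the fold change (default 0.5).
#' @return Tibble: gene_id, log2fc, lrt, p.
#' @export
contrast_test <- function(m, factors = NULL, groups, contrast,
                          dispersion = 0.1, prior_count = 0.5) {
  check_count_matrix(m)
  if (length(contrast) != 2 || !all(contrast %in% groups)) {
    abort("`contrast` must name two groups present in `groups`.")
  }
  N <- effective_lib_sizes(m, factors)
  i1 <- which(groups == contrast[1])
  i2 <- which(groups == contrast[2])
  f1 <- nb_fit_group(m[, i1, drop = FALSE], N[i1], dispersion)
  f2 <- nb_fit_group(m[, i2, drop = FALSE], N[i2], dispersion)
  f0 <- nb_fit_group(m[, c(i1, i2), drop = FALSE], N[c(i1, i2)], dispersion)
  lrt <- pmax(0, 2 * (f1$loglik + f2$loglik - f0$loglik))
  p <- pchisq(lrt, df = 1, lower.tail = FALSE)
  r0 <- prior_count / mean(N)
  log2fc <- log2((f1$rate + r0) / (f2$rate + r0))
  tibble(gene_id = rownames(m), log2fc = unname(log2fc),
         lrt = unname(lrt), p = unname(p))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjusted p-values (wraps
#' [stats::p.adjust()] with `method = "BH"`).
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted q-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  p.adjust(p, method = "BH")
}

#' Per-temperature differential-expression table
#'
#' Runs the full four-group NB analysis: dispersion estimation with
#' shrinkage, then a hypoxia-versus-normoxia likelihood-ratio contrast
#' within each temperature. Selection downstream uses the unadjusted
#' p-values; BH q-values are reported alongside.
#'
#' @param m Filtered count matrix.
#' @param meta Sample tibble with `sample_id`, `do_group`
#'   (normoxia/hypoxia), `temperature` columns.
#' @param factors Normalization factors; `NULL` computes TMM factors.
#' @param stressor_levels Levels of `do_group`, `c(reference, stressed)`;
#'   fold changes are stressed minus reference.
#' @param d0,prior_count Passed to [estimate_dispersion()] and
#'   [contrast_test()].
#' @return Tibble (the DE table): gene_id, contrast (temperature as
#'   character), log2fc, dispersion, p, q (BH within contrast).
#' @export
de_test <- function(m, meta, factors = NULL,
                    stressor_levels = c("normoxia", "hypoxia"),
                    d0 = 10, prior_count = 0.5) {
  check_count_matrix(m)
  if (!all(c("sample_id", "do_group", "temperature") %in% names(meta))) {
    abort("`meta` needs sample_id, do_group and temperature columns.")
  }
  if (!all(colnames(m) %in% meta$sample_id)) {
    abort("sample ids in `m` and `meta` do not match.")
  }
  meta <- meta[match(colnames(m), meta$sample_id), ]
  if (is.null(factors)) factors <- tmm_factors(m)
  groups <- make_groups(meta)
  disp <- estimate_dispersion(m, factors, groups, d0 = d0)
  temps <- sort(unique(meta$temperature))
  res <- purrr::map(temps, function(tt) {
    ct <- paste(rev(stressor_levels), tt, sep = ".")
    out <- contrast_test(m, factors, groups, contrast = ct,
                         dispersion = disp$table$phi_shrunk,
                         prior_count = prior_count)
    out$contrast <- as.character(tt)
    out$dispersion <- disp$table$phi_shrunk
    out
  })
  res <- dplyr::bind_rows(res)
  res <- dplyr::group_by(res, .data$contrast)
  res <- dplyr::mutate(res, q = bh_adjust(.data$p))
  res <- dplyr::ungroup(res)
  dplyr::select(res, "gene_id", "contrast", "log2fc", "dispersion",
                "lrt", "p", "q")
}
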