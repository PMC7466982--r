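# Temperature-robust candidate selection: direction-consistent
# intersection of the per-temperature DE lists, PCA of the candidates,
# stressor/confounder axis identification, correlation ranking with
# confounder exclusion, and the final top-k panel.

#' Direction-consistent intersection of per-temperature DE results
#'
#' Keeps genes significant (unadjusted p below `alpha`) in *both*
#' temperature contrasts whose log2 fold changes have the same nonzero
#' sign — the device that makes the panel robust to temperature, because
#' interaction genes (opposite DO response at the two temperatures) are
#' rejected.
#'
#' @param de DE tibble from [de_test()] with both contrasts per gene.
#' @param alpha Significance threshold on the unadjusted p (default 0.05).
#' @return Tibble: gene_id, direction (`"up"`/`"down"` in the stressed
#'   group), and per-contrast log2fc/p columns.
#' @export
consistent_intersection <- function(de, alpha = 0.05) {
  cts <- sort(unique(de$contrast))
  if (length(cts) != 2) abort("`de` must contain exactly two contrasts.")
  wide <- tidyr::pivot_wider(
    dplyr::select(de, "gene_id", "contrast", "log2fc", "p"),
    names_from = "contrast", values_from = c("log2fc", "p")
  )
  lfc1 <- wide[[paste0("log2fc_", cts[1])]]
  lfc2 <- wide[[paste0("log2fc_", cts[2])]]
  p1 <- wide[[paste0("p_", cts[1])]]
  p2 <- wide[[paste0("p_", cts[2])]]
  keep <- p1 < alpha & p2 < alpha & sign(lfc1) == sign(lfc2) & lfc1 != 0
  out <- wide[keep, , drop = FALSE]
  out$direction <- ifelse(out[[paste0("log2fc_", cts[1])]] > 0, "up", "down")
  dplyr::relocate(out, "gene_id", "direction")
}

#' PCA of candidate-gene expression
#'
#' Singular-value decomposition of the samples-by-genes matrix after each
#' gene (row of `expr`) is centered and scaled to unit variance across
#' samples. Zero-variance genes are dropped with a warning. Axis signs are
#' fixed later by [pick_axes()]'s orientation rule.
#'
#' @param expr Numeric matrix, genes x samples (e.g. log2 cpm restricted to
#'   candidate genes).
#' @return Object of class `pca_model`: `loadings` (genes x axes,
#'   orthonormal), `scores` (samples x axes), `sdev`, `explained` (variance
#'   fractions), `center`, `scale` (per-gene statistics).
#' @export
fit_pca <- function(expr) {
  if (!is.matrix(expr) || ncol(expr) < 3) {
    abort("`expr` must be a genes x samples matrix with >= 3 samples.")
  }
  ctr <- rowMeans(expr)
  scl <- apply(expr, 1, sd)
  constant <- scl == 0
  if (any(constant)) {
    warn(sprintf("dropping %d constant gene(s) from the PCA.", sum(constant)))
    expr <- expr[!constant, , drop = FALSE]
    ctr <- ctr[!constant]
    scl <- scl[!constant]
  }
  z <- (expr - ctr) / scl
  x <- t(z) # samples x genes
  sv <- svd(x)
  k <- sum(sv$d > max(sv$d) * 1e-10)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)],
                                                      nrow = k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  rownames(scores) <- colnames(expr)
  rownames(loadings) <- rownames(expr)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  sdev <- sv$d[seq_len(k)] / sqrt(nrow(x) - 1)
  structure(
    list(
      loadings = loadings, scores = scores, sdev = sdev,
      explained = sv$d[seq_len(k)]^2 / sum(sv$d^2),
      center = ctr, scale = scl
    ),
    class = "pca_model"
  )
}

#' @export
print.pca_model <- function(x, ...) {
  cat("PCA:", nrow(x$loadings), "genes,", nrow(x$scores), "samples;",
      "variance explained PC1..:",
      paste(signif(head(x$explained, 4), 3), collapse = " "), "\n")
  invisible(x)
}

#' Identify the stressor and confounder PCA axes
#'
#' Among the first `m_axes` principal components, the stressor axis is the
#' one with the largest absolute point-biserial correlation between sample
#' scores and the stressor label; the confounder axis is the distinct axis
#' most associated with the confounder. After selection, the stressor axis
#' is oriented so the stressed group's mean score is positive (the SVD sign
#' is arbitrary; the convention makes downstream correlations
#' reproducible, with downregulated genes getting negative r).
#'
#' @param model A [fit_pca()] model.
#' @param meta Sample tibble aligned with the model's samples.
#' @param stressor,confounder Column names in `meta`; each must be
#'   two-level on these samples.
#' @param stressed_level Level of `stressor` whose mean score is oriented
#'   positive (default `"hypoxia"`).
#' @param m_axes Number of leading axes searched (default 5).
#' @return List: `stressor_axis`, `confounder_axis` (integer indices),
#'   `model` (re-oriented), and `associations` tibble.
#' @export
pick_axes <- function(model, meta, stressor = "do_group",
                      confounder = "temperature",
                      stressed_level = "hypoxia", m_axes = 5) {
  stopifnot(inherits(model, "pca_model"))
  meta <- meta[match(rownames(model$scores), meta$sample_id), ]
  for (col in c(stressor, confounder)) {
    if (length(unique(meta[[col]])) != 2) {
      abort(sprintf("`%s` must be two-level on these samples.", col))
    }
  }
  m_axes <- min(m_axes, ncol(model$scores))
  s_bin <- as.numeric(factor(meta[[stressor]]))
  c_bin <- as.numeric(factor(meta[[confounder]]))
  r_s <- abs(apply(model$scores[, seq_len(m_axes), drop = FALSE], 2, cor,
                   y = s_bin))
  r_c <- abs(apply(model$scores[, seq_len(m_axes), drop = FALSE], 2, cor,
                   y = c_bin))
  stressor_axis <- which.max(r_s)
  conf_order <- order(r_c, decreasing = TRUE)
  confounder_axis <- conf_order[conf_order != stressor_axis][1]
  if (is.na(confounder_axis)) {
    abort(paste("the same axis maximizes association with both factors;",
                "inspect the PCA geometry before ranking."))
  }
  stressed <- meta[[stressor]] == stressed_level
  if (mean(model$scores[stressed, stressor_axis]) <
      mean(model$scores[!stressed, stressor_axis])) {
    model$scores[, stressor_axis] <- -model$scores[, stressor_axis]
    model$loadings[, stressor_axis] <- -model$loadings[, stressor_axis]
  }
  list(
    stressor_axis = unname(stressor_axis),
    confounder_axis = unname(confounder_axis),
    model = model,
    associations = tibble(
      axis = seq_len(m_axes),
      r_stressor = unname(r_s),
      r_confounder = unname(r_c)
    )
  )
}

#' Rank candidate genes by correlation with the stressor axis
#'
#' Per gene, Pearson correlation (and two-sided p) of its scaled expression
#' profile with the stressor-axis scores and with the confounder-axis
#' scores. Genes correlated with the confounder axis at `p < p_excl` are
#' excluded; the rest are ranked by ascending stressor-axis p within
#' direction (ties by larger |r|, then gene id).
#'
#' @param expr Genes x samples matrix (same as given to [fit_pca()]).
#' @param axes Result of [pick_axes()].
#' @param directions Tibble with `gene_id` and `direction` from
#'   [consistent_intersection()].
#' @param p_excl Confounder-axis exclusion threshold (default 0.1,
#'   two-sided).
#' @return Tibble (the candidate panel): gene_id, direction, r_axis,
#'   p_axis, r_confounder, p_confounder, excluded, rank (within
#'   direction; NA for excluded genes).
#' @export
rank_candidates <- function(expr, axes, directions, p_excl = 0.1) {
  model <- axes$model
  genes <- intersect(rownames(expr), rownames(model$loadings))
  expr <- expr[genes, , drop = FALSE]
  z <- (expr - model$center[genes]) / model$scale[genes]
  s_scores <- model$scores[, axes$stressor_axis]
  c_scores <- model$scores[, axes$confounder_axis]
  cs <- row_cor_test(z, s_scores)
  cc <- row_cor_test(z, c_scores)
  out <- tibble(
    gene_id = genes,
    r_axis = cs$r, p_axis = cs$p,
    r_confounder = cc$r, p_confounder = cc$p,
    excluded = cc$p < p_excl
  )
  out <- dplyr::inner_join(out,
                           dplyr::select(directions, "gene_id", "direction"),
                           by = "gene_id")
  out <- dplyr::arrange(out, .data$p_axis, -abs(.data$r_axis), .data$gene_id)
  out <- dplyr::group_by(out, .data$direction)
  out <- dplyr::mutate(
    out,
    rank = ifelse(.data$excluded, NA_integer_, cumsum(!.data$excluded))
  )
  out <- dplyr::ungroup(out)
  dplyr::relocate(out, "gene_id", "direction", "r_axis", "p_axis",
                  "r_confounder", "p_confounder", "rank", "excluded")
}

#' Select the final biomarker panel
#'
#' Takes the top `k_down` downregulated and `k_up` upregulated genes by
#' rank from a ranked candidate panel (excluded genes never qualify). If a
#' direction has fewer than requested, all of its genes are returned with a
#' warning.
#'
#' @param panel Tibble from [rank_candidates()].
#' @param k_down,k_up Panel sizes per direction (defaults 20 and 10).
#' @return The selected subset of `panel`, with a `selected` column set to
#'   `TRUE`, ordered down genes first.
#' @export
select_panel <- function(panel, k_down = 20, k_up = 10) {
  if (nrow(panel) == 0) abort("empty candidate panel.")
  avail <- dplyr::filter(panel, !.data$excluded)
  pick <- function(dir, k) {
    sub <- dplyr::filter(avail, .data$direction == dir)
    sub <- dplyr::arrange(sub, .data$rank)
    if (nrow(sub) < k) {
      warn(sprintf("only %d %s gene(s) available (requested %d).",
                   nrow(sub), dir, k))
    }
    head(sub, k)
  }
  out <- dplyr::bind_rows(pick("down", k_down), pick("up", k_up))
  out$selected <- TRUE
  out
}

#' Run the discovery stage on counts and metadata
#'
#' Convenience composition of the discovery pipeline: expression filter,
#' TMM normalization, MDS factor screen, per-temperature NB contrasts,
#' direction-consistent intersection, candidate PCA with axis picking,
#' correlation ranking with confounder exclusion, and final panel
#' selection.
#'
#' @param counts Raw count matrix.
#' @param meta Sample metadata tibble (sample_id, do_group, temperature,
#'   ...).
#' @param alpha,p_excl,k_down,k_up,d0 Pipeline thresholds (defaults 0.05,
#'   0.1, 20, 10, 10).
#' @param cpm_threshold,min_samples Passed to [filter_low_expression()].
#' @return List of class `discovery_result`: filtered counts, factors, mds,
#'   de table, intersection, axes, candidates, panel, and a `log` tibble of
#'   stage counts.
#' @export
discover_panel <- function(counts, meta, alpha = 0.05, p_excl = 0.1,
                           k_down = 20, k_up = 10, d0 = 10,
                           cpm_threshold = NULL, min_samples = NULL) {
  filtered <- filter_low_expression(counts, cpm_threshold, min_samples)
  factors <- tmm_factors(filtered)
  mds <- mds_screen(filtered, meta)
  de <- de_test(filtered, meta, factors, d0 = d0)
  consistent <- consistent_intersection(de, alpha = alpha)
  wide_sig <- dplyr::summarise(dplyr::group_by(de, .data$gene_id),
                               both = all(.data$p < alpha))
  if (nrow(consistent) < 2) {
    abort("fewer than two direction-consistent genes; nothing to rank.")
  }
  lcpm <- cpm(filtered, factors, log = TRUE)
  expr <- lcpm[consistent$gene_id, , drop = FALSE]
  pca <- fit_pca(expr)
  axes <- pick_axes(pca, meta)
  candidates <- rank_candidates(expr, axes, consistent, p_excl = p_excl)
  panel <- select_panel(candidates, k_down = k_down, k_up = k_up)
  structure(
    list(
      filtered = filtered, factors = factors, mds = mds, de = de,
      consistent = consistent, axes = axes, candidates = candidates,
      panel = panel,
      log = tibble(
        stage = c("input_genes", "filtered_genes", "significant_both",
                  "direction_consistent", "ranked_after_exclusion",
                  "panel"),
        n = c(nrow(counts), nrow(filtered), sum(wide_sig$both),
              nrow(consistent), sum(!candidates$excluded), nrow(panel))
      )
    ),
    class = "discovery_result"
  )
}

#' @export
print.discovery_result <- function(x, ...) {
  cat("Discovery pipeline:\n")
  print(x$log, n = Inf)
  invisible(x)
}
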