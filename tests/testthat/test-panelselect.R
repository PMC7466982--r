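# small DE-table builder for intersection tests
de_row <- function(gene, p10, p18, l10, l18) {
  tibble::tibble(
    gene_id = gene, contrast = c("10", "18"),
    log2fc = c(l10, l18), p = c(p10, p18)
  )
}

test_that("direction-consistent intersection follows its rule exactly", {
  # all 8 combinations of (sig10, sig18, same direction)
  tbl <- dplyr::bind_rows(
    de_row("both_sig_same_up", 0.01, 0.01, 1, 2),
    de_row("both_sig_same_down", 0.02, 0.03, -1, -0.5),
    de_row("both_sig_opposite", 0.01, 0.01, 1, -1),
    de_row("only10_sig_same", 0.01, 0.2, 1, 1),
    de_row("only18_sig_same", 0.2, 0.01, 1, 1),
    de_row("none_sig_same", 0.5, 0.6, 1, 1),
    de_row("none_sig_opposite", 0.5, 0.6, 1, -1),
    de_row("sig_zero_fc", 0.01, 0.01, 0, 0)
  )
  out <- consistent_intersection(tbl, alpha = 0.05)
  expect_setequal(out$gene_id, c("both_sig_same_up", "both_sig_same_down"))
  expect_equal(out$direction[out$gene_id == "both_sig_same_up"], "up")
  expect_equal(out$direction[out$gene_id == "both_sig_same_down"], "down")

  # monotone in alpha: shrinking alpha never adds genes
  wide <- consistent_intersection(tbl, alpha = 0.5)
  expect_true(all(out$gene_id %in% wide$gene_id))
  # alpha = 1 degenerates to the same-direction set
  all_dir <- consistent_intersection(tbl, alpha = 1)
  expect_setequal(
    all_dir$gene_id,
    c("both_sig_same_up", "both_sig_same_down", "only10_sig_same",
      "only18_sig_same", "none_sig_same")
  )
})

test_that("PCA reproduces closed-form decompositions", {
  set.seed(2)
  expr <- matrix(rnorm(12), 4, 3,
                 dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  model <- fit_pca(expr)
  # basis completeness: reconstruct the scaled matrix exactly
  z <- (expr - model$center) / model$scale
  recon <- model$scores %*% t(model$loadings)
  expect_equal(t(z), recon, tolerance = 1e-8, ignore_attr = TRUE)
  # loadings orthonormal
  k <- ncol(model$loadings)
  expect_equal(crossprod(model$loadings), diag(k), tolerance = 1e-8,
               ignore_attr = TRUE)
  # scores match the gene-space Gram eigendecomposition up to sign
  ev <- eigen(z %*% t(z), symmetric = TRUE)
  sc <- t(z) %*% ev$vectors[, seq_len(k)]
  for (j in seq_len(k)) {
    expect_equal(abs(model$scores[, j]), abs(sc[, j]), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  # a single planted direction dominates axis 1
  strong <- outer(c(1, -1, 2, -2), c(1, 0, -1)) +
    matrix(rnorm(12, sd = 1e-3), 4)
  dimnames(strong) <- dimnames(expr)
  m2 <- fit_pca(strong)
  expect_gt(m2$explained[1], 0.99)
  # constant genes are dropped with a warning
  cexpr <- rbind(expr, gconst = 1)
  expect_warning(fit_pca(cexpr), "constant")
})

test_that("axis picking finds the stressor and confounder axes", {
  # construct expression where DO drives most genes and temperature a few:
  # the DO contrast owns PC1, the temperature contrast PC2
  set.seed(21)
  meta <- tidyr::expand_grid(do_group = c("normoxia", "hypoxia"),
                             temperature = c(10, 18), rep = 1:6)
  meta$sample_id <- sprintf("s%02d", seq_len(nrow(meta)))
  hyp <- as.numeric(meta$do_group == "hypoxia")
  t18 <- as.numeric(meta$temperature == 18)
  expr <- rbind(
    outer(rnorm(30, 2, 0.3), hyp),  # DO-responsive genes
    outer(rnorm(10, 2, 0.3), t18)   # temperature-responsive genes
  ) + matrix(rnorm(40 * nrow(meta), sd = 0.3), 40)
  dimnames(expr) <- list(paste0("g", 1:40), meta$sample_id)
  axes <- pick_axes(fit_pca(expr), meta)
  expect_equal(axes$stressor_axis, 1)
  expect_equal(axes$confounder_axis, 2)
  # orientation: hypoxia samples score positive on the stressor axis
  sc <- axes$model$scores[, axes$stressor_axis]
  expect_gt(mean(sc[hyp == 1]), mean(sc[hyp == 0]))
  expect_gt(mean(sc[hyp == 1]), 0)

  # planted swap: temperature variance dominates -> axes (2, 1)
  sim2 <- simulate_counts(sim_design(
    n_genes = 800, seed = 22,
    fractions = c(hypoxia_up = 0.02, hypoxia_down = 0.02, temp_only = 0.2,
                  interaction = 0, null = 0.76),
    effect_size = 3
  ))
  filt <- filter_low_expression(sim2$counts)
  lcpm <- cpm(filt, tmm_factors(filt), log = TRUE)
  # candidates include the temperature genes on purpose here
  genes <- sim2$truth$gene_id[sim2$truth$class != "null"]
  genes <- intersect(genes, rownames(lcpm))
  pca <- fit_pca(lcpm[genes, ])
  axes <- pick_axes(pca, sim2$samples)
  expect_equal(axes$stressor_axis, 2)
  expect_equal(axes$confounder_axis, 1)
})

test_that("candidate ranking matches a brute-force correlation oracle", {
  sim <- small_sim(seed = 31, n_genes = 600)
  res <- suppressWarnings(discover_panel(sim$counts, sim$samples,
                                         k_down = 10, k_up = 5))
  lcpm <- cpm(res$filtered, res$factors, log = TRUE)
  expr <- lcpm[res$consistent$gene_id, ]
  model <- res$axes$model
  s_sc <- model$scores[, res$axes$stressor_axis]
  c_sc <- model$scores[, res$axes$confounder_axis]
  oracle <- purrr::map_dfr(rownames(expr), function(g) {
    zs <- (expr[g, ] - mean(expr[g, ])) / sd(expr[g, ])
    t1 <- stats::cor.test(zs, s_sc)
    t2 <- stats::cor.test(zs, c_sc)
    tibble::tibble(gene_id = g, r_axis = unname(t1$estimate),
                   p_axis = t1$p.value, p_conf = t2$p.value)
  })
  got <- res$candidates
  oracle <- oracle[match(got$gene_id, oracle$gene_id), ]
  expect_equal(got$r_axis, oracle$r_axis, tolerance = 1e-10)
  expect_equal(got$p_axis, oracle$p_axis, tolerance = 1e-10)
  expect_equal(got$excluded, oracle$p_conf < 0.1)
  # rank order equals p-value order within direction among retained genes
  for (dir in c("up", "down")) {
    sub <- got[got$direction == dir & !got$excluded, ]
    expect_equal(sub$rank[order(sub$p_axis)], sort(sub$rank))
  }

  # a gene equal to the confounder scores is excluded
  g_conf <- rbind(expr, conf_gene = c_sc)
  dirs <- dplyr::bind_rows(res$consistent[, c("gene_id", "direction")],
                           tibble::tibble(gene_id = "conf_gene",
                                          direction = "up"))
  model2 <- fit_pca(g_conf)
  axes2 <- list(model = model2, stressor_axis = res$axes$stressor_axis,
                confounder_axis = res$axes$confounder_axis)
  ranked <- rank_candidates(g_conf, axes2, dirs)
  expect_true(ranked$excluded[ranked$gene_id == "conf_gene"])
})

test_that("panel selection takes top-k per direction and clips", {
  cand <- tibble::tibble(
    gene_id = paste0("g", 1:12),
    direction = rep(c("down", "up"), c(8, 4)),
    r_axis = c(seq(-0.95, -0.60, length.out = 8),
               seq(0.9, 0.6, length.out = 4)),
    p_axis = c(seq(1e-6, 1e-3, length.out = 8),
               seq(1e-5, 1e-2, length.out = 4)),
    r_confounder = 0, p_confounder = 0.9,
    excluded = FALSE,
    rank = c(1:8, 1:4)
  )
  out <- select_panel(cand, k_down = 5, k_up = 2)
  expect_equal(nrow(out), 7)
  expect_equal(sum(out$direction == "down"), 5)
  up_only <- select_panel(cand, k_down = 0, k_up = 2)
  expect_true(all(up_only$direction == "up"))
  expect_warning(select_panel(cand, k_down = 20, k_up = 2), "only 8")
})

test_that("selected panels recover planted hypoxia genes", {
  sim <- small_sim(seed = 41, n_genes = 1500)
  res <- suppressWarnings(discover_panel(sim$counts, sim$samples))
  joined <- dplyr::left_join(res$panel, sim$truth, by = "gene_id")
  frac_hyp <- mean(joined$class %in% c("hypoxia_up", "hypoxia_down"))
  expect_gte(frac_hyp, 0.9)
  # candidate ranking invariant under gene permutation
  lcpm <- cpm(res$filtered, res$factors, log = TRUE)
  expr <- lcpm[res$consistent$gene_id, ]
  perm <- sample(nrow(expr))
  ranked_perm <- rank_candidates(expr[perm, ], res$axes, res$consistent)
  ranked <- res$candidates
  ranked_perm <- ranked_perm[match(ranked$gene_id, ranked_perm$gene_id), ]
  expect_equal(ranked$rank, ranked_perm$rank)
})
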