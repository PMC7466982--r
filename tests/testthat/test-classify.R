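# balanced two-class expression fixture with a planted mean shift
two_class_expr <- function(n_genes = 10, n_per_class = 6, shift = 2,
                           sd = 0.5, seed = 1, n_informative = n_genes) {
  set.seed(seed)
  n <- 2 * n_per_class
  labels <- rep(c("hypoxia", "normoxia"), each = n_per_class)
  x <- matrix(rnorm(n_genes * n, sd = sd), n_genes, n,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("s", seq_len(n))))
  x[seq_len(n_informative), labels == "hypoxia"] <-
    x[seq_len(n_informative), labels == "hypoxia"] + shift
  list(x = x, labels = setNames(labels, colnames(x)))
}

test_that("stratified splits preserve class balance", {
  ids <- paste0("s", 1:24)
  labels <- rep(c("N", "H"), each = 12)
  sp <- stratified_split(ids, labels, train_fraction = 2 / 3, seed = 1)
  expect_equal(length(sp$train), 16)
  expect_equal(length(sp$test), 8)
  expect_equal(sum(labels[ids %in% sp$train] == "N"), 8)
  expect_equal(sum(labels[ids %in% sp$test] == "H"), 4)
  expect_setequal(c(sp$train, sp$test), ids)
  # determinism
  expect_identical(sp, stratified_split(ids, labels, seed = 1))
  # across many seeds the proportions stay within one sample of target
  ids2 <- paste0("t", 1:17)
  lab2 <- rep(c("N", "H"), c(10, 7))
  for (s in 1:200) {
    spl <- stratified_split(ids2, lab2, train_fraction = 2 / 3, seed = s)
    n_tr_n <- sum(lab2[ids2 %in% spl$train] == "N")
    n_tr_h <- sum(lab2[ids2 %in% spl$train] == "H")
    expect_lte(abs(n_tr_n - 2 / 3 * 10), 1)
    expect_lte(abs(n_tr_h - 2 / 3 * 7), 1)
  }
  expect_error(stratified_split("a", "x"), "fewer than 2")
})

test_that("NSC matches the brute-force published-formula oracle", {
  fx <- two_class_expr(n_genes = 10, n_per_class = 6, shift = 1.5,
                       n_informative = 4, seed = 7)
  model <- nsc_fit(fx$x, fx$labels, cv_folds = 3, n_thresholds = 15)
  oracle <- oracle_nsc(fx$x, fx$labels, model$delta)
  expect_equal(model$d, oracle$d, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(model$dprime, oracle$dprime, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(model$shrunk_centroids, oracle$shrunk, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_setequal(model$genes, oracle$genes)
  # discriminant scores match for a test sample
  pred <- nsc_predict(model, fx$x[, 1, drop = FALSE])
  expect_equal(unname(pred$scores[1, ]), oracle$score(fx$x[, 1]),
               tolerance = 1e-10)
})

test_that("NSC shrinkage limits behave as designed", {
  fx <- two_class_expr(seed = 3)
  st_model <- nsc_fit(fx$x, fx$labels, cv_folds = 3)
  # gene count is nonincreasing in the threshold
  sizes <- purrr::map_int(st_model$grid, function(del) {
    dp <- sign(st_model$d) * pmax(abs(st_model$d) - del, 0)
    sum(rowSums(dp != 0) > 0)
  })
  expect_true(all(diff(sizes) <= 0))

  # delta = 0: plain nearest standardized centroid with every gene
  oracle0 <- oracle_nsc(fx$x, fx$labels, 0)
  expect_equal(oracle0$dprime, oracle0$d, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(length(oracle0$genes), nrow(fx$x))

  # delta beyond max |d|: every deviation zeroed, prediction by priors
  big <- max(abs(st_model$d)) + 1
  dp_big <- sign(st_model$d) * pmax(abs(st_model$d) - big, 0)
  expect_true(all(dp_big == 0))
  labs_unbal <- fx$labels
  labs_unbal[1:2] <- "normoxia" # normoxia becomes the larger class
  m_unbal <- nsc_fit(fx$x, labs_unbal, cv_folds = 2, n_thresholds = 5)
  # rebuild a fully shrunk model by pushing delta past the max
  m_total <- m_unbal
  m_total$dprime[] <- 0
  m_total$shrunk_centroids <- sweep(m_total$dprime, 1, m_unbal$xbar, "+")
  pred <- nsc_predict(m_total, fx$x)
  expect_true(all(pred$class ==
                    m_unbal$classes[which.max(m_unbal$priors)]))
})

test_that("NSC prediction ties break lexicographically", {
  # exactly representable values keep the two classes perfectly symmetric
  x <- matrix(c(0, 0.5, 2, 2.5), 1, 4,
              dimnames = list("g1", paste0("s", 1:4)))
  labels <- c("b_class", "b_class", "a_class", "a_class")
  model <- nsc_fit(x, labels, cv_folds = 2, n_thresholds = 3)
  # a sample at the overall mean is equidistant from both shrunken
  # centroids under equal priors
  mid <- matrix(1.25, 1, 1, dimnames = list("g1", "mid"))
  pred <- nsc_predict(model, mid)
  expect_equal(unname(pred$class), "a_class")
})

test_that("LDA matches closed forms and is scale-invariant", {
  # 1-D equal-variance classes: boundary at the midpoint of the means
  x1 <- matrix(c(0.9, 1.1, 1.0, 2.9, 3.1, 3.0), 1, 6,
               dimnames = list("g1", paste0("s", 1:6)))
  labels <- rep(c("a", "b"), each = 3)
  model <- lda_fit(x1, labels)
  just_below <- matrix(1.99, 1, 1, dimnames = list("g1", "x"))
  just_above <- matrix(2.01, 1, 1, dimnames = list("g1", "x"))
  expect_equal(unname(lda_predict(model, just_below)$class), "a")
  expect_equal(unname(lda_predict(model, just_above)$class), "b")

  # 2-D fixture: discriminant vector equals solve(S + gI, mu1 - mu0)
  set.seed(9)
  x2 <- matrix(rnorm(2 * 12), 2, 12,
               dimnames = list(c("g1", "g2"), paste0("s", 1:12)))
  lab2 <- rep(c("a", "b"), each = 6)
  x2[, lab2 == "b"] <- x2[, lab2 == "b"] + c(2, -1)
  m2 <- lda_fit(x2, lab2, gamma = 1e-8)
  expect_equal(m2$direction, unname(oracle_lda_direction(x2, lab2, 1e-8)),
               tolerance = 1e-10)

  # common scaling of all features leaves predictions unchanged
  test_x <- matrix(rnorm(2 * 5), 2, 5,
                   dimnames = list(c("g1", "g2"), paste0("t", 1:5)))
  p1 <- lda_predict(m2, test_x)$class
  m2s <- lda_fit(2 * x2, lab2)
  p2 <- lda_predict(m2s, 2 * test_x)$class
  expect_equal(p1, p2)
})

test_that("split evaluation reports accuracies the way Table-style
           summaries expect", {
  fx <- two_class_expr(n_genes = 12, n_per_class = 12, shift = 2,
                       sd = 0.5, seed = 11)
  sp <- stratified_split(colnames(fx$x), fx$labels, seed = 2)
  rep_ <- evaluate_split(fx$x, fx$labels, sp, seed = 2)
  # perfectly separated planted classes classify perfectly
  expect_equal(rep_$average_accuracy, 100)
  expect_true(all(rep_$class_accuracy$accuracy == 100))
  expect_equal(sum(rep_$confusion), length(sp$test))

  # the average is the unweighted mean of per-class accuracies
  expect_equal(mean(c(100, 75)), 87.5)
  conf <- rep_$confusion
  per_class <- 100 * diag(conf) / rowSums(conf)
  expect_equal(rep_$average_accuracy, mean(per_class))

  # swapping class labels transposes the confusion table
  swapped <- setNames(ifelse(fx$labels == "hypoxia", "normoxia", "hypoxia"),
                      names(fx$labels))
  rep_sw <- evaluate_split(fx$x, swapped, sp, seed = 2)
  expect_equal(unclass(rep_sw$confusion)[2:1, 2:1],
               unclass(rep_$confusion), ignore_attr = TRUE)
})

test_that("train-fitted PCA projects test samples consistently", {
  fx <- two_class_expr(n_genes = 8, n_per_class = 10, shift = 2, seed = 13)
  sp <- stratified_split(colnames(fx$x), fx$labels, seed = 3)
  tr <- fx$x[, sp$train]
  te <- fx$x[, sp$test]
  proj <- pca_project(tr, te, labels = fx$labels)
  # projecting the training data reproduces the fit scores
  self <- pca_project(tr, tr)
  self_te <- self$scores[self$scores$set == "test", ]
  expect_equal(self_te$PC1, self$scores$PC1[self$scores$set == "train"],
               tolerance = 1e-10)
  # test centroids separate along the same axis as train centroids
  cent <- proj$centroids
  gap <- function(set) {
    d <- cent[cent$set == set, ]
    d$PC1[d$label == "hypoxia"] - d$PC1[d$label == "normoxia"]
  }
  expect_equal(sign(gap("train")), sign(gap("test")))
  expect_gt(abs(gap("test")), 1)
})

test_that("cross-platform correlation recovers planted concordance", {
  expect_equal(cross_platform_correlation(
    matrix(1:9, 3, 3, dimnames = list(letters[1:3], LETTERS[1:3])) + 0,
    matrix(1:9, 3, 3, dimnames = list(letters[1:3], LETTERS[1:3])) + 0
  )$overall$r, 1, tolerance = 1e-12)
  set.seed(15)
  base <- matrix(rnorm(5 * 10), 5, 10,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  neg <- cross_platform_correlation(base, -base)
  expect_equal(neg$overall$r, -1, tolerance = 1e-12)

  # shared-signal model: r should recover the planted signal fraction
  rho <- 0.8
  rs <- purrr::map_dbl(1:50, function(s) {
    set.seed(s)
    signal <- matrix(rnorm(10 * 24), 10, 24)
    a <- rho * signal + sqrt(1 - rho^2) * matrix(rnorm(240), 10, 24)
    b <- rho * signal + sqrt(1 - rho^2) * matrix(rnorm(240), 10, 24)
    dimnames(a) <- dimnames(b) <- list(paste0("g", 1:10), paste0("s", 1:24))
    cross_platform_correlation(a, b)$overall$r
  })
  expect_equal(mean(rs), rho^2, tolerance = 0.05)
})
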