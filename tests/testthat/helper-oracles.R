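# Independent oracle implementations used to cross-check the package.
# These are deliberately written brute-force, straight from the published
# formulas, and share no code with the implementations they check.

# a small count matrix with named dims
toy_counts <- function(x, n_genes, n_samples, genes = NULL, samples = NULL) {
  matrix(x, n_genes, n_samples,
         dimnames = list(genes %||% paste0("g", seq_len(n_genes)),
                         samples %||% paste0("s", seq_len(n_samples))))
}

# two-group count matrix with a filler gene equalizing library sizes, so
# group means are directly comparable to unit-offset ML fits
two_group_fixture <- function(y1, y2, total = 1000) {
  y <- c(y1, y2)
  m <- rbind(g1 = y, filler = total - y)
  colnames(m) <- paste0("s", seq_along(y))
  list(m = m, groups = rep(c("a", "b"), c(length(y1), length(y2))))
}

# grid-search / optimize ML of a single NB mean (equal library sizes)
oracle_nb_mean <- function(y, phi, interval = c(1e-3, 1e4)) {
  ll <- function(mu) sum(dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
  stats::optimize(ll, interval, maximum = TRUE, tol = 1e-12)$maximum
}

oracle_nb_loglik <- function(y, mu, phi) {
  sum(dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
}

# trimmed-mean-of-M normalization, coded independently from the published
# algorithm (reference by upper-quartile rule, 30%/5% double trim,
# inverse-variance weights, geometric-mean-1 rescaling)
oracle_tmm <- function(m) {
  lib <- colSums(m)
  f75 <- apply(sweep(m, 2, lib, "/"), 2, quantile, probs = 0.75)
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(m)), function(j) {
    y <- m[, j]; r <- m[, ref]; nO <- lib[j]; nR <- lib[ref]
    logR <- log2((y / nO) / (r / nR))
    absE <- (log2(y / nO) + log2(r / nR)) / 2
    v <- (nO - y) / (nO * y) + (nR - r) / (nR * r)
    keep <- is.finite(logR) & is.finite(absE) & absE > -1e10
    logR <- logR[keep]; absE <- absE[keep]; v <- v[keep]
    if (max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * 0.3) + 1; hiL <- n + 1 - loL
    loS <- floor(n * 0.05) + 1; hiS <- n + 1 - loS
    k <- rank(logR) >= loL & rank(logR) <= hiL &
      rank(absE) >= loS & rank(absE) <= hiS
    fj <- 2^(sum(logR[k] / v[k]) / sum(1 / v[k]))
    if (!is.finite(fj)) fj <- 1
    fj
  }, numeric(1))
  f / exp(mean(log(f)))
}

# classical MDS by explicit double centering + eigendecomposition
oracle_cmdscale <- function(d, k = 2) {
  d2 <- as.matrix(d)^2
  n <- nrow(d2)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% d2 %*% J
  e <- eigen(B, symmetric = TRUE)
  e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(e$values[seq_len(k)], 0)), k)
}

# nearest-shrunken-centroid statistics from the published formulas
oracle_nsc <- function(x, labels, delta, s0 = NULL) {
  classes <- sort(unique(labels))
  n <- ncol(x); K <- length(classes)
  nk <- sapply(classes, function(k) sum(labels == k))
  xbar <- apply(x, 1, mean)
  cent <- sapply(classes, function(k) apply(x[, labels == k, drop = FALSE], 1, mean))
  s2 <- rep(0, nrow(x))
  for (k in classes) {
    xk <- x[, labels == k, drop = FALSE]
    s2 <- s2 + apply((xk - cent[, k])^2, 1, sum)
  }
  s <- sqrt(s2 / (n - K))
  if (is.null(s0)) s0 <- median(s)
  mk <- sqrt(1 / nk - 1 / n)
  d <- (cent - xbar) / outer(s + s0, mk)
  dprime <- sign(d) * pmax(abs(d) - delta, 0)
  shrunk <- xbar + outer(s + s0, mk) * dprime
  prior <- nk / n
  score <- function(xs) {
    unname(sapply(seq_along(classes), function(k) {
      sum((xs - shrunk[, k])^2 / (s + s0)^2) - 2 * log(prior[k])
    }))
  }
  list(d = d, dprime = dprime, shrunk = shrunk, s = s, s0 = s0,
       genes = rownames(x)[apply(dprime != 0, 1, any)],
       classes = classes, score = score)
}

# closed-form two-class LDA pieces
oracle_lda_direction <- function(x, labels, gamma) {
  classes <- sort(unique(labels))
  mu0 <- rowMeans(x[, labels == classes[1], drop = FALSE])
  mu1 <- rowMeans(x[, labels == classes[2], drop = FALSE])
  S <- matrix(0, nrow(x), nrow(x))
  for (k in classes) {
    xk <- x[, labels == k, drop = FALSE]
    mu <- rowMeans(xk)
    S <- S + tcrossprod(xk - mu)
  }
  S <- S / (ncol(x) - 2)
  solve(S + diag(gamma, nrow(x)), mu1 - mu0)
}

# reference-gene stability by direct variance decomposition
oracle_stability <- function(y, groups) {
  grand <- mean(y, na.rm = TRUE)
  vals <- sapply(unique(groups), function(g) {
    yg <- y[groups == g]; yg <- yg[!is.na(yg)]
    abs(mean(yg) - grand) +
      sqrt((if (length(yg) > 1) var(yg) else 0) / length(yg))
  })
  mean(vals)
}

# small balanced 2x2 simulated dataset used by several suites
small_sim <- function(seed = 1, n_genes = 400, ...) {
  simulate_counts(sim_design(n_genes = n_genes, seed = seed, ...))
}

null_fractions <- c(hypoxia_up = 0, hypoxia_down = 0, temp_only = 0,
                    interaction = 0, null = 1)
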