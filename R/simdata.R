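#' Describe a synthetic two-factor expression experiment
#'
#' Builds the design object consumed by [simulate_counts()] and
#' [simulate_ct()]. The defaults emulate a 2 x 2 dissolved-oxygen (DO) by
#' temperature tank experiment read to bulk RNA-seq depth: six fish per
#' treatment cell, ~5,000 expressed genes, library sizes in the 9.4-16.9
#' million read range, negative-binomial dispersion 0.1, and planted gene
#' classes - genes shifted by hypoxia in the same direction at both
#' temperatures (up or down), genes responding to temperature only, genes
#' whose DO response flips sign between temperatures (interaction), and
#' null genes.
#'
#' @param n_per_group Samples per cell of the 2 x 2 DO-by-temperature design.
#' @param n_genes Total number of simulated genes.
#' @param fractions Named proportions of the gene classes `hypoxia_up`,
#'   `hypoxia_down`, `temp_only`, `interaction`, `null`; must sum to 1.
#' @param effect_size Magnitude of the planted log2 fold change.
#' @param dispersion Negative-binomial dispersion phi (variance = mu + phi mu^2).
#' @param lib_size_range Length-2 numeric, min/max expected library size.
#' @param seed Integer RNG seed.
#' @return A list of class `sim_design`.
#' @export
#' @examples
#' d <- sim_design(n_genes = 500, seed = 1)
#' sim <- simulate_counts(d)
#' dim(sim$counts)
sim_design <- function(n_per_group = 6,
                       n_genes = 5000,
                       fractions = c(hypoxia_up = 0.02, hypoxia_down = 0.03,
                                     temp_only = 0.05, interaction = 0.02,
                                     null = 0.88),
                       effect_size = 2,
                       dispersion = 0.1,
                       lib_size_range = c(9.4e6, 16.9e6),
                       seed = 1L) {
  classes <- c("hypoxia_up", "hypoxia_down", "temp_only", "interaction", "null")
  if (!setequal(names(fractions), classes)) {
    abort("`fractions` must be named with the five gene classes.")
  }
  fractions <- fractions[classes]
  if (abs(sum(fractions) - 1) > 1e-8) abort("`fractions` must sum to 1.")
  if (any(fractions < 0)) abort("`fractions` must be nonnegative.")
  if (n_per_group < 2) abort("`n_per_group` must be at least 2.")
  if (!is.finite(effect_size)) abort("`effect_size` must be finite.")
  if (!is.finite(dispersion) || dispersion <= 0) abort("`dispersion` must be positive.")
  if (length(lib_size_range) != 2 || any(lib_size_range <= 0) ||
      lib_size_range[1] > lib_size_range[2]) {
    abort("`lib_size_range` must be an increasing pair of positive sizes.")
  }
  structure(
    list(
      n_per_group = as.integer(n_per_group), n_genes = as.integer(n_genes),
      fractions = fractions, effect_size = effect_size,
      dispersion = dispersion, lib_size_range = lib_size_range,
      seed = as.integer(seed)
    ),
    class = "sim_design"
  )
}

# assign gene classes deterministically by proportion (rounded, remainder
# to null) so fractions are exact up to integer rounding
assign_classes <- function(n_genes, fractions) {
  counts <- floor(fractions * n_genes)
  counts["null"] <- n_genes - sum(counts[names(counts) != "null"])
  rep(names(counts), times = counts)
}

#' Simulate a gene-by-sample count matrix with planted effects
#'
#' Draws negative-binomial counts for a 2 x 2 DO-by-temperature design.
#' Baseline gene abundances are log-normal (so a realistic fraction of genes
#' falls under a counts-per-million filter); planted effects are additive on
#' the log2 mean. Hypoxia-consistent genes shift in the same direction at
#' both temperatures, `temp_only` genes shift only with temperature, and
#' `interaction` genes get +effect in hypoxia at 10 degrees and -effect at
#' 18 degrees, which is exactly the signature a direction-consistent
#' intersection must reject.
#'
#' @param design A [sim_design()] object.
#' @return A list with `counts` (integer matrix, genes x samples), `samples`
#'   (tibble: sample_id, do_group, temperature, trial), and `truth` (tibble:
#'   gene_id, class, and the true log2 fold changes `lfc_do_10`, `lfc_do_18`
#'   for hypoxia minus normoxia at each temperature and `lfc_temp` for
#'   18 minus 10 degrees).
#' @export
simulate_counts <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(design$seed)
  n_g <- design$n_genes
  npg <- design$n_per_group
  e <- design$effect_size
  phi <- design$dispersion

  samples <- tidyr::expand_grid(
    do_group = c("normoxia", "hypoxia"),
    temperature = c(10, 18),
    rep = seq_len(npg)
  )
  samples <- dplyr::mutate(
    samples,
    sample_id = sprintf("s%02d_%s_%d", dplyr::row_number(),
                        substr(.data$do_group, 1, 1), .data$temperature),
    trial = ifelse(.data$rep <= ceiling(npg / 2), "trial3", "trial4")
  )
  n_s <- nrow(samples)

  gene_id <- sprintf("g%05d", seq_len(n_g))
  class <- assign_classes(n_g, design$fractions)

  lfc_do_10 <- ifelse(class == "hypoxia_up", e,
               ifelse(class == "hypoxia_down", -e,
               ifelse(class == "interaction", e, 0)))
  lfc_do_18 <- ifelse(class == "hypoxia_up", e,
               ifelse(class == "hypoxia_down", -e,
               ifelse(class == "interaction", -e, 0)))
  lfc_temp <- ifelse(class == "temp_only", e, 0)

  # baseline relative abundance, heavy-tailed so the cpm filter bites
  base <- rlnorm(n_g, meanlog = 0, sdlog = 2.5)
  prop <- base / sum(base)
  lib <- runif(n_s, design$lib_size_range[1], design$lib_size_range[2])

  hyp <- as.numeric(samples$do_group == "hypoxia")
  t18 <- as.numeric(samples$temperature == 18)
  # genes x samples log2 shift (planted effects centered so the hypoxia
  # contrast is lfc while the baseline stays the normoxia mean)
  shift <- outer(lfc_do_10, hyp * (1 - t18)) +
    outer(lfc_do_18, hyp * t18) +
    outer(lfc_temp, t18)
  mu <- (prop %o% lib) * 2^shift
  counts <- matrix(
    rnbinom(n_g * n_s, size = 1 / phi, mu = mu),
    nrow = n_g,
    dimnames = list(gene_id, samples$sample_id)
  )

  list(
    counts = counts,
    samples = tibble(
      sample_id = samples$sample_id,
      do_group = samples$do_group,
      temperature = samples$temperature,
      trial = samples$trial
    ),
    truth = tibble(
      gene_id = gene_id, class = class,
      lfc_do_10 = lfc_do_10, lfc_do_18 = lfc_do_18, lfc_temp = lfc_temp
    )
  )
}

#' Simulate a qPCR Ct matrix for a multi-factor validation cohort
#'
#' Emulates a microfluidics qPCR run of a small biomarker panel on a cohort
#' spanning smolt stages, salinities, dissolved-oxygen groups and
#' live/distressed status, plus one inter-array calibrator sample. Target
#' Ct values are the assay baseline minus the planted log2 expression shift
#' (one Ct per doubling, i.e. 100% amplification efficiency) plus Gaussian
#' technical noise; the housekeeping assay carries no group effect.
#' Distressed fish receive an extra global downshift (higher expression) on
#' a configurable subset of panel genes, reproducing the observation that
#' mortality status separates samples.
#'
#' @param panel Character vector of assay ids; must include `housekeeping`.
#' @param design A [sim_design()] object (supplies effect size and seed).
#' @param truth Truth tibble from [simulate_counts()]; assays in `panel`
#'   that match `truth$gene_id` inherit that gene's class, others are null.
#' @param housekeeping Id of the housekeeping assay within `panel`.
#' @param n_live,n_distressed Samples per (stage, salinity, DO) cell.
#' @param sigma_tech Technical noise SD on the Ct scale (cycles).
#' @param missing_rate Probability that any Ct cell is missing.
#' @param distressed_shift Extra log2 upshift applied to `distressed_genes`
#'   in distressed fish.
#' @param distressed_genes Assays receiving the distressed shift; defaults
#'   to the first half of the non-housekeeping panel.
#' @return A list with `ct` (assay x sample matrix), `housekeeping`,
#'   `calibrator` (the added calibrator sample id), `samples` (tibble:
#'   sample_id, do_group, temperature, salinity, smolt_stage, status), and
#'   `shifts` (assay x sample matrix of planted log2 expression shifts).
#' @export
simulate_ct <- function(panel, design, truth,
                        housekeeping = "housekeeping",
                        n_live = 10, n_distressed = 3,
                        sigma_tech = 0.25, missing_rate = 0.02,
                        distressed_shift = 1.5,
                        distressed_genes = NULL) {
  stopifnot(inherits(design, "sim_design"))
  if (!housekeeping %in% panel) {
    abort("`panel` must include the designated housekeeping assay.")
  }
  set.seed(design$seed + 1L)
  targets <- setdiff(panel, housekeeping)
  if (is.null(distressed_genes)) {
    distressed_genes <- head(targets, ceiling(length(targets) / 2))
  }

  cohort <- tidyr::expand_grid(
    smolt_stage = c("pre", "smolt", "de-smolt"),
    salinity = c("FW", "BW", "SW"),
    do_group = c("normoxia", "hypoxia"),
    status = c("live", "distressed")
  )
  cohort$n <- ifelse(cohort$status == "live", n_live, n_distressed)
  samples <- tidyr::uncount(cohort, weights = .data$n)
  samples$temperature <- rep_len(c(10, 18), nrow(samples))
  samples$sample_id <- sprintf("v%03d", seq_len(nrow(samples)))

  cls <- setNames(truth$class, truth$gene_id)
  e <- design$effect_size
  hyp <- as.numeric(samples$do_group == "hypoxia")
  t18 <- as.numeric(samples$temperature == 18)
  dis <- as.numeric(samples$status == "distressed")

  shift_for <- function(a) {
    k <- if (a %in% names(cls)) cls[[a]] else "null"
    s <- switch(k,
      hypoxia_up = e * hyp,
      hypoxia_down = -e * hyp,
      temp_only = e * t18,
      interaction = e * hyp * (1 - t18) - e * hyp * t18,
      rep(0, nrow(samples))
    )
    if (a %in% distressed_genes) s <- s + distressed_shift * dis
    s
  }
  shifts <- t(vapply(targets, shift_for, numeric(nrow(samples))))

  mu_hk <- 20
  base_ct <- setNames(runif(length(targets), 22, 30), targets)
  ct_targets <- base_ct - shifts +
    matrix(rnorm(length(shifts), 0, sigma_tech), nrow = nrow(shifts))
  ct_hk <- mu_hk + rnorm(nrow(samples), 0, sigma_tech)
  ct <- rbind(matrix(ct_hk, nrow = 1), ct_targets)
  rownames(ct) <- c(housekeeping, targets)
  colnames(ct) <- samples$sample_id

  # inter-array calibrator: a clean no-shift sample, never missing
  cal_id <- "calibrator"
  cal <- c(mu_hk, base_ct) + rnorm(nrow(ct), 0, sigma_tech)
  if (missing_rate > 0) {
    miss <- matrix(rbinom(length(ct), 1, missing_rate) == 1, nrow = nrow(ct))
    ct[miss] <- NA_real_
  }
  ct <- cbind(ct, cal)
  colnames(ct)[ncol(ct)] <- cal_id

  shifts_full <- rbind(matrix(0, 1, ncol(shifts)), shifts)
  rownames(shifts_full) <- c(housekeeping, targets)
  shifts_full <- cbind(shifts_full, 0)
  colnames(shifts_full) <- colnames(ct)

  list(
    ct = ct,
    housekeeping = housekeeping,
    calibrator = cal_id,
    samples = tibble(
      sample_id = samples$sample_id,
      do_group = samples$do_group,
      temperature = samples$temperature,
      salinity = samples$salinity,
      smolt_stage = samples$smolt_stage,
      status = samples$status
    ),
    shifts = shifts_full
  )
}

#' Write simulated data to disk
#'
#' Writes the count matrix as TSV (first column `gene_id`), the sample table
#' as CSV, and the truth table as JSON.
#'
#' @param sim Result of [simulate_counts()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    samples = file.path(dir, "samples.csv"),
    truth = file.path(dir, "truth.json")
  )
  write_counts(sim$counts, paths["counts"])
  readr::write_csv(sim$samples, paths["samples"])
  jsonlite::write_json(sim$truth, paths["truth"], digits = NA)
  invisible(paths)
}
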