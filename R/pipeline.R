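# Configuration-driven orchestration: YAML config, the discovery run
# (counts -> panel) and the validation run (Ct -> per-stratum reports),
# each writing intermediates plus a reproducibility manifest.

default_config <- function() {
  list(
    seed = 1L,
    outdir = "hypoxpanel_out",
    counts = NULL, metadata = NULL, ct = NULL,
    simulation = NULL, # a list of sim_design() arguments, or NULL
    alpha = 0.05, p_excl = 0.1, k_down = 20, k_up = 10,
    cpm_threshold = NULL, min_samples = NULL, d0 = 10,
    train_fraction = 2 / 3, cv_folds = 5, n_thresholds = 30,
    min_class_size = 4
  )
}

#' Read a pipeline configuration
#'
#' Loads a YAML file and fills unset fields with the pipeline defaults
#' (alpha = 0.05, p_excl = 0.1, k_down = 20, k_up = 10, train_fraction =
#' 2/3, data-driven cpm rule). A `simulation:` block (arguments for
#' [sim_design()]) may replace the `counts`/`metadata` paths.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides Named list overriding any field.
#' @return A config list.
#' @export
read_pipeline_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    cfg <- modifyList(cfg, yaml::read_yaml(path))
  }
  cfg <- modifyList(cfg, overrides)
  stopifnot(cfg$alpha > 0, cfg$alpha <= 1, cfg$p_excl > 0, cfg$p_excl <= 1,
            cfg$k_down >= 0, cfg$k_up >= 0,
            cfg$train_fraction > 0, cfg$train_fraction < 1)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

write_manifest <- function(cfg, dir, extra = list()) {
  manifest <- c(list(
    config = cfg[!vapply(cfg, is.null, logical(1))],
    config_hash = rlang::hash(cfg),
    seed = cfg$seed,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("hypoxpanel"))
  ), extra)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

resolve_discovery_inputs <- function(cfg) {
  if (!is.null(cfg$simulation)) {
    design <- do.call(sim_design, modifyList(cfg$simulation,
                                             list(seed = cfg$seed)))
    sim <- simulate_counts(design)
    list(counts = sim$counts, meta = sim$samples, truth = sim$truth)
  } else {
    if (is.null(cfg$counts) || is.null(cfg$metadata)) {
      abort("config needs `counts` + `metadata` paths or a `simulation` block.")
    }
    meta <- readr::read_csv(cfg$metadata, show_col_types = FALSE)
    req <- c("sample_id", "do_group", "temperature")
    if (!all(req %in% names(meta))) {
      abort(paste("metadata is missing column(s):",
                  paste(setdiff(req, names(meta)), collapse = ", ")))
    }
    counts <- read_counts(cfg$counts)
    if (!setequal(colnames(counts), meta$sample_id)) {
      abort("sample ids differ between the count matrix and the metadata.")
    }
    list(counts = counts, meta = meta, truth = NULL)
  }
}

#' Run the discovery workflow from a configuration
#'
#' Filter, normalize, MDS screen, per-temperature NB contrasts,
#' direction-consistent intersection, candidate PCA ranking and panel
#' selection; writes every intermediate (DE table, candidate panel, PCA
#' scores, MDS coordinates, stage-count log) plus a manifest to
#' `cfg$outdir`.
#'
#' @param cfg Config list from [read_pipeline_config()].
#' @return The [discover_panel()] result, invisibly-ish (returned).
#' @export
run_discover <- function(cfg) {
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  inp <- resolve_discovery_inputs(cfg)
  res <- discover_panel(
    inp$counts, inp$meta,
    alpha = cfg$alpha, p_excl = cfg$p_excl,
    k_down = cfg$k_down, k_up = cfg$k_up, d0 = cfg$d0,
    cpm_threshold = cfg$cpm_threshold, min_samples = cfg$min_samples
  )
  readr::write_tsv(res$de, file.path(cfg$outdir, "de_table.tsv"))
  readr::write_tsv(res$candidates, file.path(cfg$outdir, "candidates.tsv"))
  readr::write_tsv(res$panel, file.path(cfg$outdir, "panel.tsv"))
  readr::write_csv(res$mds$coords, file.path(cfg$outdir, "mds_coords.csv"))
  readr::write_csv(
    as_tibble(res$axes$model$scores, rownames = "sample_id"),
    file.path(cfg$outdir, "pca_scores.csv")
  )
  readr::write_tsv(res$log, file.path(cfg$outdir, "stage_log.tsv"))
  if (!is.null(inp$truth)) {
    jsonlite::write_json(inp$truth, file.path(cfg$outdir, "truth.json"),
                         digits = NA)
  }
  write_manifest(cfg, cfg$outdir,
                 extra = list(stage_log = as.list(setNames(res$log$n,
                                                           res$log$stage))))
  res
}

#' Validate a panel within sample strata
#'
#' Splits the cohort by the given stratification columns, and within each
#' stratum runs [stratified_split()], [evaluate_split()] (NSC then LDA) on
#' the expression matrix. Strata where any class has fewer than
#' `min_class_size` samples are skipped with the reason recorded.
#'
#' @param expr Assays x samples log2 relative-expression matrix.
#' @param meta Sample tibble with `sample_id`, the label column and the
#'   stratification columns.
#' @param strata Character vector of metadata columns defining strata.
#' @param label_col Two-level class column (default `"do_group"`).
#' @param min_class_size Minimum per-class samples for a stratum (default 4).
#' @param train_fraction,cv_folds,n_thresholds,seed Split/NSC settings.
#' @return Tibble with one row per stratum: the stratum key columns, n,
#'   skipped, reason, per-class accuracies, average, selected genes
#'   (list-column) and the `split_report` (list-column).
#' @export
validate_strata <- function(expr, meta, strata, label_col = "do_group",
                            min_class_size = 4, train_fraction = 2 / 3,
                            cv_folds = 5, n_thresholds = 30, seed = 1L) {
  meta <- meta[meta$sample_id %in% colnames(expr), , drop = FALSE]
  keys <- dplyr::distinct(meta[, strata, drop = FALSE])
  out <- purrr::pmap_dfr(keys, function(...) {
    key <- list(...)
    sel <- rep(TRUE, nrow(meta))
    for (k in names(key)) sel <- sel & meta[[k]] == key[[k]]
    sub <- meta[sel, ]
    labs <- setNames(sub[[label_col]], sub$sample_id)
    tab <- table(labs)
    base <- as_tibble(key)
    base$n <- nrow(sub)
    if (length(tab) < 2 || any(tab < min_class_size)) {
      reason <- sprintf("class below minimum size (%s)",
                        paste(sprintf("%s=%d", names(tab), tab),
                              collapse = ", "))
      return(dplyr::bind_cols(base, tibble(
        skipped = TRUE, reason = reason, average_accuracy = NA_real_,
        genes = list(character(0)), report = list(NULL)
      )))
    }
    split <- stratified_split(sub$sample_id, labs,
                              train_fraction = train_fraction, seed = seed)
    rep_ <- evaluate_split(expr[, sub$sample_id, drop = FALSE], labs, split,
                           cv_folds = cv_folds, n_thresholds = n_thresholds,
                           seed = seed)
    dplyr::bind_cols(base, tibble(
      skipped = FALSE, reason = NA_character_,
      average_accuracy = rep_$average_accuracy,
      genes = list(rep_$genes), report = list(rep_)
    ))
  })
  out
}

#' Run the validation workflow from a configuration
#'
#' Reads (or simulates) the Ct matrix and cohort metadata, quantifies
#' relative expression by delta-delta-Ct, then evaluates the panel per
#' stratum: live fish stratified by smolt stage and salinity, distressed
#' fish by salinity — mirroring how a multi-stressor validation cohort is
#' analyzed. Writes a per-stratum summary TSV (classes as columns plus the
#' unweighted average), a JSON report, and a manifest.
#'
#' @param cfg Config list from [read_pipeline_config()]. When
#'   `cfg$simulation` is set, the cohort is simulated with [simulate_ct()]
#'   using a panel of 30 planted genes.
#' @return List: `expr`, `samples`, `strata` (the summary tibble).
#' @export
run_validate <- function(cfg) {
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(cfg$simulation)) {
    design <- do.call(sim_design, modifyList(cfg$simulation,
                                             list(seed = cfg$seed)))
    sim <- simulate_counts(design)
    markers <- sim$truth$gene_id[sim$truth$class %in%
                                   c("hypoxia_up", "hypoxia_down")]
    panel <- c("housekeeping", head(markers, 30))
    ctsim <- simulate_ct(panel, design, sim$truth)
    ct <- ct_matrix(ctsim$ct, ctsim$housekeeping, ctsim$calibrator)
    samples <- ctsim$samples
  } else {
    if (is.null(cfg$ct) || is.null(cfg$metadata)) {
      abort("config needs `ct` + `metadata` paths or a `simulation` block.")
    }
    ct <- read_ct(cfg$ct)
    samples <- readr::read_csv(cfg$metadata, show_col_types = FALSE)
  }
  expr <- suppressWarnings(delta_delta_ct(ct))
  expr <- expr[, setdiff(colnames(expr), ct$calibrator), drop = FALSE]

  live <- samples[samples$status == "live", ]
  dis <- samples[samples$status == "distressed", ]
  res_live <- validate_strata(
    expr, live, strata = c("smolt_stage", "salinity"),
    min_class_size = cfg$min_class_size,
    train_fraction = cfg$train_fraction, cv_folds = cfg$cv_folds,
    n_thresholds = cfg$n_thresholds, seed = cfg$seed
  )
  res_live$status <- "live"
  res_dis <- validate_strata(
    expr, dis, strata = "salinity",
    min_class_size = cfg$min_class_size,
    train_fraction = cfg$train_fraction, cv_folds = cfg$cv_folds,
    n_thresholds = cfg$n_thresholds, seed = cfg$seed
  )
  res_dis$status <- "distressed"
  res_dis$smolt_stage <- NA_character_
  strata <- dplyr::bind_rows(res_live, res_dis)

  summary_tbl <- purrr::pmap_dfr(
    list(seq_len(nrow(strata))), function(i) {
      row <- strata[i, ]
      acc <- if (row$skipped) {
        tibble(N = NA_real_, H = NA_real_)
      } else {
        r <- row$report[[1]]$class_accuracy
        tibble(N = r$accuracy[r$class == "normoxia"],
               H = r$accuracy[r$class == "hypoxia"])
      }
      dplyr::bind_cols(
        tibble(status = row$status, smolt_stage = row$smolt_stage,
               salinity = row$salinity, n = row$n, skipped = row$skipped,
               reason = row$reason),
        acc,
        tibble(Average = row$average_accuracy,
               genes = paste(row$genes[[1]], collapse = ","))
      )
    }
  )
  readr::write_tsv(summary_tbl, file.path(cfg$outdir, "strata_summary.tsv"))
  report <- purrr::map(seq_len(nrow(strata)), function(i) {
    row <- strata[i, ]
    rep_ <- row$report[[1]]
    list(
      status = row$status, smolt_stage = row$smolt_stage,
      salinity = row$salinity, n = row$n, skipped = row$skipped,
      reason = row$reason,
      confusion = if (!row$skipped) as.data.frame(rep_$confusion) else NULL,
      class_accuracy = if (!row$skipped) rep_$class_accuracy else NULL,
      average_accuracy = row$average_accuracy,
      genes = row$genes[[1]]
    )
  })
  jsonlite::write_json(report, file.path(cfg$outdir, "strata_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(cfg, cfg$outdir)
  list(expr = expr, samples = samples, strata = strata,
       summary = summary_tbl)
}
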