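#' Run configuration
#'
#' Bundles everything one reproducible pipeline run needs: the generator
#' configuration (or an input directory of event files), panel, gating
#' tree, QC parameters, the statistics plan and the output directory.
#'
#' @param out_dir Output directory (created if missing).
#' @param cohort A [cohort_config()]; ignored when `input_dir` is given.
#' @param input_dir Optional directory of event files (`.fcs` or `.csv`)
#'   plus `meta.tsv`; when given, the generator is skipped.
#' @param gating_tree A [gating_tree()] or a path readable by
#'   [read_gating_tree()]; defaults to the panel's tree.
#' @param transform `"asinh"` or `"logicle"`.
#' @param n_segments,z_cut Event-cleaning parameters
#'   (see [clean_time_anomalies()]).
#' @param phenotype_max_depth Depth cap for phenotype enumeration.
#' @param phenotype_filter_rule `"all"` or `"median"`.
#' @param fc_day Later day for fold changes (default 1).
#' @param pvca_factors Metadata factors for variance attribution.
#' @param pvca_threshold Cumulative explained-variance cut.
#' @param external_sex_calls Optional named vector of externally supplied
#'   sex calls per sample id (metadata cross-check hook).
#' @param seed Integer master seed (overrides the cohort seed).
#' @return A `RunConfig` list.
#' @export
run_config <- function(out_dir, cohort = cohort_config(), input_dir = NULL,
                       gating_tree = NULL, transform = "asinh",
                       n_segments = NULL, z_cut = 4,
                       phenotype_max_depth = Inf,
                       phenotype_filter_rule = "all",
                       fc_day = 1,
                       pvca_factors = c("dol", "bf_bin", "vaccine_arm",
                                        "site", "sex", "season",
                                        "maternal_age_bin", "plate"),
                       pvca_threshold = 0.9,
                       external_sex_calls = NULL,
                       seed = NULL) {
  if (!is.null(seed)) cohort$seed <- as.integer(seed)
  if (is.character(gating_tree)) {
    if (!file.exists(gating_tree)) stop("missing gating-tree file: ", gating_tree)
    gating_tree <- read_gating_tree(gating_tree)
  }
  structure(list(out_dir = out_dir, cohort = cohort, input_dir = input_dir,
                 gating_tree = gating_tree, transform = transform,
                 n_segments = n_segments, z_cut = z_cut,
                 phenotype_max_depth = phenotype_max_depth,
                 phenotype_filter_rule = phenotype_filter_rule,
                 fc_day = fc_day, pvca_factors = pvca_factors,
                 pvca_threshold = pvca_threshold,
                 external_sex_calls = external_sex_calls),
            class = "RunConfig")
}

#' Default phenotype measurements for a panel
#'
#' Binary marker measurements for every phenotyping marker plus one
#' bivariate polygon filter on (CD45, CD66) capturing the granulocyte
#' region, whose membership enters enumeration as an extra binary
#' dimension.
#'
#' @param panel A [panel_config()].
#' @return List of [measurement_spec()]s.
#' @export
default_measurements <- function(panel) {
  specs <- lapply(panel$phenotype_markers, function(mk) {
    measurement_spec(mk, "marker_threshold", mk)
  })
  poly <- rbind(c(3.2, 3.5), c(6.8, 3.5), c(6.8, 6.8), c(3.2, 6.8))
  c(specs, list(measurement_spec("CD66CD45", "polygon_filter",
                                 c("CD45", "CD66"), polygon = poly)))
}

process_sample <- function(events, cfg, panel, tree, measurements) {
  tspec <- default_transform_spec(events, type = cfg$transform,
                                  cofactor = panel$transform_cofactor)
  ev <- transform_events(events, tspec)
  cl <- clean_time_anomalies(ev, n_segments = cfg$n_segments, z_cut = cfg$z_cut)
  ev <- cl$events
  bead_events <- count_bead_events(ev)
  pc <- apply_gating_tree(ev, tree)
  # per-channel thresholds realized by the tree (first estimate per channel)
  thr <- list()
  if (!is.null(pc$thresholds)) {
    tt <- pc$thresholds[!duplicated(pc$thresholds$channel), ]
    thr <- stats::setNames(as.list(tt$threshold), tt$channel)
  }
  live_idx <- pc$membership[["Live"]]
  phen <- NULL
  if (!is.null(measurements) && sum(live_idx) > 0) {
    live_ev <- subset_events(ev, live_idx)
    need <- vapply(measurements, function(m) {
      m$kind == "marker_threshold" && is.null(thr[[m$name]])
    }, TRUE)
    for (m in measurements[need]) {
      est <- density_threshold(live_ev$exprs[, m$channels],
                               fallback_percentile = 0.98)
      thr[[m$name]] <- est$threshold
    }
    lev <- assign_levels(live_ev, measurements, thr)
    phen <- enumerate_phenotypes(lev, max_depth = cfg$phenotype_max_depth)
  }
  list(report = cl$report, bead_events = bead_events, counts = pc$counts,
       thresholds = pc$thresholds, flags = pc$flags, phenotypes = phen)
}

write_tsv <- function(x, dir, name) {
  p <- file.path(dir, name)
  data.table::fwrite(data.table::as.data.table(x), p, sep = "\t")
  p
}

#' Run the full pipeline
#'
#' Executes generate (or load) -> transform -> event cleaning -> gating ->
#' bead normalization -> phenotype enumeration -> sample QC exclusion ->
#' ontogeny statistics -> variance attribution, writing each stage's tables
#' under `config$out_dir` together with a manifest, and returns a run
#' report.
#'
#' @param config A [run_config()].
#' @param stages Stages to run (subsets always include the generate/gate
#'   core).
#' @param quiet Suppress per-stage log lines.
#' @return A list of class `neonflow_run` with the stage outputs.
#' @export
run_pipeline <- function(config,
                         stages = c("enumerate", "stats", "pvca", "write"),
                         quiet = FALSE) {
  t0 <- Sys.time()
  log_ <- function(...) if (!quiet) message(sprintf(...))
  ccfg <- config$cohort
  panel <- panel_config(ccfg$panel)
  tree <- if (is.null(config$gating_tree)) panel$tree else config$gating_tree
  measurements <- if ("enumerate" %in% stages) default_measurements(panel) else NULL

  if (!is.null(config$input_dir)) {
    meta <- data.table::fread(file.path(config$input_dir, "meta.tsv"))
    files <- list.files(config$input_dir, pattern = "\\.(fcs|csv)$",
                        full.names = TRUE)
    loader <- function(i) {
      f <- files[grepl(meta$sample_id[i], basename(files), fixed = TRUE)][1]
      read_events(f, dialect = if (grepl("\\.fcs$", f)) "fcs" else "csv",
                  channel_roles = panel$roles, sample_id = meta$sample_id[i])
    }
    truth <- NULL
    log_("loaded metadata for %d samples from %s", nrow(meta), config$input_dir)
  } else {
    cohort <- simulate_cohort(ccfg, events = FALSE)
    meta <- cohort$meta
    truth <- cohort$truth
    conc <- cohort$conc
    loader <- function(i) {
      realize_sample_events(conc[i, ], ccfg, panel, meta$sample_id[i],
                            sample_seed_for(ccfg$seed, i))
    }
    log_("simulated cohort: %d subjects, %d samples", ccfg$n_subjects, nrow(meta))
  }
  n <- nrow(meta)

  counts_raw <- NULL
  bead_events <- numeric(n)
  qc_reports <- vector("list", n)
  phen_raw <- NULL
  for (i in seq_len(n)) {
    res <- process_sample(loader(i), config, panel, tree, measurements)
    if (is.null(counts_raw)) {
      counts_raw <- matrix(0, n, length(res$counts),
                           dimnames = list(meta$sample_id, names(res$counts)))
    }
    counts_raw[i, names(res$counts)] <- res$counts
    bead_events[i] <- res$bead_events
    qc_reports[[i]] <- res$report
    if (!is.null(res$phenotypes)) {
      if (is.null(phen_raw)) {
        phen_raw <- matrix(0, n, nrow(res$phenotypes),
                           dimnames = list(meta$sample_id, res$phenotypes$phenotype))
      }
      phen_raw[i, ] <- res$phenotypes$count
    }
  }
  names(bead_events) <- meta$sample_id
  log_("gated %d samples (%d populations)", n, ncol(counts_raw))

  # sample QC: mean - 3 SD thresholds on size-gate and live counts
  thresholds <- sample_exclusion_thresholds(counts_raw[, "Size"],
                                            counts_raw[, "Live"])
  meta_sex <- stats::setNames(as.character(meta$sex), meta$sample_id)
  exclusions <- apply_sample_exclusions(meta$sample_id, counts_raw[, "Size"],
                                        counts_raw[, "Live"], thresholds,
                                        meta_sex, config$external_sex_calls)
  keep <- !exclusions$excluded
  log_("sample QC: excluded %d of %d samples (t_size=%.0f, t_live=%.0f)",
       sum(!keep), n, thresholds$t_size, thresholds$t_live)

  # internal control stability across plates
  control <- NULL
  if (!is.null(meta$plate) && length(unique(meta$plate)) >= 2) {
    n_plates <- length(unique(meta$plate))
    ic <- simulate_internal_control(n_plates, ccfg, n_replicates = 3,
                                    seed = ccfg$seed + 1)
    ic_counts <- lapply(seq_along(ic$samples), function(j) {
      ev <- transform_events(ic$samples[[j]],
                             default_transform_spec(ic$samples[[j]],
                                                    type = config$transform,
                                                    cofactor = panel$transform_cofactor))
      pc <- apply_gating_tree(ev, tree)
      leaf <- setdiff(names(pc$counts),
                      c("All", "Cells", "Size", "Singlets", "Live", "Leukocytes"))
      data.table::data.table(sample_id = ic$meta$sample_id[j],
                             plate = ic$meta$plate[j],
                             population = leaf, count = pc$counts[leaf])
    })
    control <- control_stability_check(data.table::rbindlist(ic_counts))
    log_("internal control: %d/%d populations stable across %d plates",
         sum(control$pass), nrow(control), n_plates)
  }

  # bead-normalized absolute concentrations for retained samples
  kept_ids <- meta$sample_id[keep]
  cells_per_ul <- counts_raw[kept_ids, , drop = FALSE] *
    (ccfg$beads_added / bead_events[kept_ids]) / ccfg$blood_volume_ul
  meta_kept <- meta[keep, ]

  phen <- NULL
  if (!is.null(phen_raw)) {
    phen <- normalize_and_filter(phen_raw[kept_ids, , drop = FALSE],
                                 bead_events[kept_ids], ccfg$beads_added,
                                 ccfg$blood_volume_ul,
                                 min_cells_per_ul = panel$min_cells_per_ul,
                                 rule = config$phenotype_filter_rule)
    log_("phenotypes: %d enumerated, %d above %g cells/ul",
         ncol(phen_raw), length(phen$kept), panel$min_cells_per_ul)
  }

  analysis_pops <- setdiff(colnames(cells_per_ul),
                           c("All", "Cells", "Size", "Singlets", "Live",
                             "Leukocytes"))
  comparisons <- fc <- pv <- NULL
  if ("stats" %in% stages) {
    comparisons <- pairwise_day_comparison(
      cells_per_ul[, analysis_pops, drop = FALSE], meta_kept)
    fc <- fold_change_table(cells_per_ul[, analysis_pops, drop = FALSE],
                            meta_kept, day = config$fc_day)
    nsig <- sum(comparisons$band != "ns", na.rm = TRUE)
    log_("statistics: %d population x contrast rows, %d significant",
         nrow(comparisons), nsig)
  }
  if ("pvca" %in% stages) {
    m2 <- data.table::as.data.table(meta_kept)
    m2$maternal_age_bin <- stratify(m2, "maternal_age")
    lg <- log10(cells_per_ul[, analysis_pops, drop = FALSE] + 1)
    lg <- lg[, apply(lg, 2, stats::sd) > 0, drop = FALSE]  # drop empty pops
    pv <- pvca(lg, m2, config$pvca_factors, config$pvca_threshold,
               condition_on = "dol")
    top <- names(sort(unclass(pv)[setdiff(names(pv), "residual")],
                      decreasing = TRUE))[1:2]
    log_("PVCA: top modelled factors %s, %s", top[1], top[2])
  }

  result <- structure(list(
    meta = meta, truth = truth, counts_raw = counts_raw,
    bead_events = bead_events, thresholds = thresholds,
    exclusions = exclusions, control_stability = control,
    cells_per_ul = cells_per_ul, meta_kept = meta_kept,
    phenotypes = phen, comparisons = comparisons, fold_changes = fc,
    pvca = pv, analysis_populations = analysis_pops,
    qc_reports = qc_reports,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "neonflow_run")

  if ("write" %in% stages) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(
      write_tsv(meta, config$out_dir, "meta.tsv"),
      if (!is.null(truth)) write_tsv(truth, config$out_dir, "truth.tsv"),
      write_tsv(exclusions, config$out_dir, "qc_samples.tsv"),
      write_tsv(data.table::data.table(sample_id = rownames(cells_per_ul),
                                       cells_per_ul),
                config$out_dir, "population_counts.tsv"),
      if (!is.null(comparisons)) write_tsv(comparisons, config$out_dir,
                                           "comparisons.tsv"),
      if (!is.null(fc)) write_tsv(fc, config$out_dir, "fold_changes.tsv"),
      if (!is.null(control)) write_tsv(control, config$out_dir,
                                       "control_stability.tsv"),
      if (!is.null(pv)) write_tsv(
        data.table::data.table(factor = names(pv),
                               proportion = as.numeric(pv)),
        config$out_dir, "pvca.tsv"),
      if (!is.null(phen)) write_tsv(
        data.table::data.table(sample_id = rownames(phen$values),
                               phen$values),
        config$out_dir, "phenotype_counts.tsv"))
    manifest <- list(
      seed = ccfg$seed,
      package_version = as.character(utils::packageVersion("neonflow")),
      n_samples = n, n_excluded = sum(!keep),
      qc_thresholds = thresholds,
      files = as.list(tools::md5sum(unlist(files))))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    result$manifest <- manifest
    log_("wrote outputs to %s", config$out_dir)
  }
  result
}

#' @export
print.neonflow_run <- function(x, ...) {
  cat(sprintf("neonflow run: %d samples, %d excluded, %d analysis populations\n",
              nrow(x$meta), sum(x$exclusions$excluded),
              length(x$analysis_populations)))
  if (!is.null(x$phenotypes)) {
    cat(sprintf("  phenotypes kept: %d (min %g cells/ul)\n",
                length(x$phenotypes$kept), x$phenotypes$min_cells_per_ul))
  }
  if (!is.null(x$pvca)) {
    v <- sort(unclass(x$pvca), decreasing = TRUE)
    cat(sprintf("  PVCA top: %s (%.1f%%)\n", names(v)[1], 100 * v[1]))
  }
  cat(sprintf("  elapsed: %.1f s\n", x$elapsed_s))
  invisible(x)
}

# ---- derived summaries used by the statistics plan ---------------------

#' Hour-binned medians and adjacent-bin contrasts for one population
#'
#' @param counts Samples x populations matrix (cells/ul).
#' @param meta Metadata with `sample_id` and `hours_since_birth`.
#' @param population Population to summarize.
#' @param first_day_width Bin width within the first day (hours).
#' @return List with `summary` (bin, n, median) and `adjacent` (bin pair,
#'   rank-sum p-value).
#' @export
hour_bin_summary <- function(counts, meta, population, first_day_width = 4) {
  meta <- data.table::as.data.table(meta)
  v <- counts[meta$sample_id, population]
  b <- hour_bins(meta$hours_since_birth, first_day_width)
  groups <- split(v, b, drop = FALSE)
  groups <- groups[lengths(groups) > 0]
  summary <- data.table::data.table(
    bin = names(groups), n = lengths(groups),
    median = vapply(groups, stats::median, 0))
  adj <- NULL
  if (length(groups) >= 2) {
    adj <- data.table::rbindlist(lapply(seq_len(length(groups) - 1), function(i) {
      data.table::data.table(
        from = names(groups)[i], to = names(groups)[i + 1],
        p_value = wilcoxon_rank_sum(groups[[i]], groups[[i + 1]]))
    }))
  }
  list(summary = summary, adjacent = adj)
}

#' Vaccine-arm contrasts against the unvaccinated group
#'
#' For each arm and day of life, a rank-sum test of the arm's counts
#' against the `none` arm on the same day, with the mean percent difference.
#' BH adjustment is applied within each arm's family of day contrasts (each
#' vaccine is its own comparison family, mirroring per-vaccine panels).
#'
#' @param counts Samples x populations matrix (cells/ul).
#' @param meta Metadata with `sample_id`, `dol`, `vaccine_arm`.
#' @param population Population to test.
#' @param days Days of life to test (default the later visits 1, 3, 7).
#' @return data.table with `arm`, `dol`, `p_value`, `p_adjusted`,
#'   `mean_increase_pct`, `n_arm`, `n_none`.
#' @export
vaccine_contrasts <- function(counts, meta, population, days = c(1, 3, 7)) {
  meta <- data.table::as.data.table(meta)
  arms <- setdiff(unique(meta$vaccine_arm), "none")
  rows <- list()
  for (arm in arms) {
    for (d in days) {
      x <- counts[meta$sample_id[meta$vaccine_arm == arm & meta$dol == d],
                  population]
      y <- counts[meta$sample_id[meta$vaccine_arm == "none" & meta$dol == d],
                  population]
      if (!length(x) || !length(y)) next
      rows[[length(rows) + 1]] <- data.table::data.table(
        arm = arm, dol = d, p_value = wilcoxon_rank_sum(x, y),
        mean_increase_pct = 100 * (mean(x) / mean(y) - 1),
        n_arm = length(x), n_none = length(y))
    }
  }
  out <- data.table::rbindlist(rows)
  out[, p_adjusted := bh_adjust(p_value), by = arm]
  out[]
}

#' Fold-change versus breastfeeding-delay association
#'
#' Per-subject day-d / day-0 fold changes for one population, joined with
#' the subject's breastfeeding-initiation delay, with the Pearson trend
#' test.
#'
#' @param counts Samples x populations matrix (cells/ul).
#' @param meta Metadata with `subject_id`, `dol`, `breastfeeding_delay_hr`.
#' @param population Population.
#' @param day Later day (default 1).
#' @param max_delay_hr Delays above this are out of range and excluded.
#' @return List with `table` (subject, delay, fc) and `trend`
#'   (`r`, `p_value`, `n`).
#' @export
bf_fc_association <- function(counts, meta, population, day = 1,
                              max_delay_hr = 23) {
  fc <- fold_change_table(counts[, population, drop = FALSE], meta, day = day)
  meta <- data.table::as.data.table(meta)
  delay <- meta$breastfeeding_delay_hr[match(fc$subject_id, meta$subject_id)]
  keep <- !is.na(delay) & delay <= max_delay_hr
  tab <- data.table::data.table(subject_id = fc$subject_id[keep],
                                delay_hr = delay[keep], fc = fc$fc[keep])
  list(table = tab,
       trend = trend_correlation(tab$delay_hr, tab$fc))
}
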