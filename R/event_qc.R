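#' Remove time-localized acquisition anomalies
#'
#' Simplified flow-rate quality control: events are split into `n_segments`
#' contiguous time segments; per segment and marker channel, a robust
#' z-score of the segment mean against the median and MAD of all segment
#' means of that channel is computed; segments whose maximum |z| exceeds
#' `z_cut` are removed.
#'
#' @param events An `EventTable` on the analysis scale with a time channel.
#' @param n_segments Number of segments (default `max(8, events / 2000)`).
#' @param z_cut Removal threshold on the robust z-score (default 4).
#' @return List with the cleaned `events` and a `report` (class `QcReport`)
#'   listing removed segments.
#' @export
clean_time_anomalies <- function(events, n_segments = NULL, z_cut = 4) {
  tch <- channels_by_role(events, "time")
  if (length(tch) != 1) stop("sample has no time channel")
  tv <- events$exprs[, tch]
  if (is.unsorted(tv)) stop("time channel must be non-decreasing")
  ne <- n_events(events)
  if (is.null(n_segments)) n_segments <- max(8, ne %/% 2000)
  if (n_segments < 3) stop("need n_segments >= 3")
  report <- list(sample_id = events$sample_id, events_before = ne,
                 events_after = ne, removed_segments = NULL,
                 excluded = FALSE, exclusion_reason = "none", warning = NULL)
  if (ne < n_segments) {
    report$warning <- "fewer events than segments; no cleaning applied"
    class(report) <- "QcReport"
    return(list(events = events, report = report))
  }
  seg <- cut(seq_len(ne), breaks = n_segments, labels = FALSE)
  markers <- channels_by_role(events, "marker")
  seg_means <- vapply(markers, function(ch) {
    as.vector(tapply(events$exprs[, ch], seg, mean))
  }, numeric(n_segments))
  z <- seg_means
  seg_n <- tabulate(seg, nbins = n_segments)
  for (j in seq_along(markers)) {
    med <- stats::median(seg_means[, j])
    s <- stats::mad(seg_means[, j])
    # floor the scale with the expected sampling SE of a segment mean, so a
    # run of incidentally tight segment means cannot inflate the z-scores
    se <- stats::sd(events$exprs[, markers[j]]) / sqrt(stats::median(seg_n))
    s <- max(s, se)
    z[, j] <- if (s > 0) (seg_means[, j] - med) / s else 0
  }
  bad <- which(apply(abs(z), 1, max) > z_cut)
  if (length(bad)) {
    removed <- do.call(rbind, lapply(bad, function(b) {
      j <- which.max(abs(z[b, ]))
      idx <- which(seg == b)
      data.frame(start_index = min(idx), end_index = max(idx),
                 channel = markers[j], z_score = z[b, j])
    }))
    keep <- !(seg %in% bad)
    events <- subset_events(events, keep)
    report$removed_segments <- removed
    report$events_after <- n_events(events)
  }
  class(report) <- "QcReport"
  list(events = events, report = report)
}

#' Cohort-level sample exclusion thresholds
#'
#' The minimum acceptable count is the cohort mean minus three times the
#' sample (n-1) standard deviation, computed separately for the size-gate
#' event counts and the live-cell counts.
#'
#' @param size_gate_counts Per-sample event counts in the size gate.
#' @param live_counts Per-sample live-cell counts.
#' @return List with `t_size` and `t_live`.
#' @export
sample_exclusion_thresholds <- function(size_gate_counts, live_counts) {
  if (length(size_gate_counts) < 2 || length(live_counts) < 2) {
    stop("thresholds need >= 2 samples")
  }
  list(t_size = mean(size_gate_counts) - 3 * stats::sd(size_gate_counts),
       t_live = mean(live_counts) - 3 * stats::sd(live_counts))
}

#' Apply the sample exclusion rules
#'
#' Excludes samples whose size-gate count falls below `t_size`
#' (`low_total_cells`), whose live count falls below `t_live`
#' (`low_live_cells`), or whose metadata sex conflicts with an externally
#' supplied sex call (`sex_mismatch`).  No sequence data is processed; sex
#' calls come from the caller.
#'
#' @param sample_ids Character vector of sample ids.
#' @param size_gate_counts,live_counts Per-sample counts, aligned with
#'   `sample_ids`.
#' @param thresholds Output of [sample_exclusion_thresholds()].
#' @param meta_sex Optional named vector: metadata sex per sample id.
#' @param external_sex_calls Optional named vector: externally determined
#'   sex per sample id.
#' @return data.table with `sample_id`, `excluded`, `exclusion_reason`.
#' @export
apply_sample_exclusions <- function(sample_ids, size_gate_counts, live_counts,
                                    thresholds, meta_sex = NULL,
                                    external_sex_calls = NULL) {
  reason <- rep("none", length(sample_ids))
  reason[live_counts < thresholds$t_live] <- "low_live_cells"
  reason[size_gate_counts < thresholds$t_size] <- "low_total_cells"
  if (!is.null(external_sex_calls)) {
    if (is.null(meta_sex)) stop("sex-mismatch checking needs metadata sex")
    called <- intersect(names(external_sex_calls), sample_ids)
    mm <- called[external_sex_calls[called] != meta_sex[called]]
    reason[sample_ids %in% mm] <- "sex_mismatch"
  }
  data.table::data.table(sample_id = sample_ids,
                         excluded = reason != "none",
                         exclusion_reason = reason)
}

#' Internal-control stability across plates
#'
#' A Kruskal-Wallis test per population of the control counts across
#' plates; stability passes when p > 0.05 (no detectable plate effect).
#'
#' @param control_counts data.frame/data.table with columns `plate`,
#'   `population`, `count` (>= 1 control per plate, >= 2 plates).
#' @return data.table with `population`, `p_value`, `pass`.
#' @export
control_stability_check <- function(control_counts) {
  cc <- data.table::as.data.table(control_counts)
  plates <- unique(cc$plate)
  if (length(plates) < 2) stop("control stability needs >= 2 plates")
  pops <- unique(cc$population)
  res <- lapply(pops, function(p) {
    sub <- cc[cc$population == p, ]
    if (!all(plates %in% sub$plate)) {
      stop("a plate has zero controls for population ", p)
    }
    groups <- split(sub$count, sub$plate)
    pv <- kruskal_wallis(groups)
    data.table::data.table(population = p, p_value = pv, pass = pv > 0.05)
  })
  data.table::rbindlist(res)
}

#' Per-sample density summaries for visual review
#'
#' The visual QC criteria (sample colour, odd distributions) are outside
#' automated scope; this hook emits compact per-channel density summaries a
#' reviewer can screen instead.
#'
#' @param events An `EventTable` on the analysis scale.
#' @param n_grid Grid points per channel.
#' @return data.table with `channel`, `x`, `density`.
#' @export
density_summary <- function(events, n_grid = 64) {
  chans <- c(channels_by_role(events, "marker"),
             channels_by_role(events, "scatter"))
  data.table::rbindlist(lapply(chans, function(ch) {
    d <- stats::density(events$exprs[, ch], n = n_grid)
    data.table::data.table(channel = ch, x = d$x, density = d$y)
  }))
}
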