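#' Two-sided Wilcoxon rank-sum test
#'
#' Exact p-value for small samples without ties, normal approximation with
#' tie correction otherwise (the default behaviour of [stats::wilcox.test()]).
#'
#' @param x,y Numeric vectors (each non-empty).
#' @return The two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty group in rank-sum test")
  if (length(unique(c(x, y))) == 1) return(1)  # no variation at all
  suppressWarnings(stats::wilcox.test(x, y)$p.value)
}

#' Two-sided Wilcoxon signed-rank test for paired data
#'
#' @param x,y Paired numeric vectors of equal length.
#' @return The two-sided p-value.  All-zero paired differences give p = 1
#'   with attribute `degenerate = TRUE`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (!length(x) || length(x) != length(y)) {
    stop("paired test needs equal-length non-empty vectors")
  }
  if (all(x - y == 0)) {
    return(structure(1, degenerate = TRUE))
  }
  suppressWarnings(stats::wilcox.test(x, y, paired = TRUE)$p.value)
}

#' Kruskal-Wallis test across groups
#'
#' @param groups List of numeric vectors (>= 2 non-empty groups).
#' @return The p-value.
#' @export
kruskal_wallis <- function(groups) {
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 2) stop("Kruskal-Wallis needs >= 2 non-empty groups")
  if (length(unique(unlist(groups))) == 1) return(1)  # no variation at all
  stats::kruskal.test(groups)$p.value
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment, order-preserving and capped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA passed through).
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Signed Cohen's d between an earlier and a later group
#'
#' `d = (mean(early) - mean(late)) / pooled_sd` with the pooled sample
#' standard deviation.  By convention a positive coefficient indicates a
#' mean decreasing from the earlier to the later group, a negative one a
#' mean increasing.
#'
#' @param early,late Numeric vectors with at least 2 values each.
#' @return Signed d.  A zero pooled SD returns a signed infinity sentinel
#'   (0 for identical means) with attribute `undefined = TRUE`.
#' @export
cohens_d <- function(early, late) {
  n1 <- length(early); n2 <- length(late)
  if (n1 < 2 || n2 < 2) stop("Cohen's d needs >= 2 values per group")
  sp <- sqrt(((n1 - 1) * stats::var(early) + (n2 - 1) * stats::var(late)) /
               (n1 + n2 - 2))
  delta <- mean(early) - mean(late)
  if (sp == 0) {
    return(structure(if (delta == 0) 0 else sign(delta) * Inf,
                     undefined = TRUE))
  }
  delta / sp
}

#' Significance bands
#'
#' p in (0.01, 0.05] is "moderately significant", p <= 0.01 "highly
#' significant", otherwise "ns".
#'
#' @param p Numeric p-values.
#' @return Character vector of band labels.
#' @export
significance_band <- function(p) {
  out <- rep("ns", length(p))
  out[p <= 0.05] <- "moderate"
  out[p <= 0.01] <- "high"
  out[is.na(p)] <- NA_character_
  out
}

#' Breastfeeding-initiation delay bins
#'
#' Default edges 0-3, 3-5, 5-23 hours (half-open on the left, final bin
#' closed); delays above 23 hr get the out-of-range label and are excluded
#' from delayed-breastfeeding analyses.  `mode = "tertile"` instead derives
#' edges as empirical tertiles of the positive delays, equalizing group
#' sizes.
#'
#' @param delay_hr Non-negative delays in hours.
#' @param edges Bin edges (default `c(0, 3, 5, 23)`).
#' @param mode `"fixed"` or `"tertile"`.
#' @return Character bin labels (`"0-3"`, `"3-5"`, `"5-23"`, or
#'   `"out_of_range"`).
#' @export
assign_breastfeeding_bin <- function(delay_hr, edges = c(0, 3, 5, 23),
                                     mode = c("fixed", "tertile")) {
  mode <- match.arg(mode)
  if (any(delay_hr < 0, na.rm = TRUE)) stop("delays must be >= 0")
  if (mode == "tertile") {
    pos <- delay_hr[delay_hr > 0 & delay_hr <= max(edges)]
    qs <- stats::quantile(pos, c(1/3, 2/3), names = FALSE)
    edges <- c(edges[1], qs, max(edges))
  }
  labels <- paste0(utils::head(edges, -1), "-", edges[-1])
  out <- rep("out_of_range", length(delay_hr))
  for (i in seq_along(labels)) {
    sel <- if (i == length(labels)) {
      delay_hr >= edges[i] & delay_hr <= edges[i + 1]
    } else {
      delay_hr >= edges[i] & delay_hr < edges[i + 1]
    }
    out[sel] <- labels[i]
  }
  out[is.na(delay_hr)] <- NA_character_
  out
}

#' Per-subject fold change between day 0 and a later day
#'
#' `FC = cells/ul at day d / cells/ul at day 0`, per subject and
#' population.  Subjects missing either visit are omitted; zero
#' denominators are omitted and logged in the `dropped` attribute.
#'
#' @param counts Numeric matrix, samples x populations, in cells/ul.
#' @param meta Metadata with `sample_id`, `subject_id`, `dol`.
#' @param day The later day (1, 3 or 7).
#' @return data.table with `subject_id`, `population`, `fc`.
#' @export
fold_change_table <- function(counts, meta, day = 1) {
  if (day == 0) stop("fold change needs a later day than 0")
  meta <- data.table::as.data.table(meta)
  m0 <- meta[meta$dol == 0, ]
  md <- meta[meta$dol == day, ]
  common <- intersect(m0$subject_id, md$subject_id)
  m0 <- m0[match(common, m0$subject_id), ]
  md <- md[match(common, md$subject_id), ]
  a <- counts[md$sample_id, , drop = FALSE]
  b <- counts[m0$sample_id, , drop = FALSE]
  fc <- a / b
  dropped <- character()
  out <- data.table::data.table(
    subject_id = rep(common, ncol(counts)),
    population = rep(colnames(counts), each = length(common)),
    fc = as.vector(fc))
  bad <- !is.finite(out$fc)
  if (any(bad)) {
    dropped <- unique(out$subject_id[bad])
    out <- out[!bad, ]
  }
  data.table::setattr(out, "dropped", dropped)
  out
}

#' Table-style cross-day comparison of all populations
#'
#' Per population: one Kruskal-Wallis test across all days present, then an
#' unpaired Wilcoxon rank-sum test and signed Cohen's d for each adjacent
#' day pair.  BH adjustment is applied within one contrast family (one
#' contrast across all populations).  With `paired = TRUE` the day pairs are
#' same-subject day-0 versus visit-2 comparisons using the signed-rank test.
#'
#' @param counts Numeric matrix, samples x populations (cells/ul).
#' @param meta Metadata with `sample_id`, `subject_id`, `dol`.
#' @param paired Use the paired day-0-vs-later-day design.
#' @return data.table with one row per population x contrast: `population`,
#'   `contrast`, `test`, `p_value`, `p_adjusted`, `cohens_d`, `n1`, `n2`,
#'   `band`.
#' @export
pairwise_day_comparison <- function(counts, meta, paired = FALSE) {
  meta <- data.table::as.data.table(meta)
  days <- sort(unique(meta$dol))
  if (length(days) < 2) stop("need >= 2 days of life present")
  pops <- colnames(counts)
  pairs <- if (paired) {
    lapply(setdiff(days, 0), function(d) c(0, d))
  } else {
    lapply(seq_len(length(days) - 1), function(i) days[c(i, i + 1)])
  }
  rows <- list()
  for (p in pops) {
    groups <- lapply(days, function(d) counts[meta$sample_id[meta$dol == d], p])
    rows[[length(rows) + 1]] <- data.table::data.table(
      population = p, contrast = "all_days", test = "kruskal",
      p_value = kruskal_wallis(groups), cohens_d = NA_real_,
      n1 = sum(lengths(groups)), n2 = NA_integer_)
    for (pr in pairs) {
      if (!paired) {
        x <- counts[meta$sample_id[meta$dol == pr[1]], p]
        y <- counts[meta$sample_id[meta$dol == pr[2]], p]
        if (!length(x) || !length(y)) next
        pv <- wilcoxon_rank_sum(x, y)
        test <- "wilcoxon_rank_sum"
      } else {
        s0 <- meta[meta$dol == 0, ]
        sd_ <- meta[meta$dol == pr[2], ]
        common <- intersect(s0$subject_id, sd_$subject_id)
        if (!length(common)) next
        x <- counts[s0$sample_id[match(common, s0$subject_id)], p]
        y <- counts[sd_$sample_id[match(common, sd_$subject_id)], p]
        pv <- wilcoxon_signed_rank(x, y)
        test <- "wilcoxon_signed_rank"
      }
      rows[[length(rows) + 1]] <- data.table::data.table(
        population = p,
        contrast = sprintf("DOL%d_vs_DOL%d", pr[1], pr[2]),
        test = test, p_value = as.numeric(pv),
        cohens_d = if (length(x) >= 2 && length(y) >= 2) cohens_d(x, y) else NA_real_,
        n1 = length(x), n2 = length(y))
    }
  }
  out <- data.table::rbindlist(rows)
  out[, p_adjusted := bh_adjust(p_value), by = contrast]
  out[, band := significance_band(p_adjusted)]
  out[]
}

#' Balanced subsampling test for unequal group sizes
#'
#' Repeatedly draws `|small|` samples without replacement from the large
#' group, applies the rank-sum test against the small group, and summarizes
#' the consistency of the p-values across simulations.
#'
#' @param large,small Numeric vectors with `length(large) >= length(small)`.
#' @param n_sims Number of simulations (default 50).
#' @param alpha Significance level for the consistency summary.
#' @param seed Integer seed.
#' @return List with `p_values` (length `n_sims`) and `significant_fraction`.
#' @export
balanced_subsample_test <- function(large, small, n_sims = 50, alpha = 0.05,
                                    seed = 1) {
  if (length(large) < length(small)) {
    stop("the large group must be at least as big as the small group")
  }
  if (n_sims < 1) stop("n_sims must be >= 1")
  set.seed(seed)
  p <- vapply(seq_len(n_sims), function(i) {
    wilcoxon_rank_sum(sample(large, length(small)), small)
  }, 0)
  list(p_values = p, significant_fraction = mean(p <= alpha))
}

#' Pearson trend correlation
#'
#' @param x Predictor (e.g. hours since birth or delay).
#' @param y Response (e.g. counts or fold changes).
#' @param window Optional `c(lo, hi)` restricting to `lo < x <= hi`.
#' @return List with `r`, `p_value`, `n`.
#' @export
trend_correlation <- function(x, y, window = NULL) {
  if (!is.null(window)) {
    keep <- x > window[1] & x <= window[2]
    x <- x[keep]; y <- y[keep]
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("trend correlation needs >= 3 finite pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("trend correlation undefined for zero-variance input")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Stratification labels for clinical contrasts
#'
#' Supported rules: `maternal_age` (under/over 30 years), `time_of_birth`
#' (6-hour windows; morning = 6 am to 12 pm), `sex`, `season`, `site`,
#' `vaccine_vs_none` (each arm against the unvaccinated group).
#'
#' @param meta Metadata table.
#' @param factor One of the rules above.
#' @return Character vector of group labels per row of `meta`.
#' @export
stratify <- function(meta, factor) {
  meta <- data.table::as.data.table(meta)
  switch(factor,
    maternal_age = ifelse(meta$maternal_age_years < 30, "under_30", "30_plus"),
    time_of_birth = as.character(time_of_birth_label(meta$time_of_birth_hr)),
    sex = as.character(meta$sex),
    season = as.character(meta$season),
    site = as.character(meta$site),
    vaccine_vs_none = ifelse(meta$vaccine_arm == "none", "none",
                             as.character(meta$vaccine_arm)),
    stop("unknown stratification factor: ", factor))
}

#' Bin hours since birth for trajectory summaries
#'
#' Fine 4-hour bins over the first day, then the decline window (24-60 hr)
#' and the stable window (60-270 hr).  Bins are half-open on the left; the
#' final bin is closed.
#'
#' @param hours Hours since birth.
#' @param first_day_width Width of the bins within `[0, 24)`.
#' @return Factor of bin labels, ordered by time.
#' @export
hour_bins <- function(hours, first_day_width = 4) {
  edges <- c(seq(0, 24, by = first_day_width), 60, 270)
  labels <- paste0(utils::head(edges, -1), "-", edges[-1])
  cut(hours, breaks = edges, labels = labels, right = FALSE,
      include.lowest = TRUE)
}
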