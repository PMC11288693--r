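#' Measurement specification for phenotype enumeration
#'
#' A measurement is one dimension of the combinatorial immunophenotype
#' space: either a marker with `k` thresholds (giving `k + 1` expression
#' levels) or a 2D polygon filter (inside/outside, treated as a binary
#' dimension).
#'
#' @param name Unique measurement name (used in phenotype labels).
#' @param kind `"marker_threshold"` or `"polygon_filter"`.
#' @param channels One channel (marker) or two (polygon filter).
#' @param n_thresholds Number of thresholds for a marker measurement.
#' @param polygon Vertex matrix for a polygon filter.
#' @return A `MeasurementSpec` list with a `levels` count.
#' @export
measurement_spec <- function(name, kind = c("marker_threshold", "polygon_filter"),
                             channels, n_thresholds = 1, polygon = NULL) {
  kind <- match.arg(kind)
  if (kind == "marker_threshold") {
    stopifnot(length(channels) == 1, n_thresholds >= 1)
    levels <- n_thresholds + 1
  } else {
    stopifnot(length(channels) == 2)
    polygon <- validate_polygon(polygon)
    levels <- 2
  }
  structure(list(name = name, kind = kind, channels = channels,
                 n_thresholds = n_thresholds, polygon = polygon,
                 levels = as.integer(levels)),
            class = "MeasurementSpec")
}

#' Assign per-event levels on every measurement
#'
#' Marker level = number of thresholds strictly below the event's value
#' (so an event exactly at a threshold is on the negative side, matching
#' the 1D gating convention).  Polygon level = 1 inside, 0 outside.
#'
#' @param events An `EventTable` on the analysis scale.
#' @param specs List of [measurement_spec()]s.
#' @param thresholds Named list: for each marker measurement, its strictly
#'   increasing threshold vector.
#' @return Integer `LevelMatrix` (events x measurements), entries in
#'   `[0, levels - 1]`.
#' @export
assign_levels <- function(events, specs, thresholds = list()) {
  nms <- vapply(specs, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("measurement names must be unique")
  out <- matrix(0L, n_events(events), length(specs),
                dimnames = list(NULL, nms))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    if (sp$kind == "marker_threshold") {
      thr <- thresholds[[sp$name]]
      if (is.null(thr)) {
        stop("configuration error: missing threshold for measurement '",
             sp$name, "'")
      }
      if (is.unsorted(thr, strictly = TRUE)) {
        stop("thresholds for '", sp$name, "' must be strictly increasing")
      }
      v <- events$exprs[, sp$channels]
      lev <- integer(length(v))
      for (t in thr) lev <- lev + (v > t)
      out[, i] <- lev
    } else {
      pts <- events$exprs[, sp$channels, drop = FALSE]
      out[, i] <- as.integer(polygon_membership(pts, sp$polygon))
    }
  }
  attr(out, "levels") <- vapply(specs, `[[`, 0L, "levels")
  out
}

# extend dimension j of the joint cube with a marginal "neutral" slot
extend_neutral <- function(A, j) {
  d <- dim(A)
  perm <- c(j, setdiff(seq_along(d), j))
  Ap <- aperm(A, perm)
  M <- matrix(Ap, nrow = d[j])
  M2 <- rbind(M, colSums(M))
  B <- array(M2, c(d[j] + 1L, d[-j]))
  aperm(B, order(perm))
}

#' Enumerate all combinatorial immunophenotypes
#'
#' Counts, for every phenotype code that constrains between 1 and
#' `max_depth` measurements (all remaining measurements neutral), the
#' number of events matching every constrained level.  With `m` binary
#' measurements and unlimited depth this yields `3^m - 1` phenotypes; a
#' depth limit `d` yields `sum_{i=1}^{d} C(m, i) 2^i`.
#'
#' Internally the joint level contingency cube is computed once and
#' marginalized per dimension (a zeta transform), so the cost is
#' `O(events + prod(levels + 1))` rather than per-(event, phenotype).
#'
#' @param levels A `LevelMatrix` from [assign_levels()].
#' @param max_depth Maximum number of constrained measurements
#'   (default unlimited).
#' @param mem_cap Refuse enumerations needing more than this many phenotype
#'   cells (default 5e6).
#' @return data.table with one row per phenotype: `phenotype` (label),
#'   `depth`, `count`, plus one code column per measurement (level index or
#'   NA for neutral).
#' @export
enumerate_phenotypes <- function(levels, max_depth = Inf, mem_cap = 5e6) {
  m <- ncol(levels)
  if (is.null(m) || m == 0) stop("no measurements to enumerate")
  k <- attr(levels, "levels")
  if (is.null(k)) k <- apply(levels, 2, max) + 1L
  cells <- prod(k + 1)
  if (cells > mem_cap) {
    stop(sprintf(paste0("enumeration refused: %d measurements would need ",
                        "%.0f phenotype cells (cap %d)"), m, cells, mem_cap))
  }
  # joint contingency cube over observed levels
  strides <- cumprod(c(1, utils::head(k, -1)))
  lin <- as.vector(1 + levels %*% strides)
  joint <- array(tabulate(lin, nbins = prod(k)), dim = k)
  cube <- joint
  for (j in seq_len(m)) cube <- extend_neutral(cube, j)
  # grid of codes; slot k[j] + 1 (here coded NA) is neutral
  grids <- lapply(seq_len(m), function(j) c(0:(k[j] - 1), NA))
  codes <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  colnames(codes) <- colnames(levels)
  depth <- rowSums(!is.na(codes))
  keep <- depth >= 1 & depth <= max_depth
  out <- data.table::data.table(
    phenotype = phenotype_label_rows(codes[keep, , drop = FALSE], k),
    depth = as.integer(depth[keep]),
    count = as.integer(round(as.vector(cube)[keep])))
  out <- cbind(out, data.table::as.data.table(codes[keep, , drop = FALSE]))
  data.table::setattr(out, "levels", k)
  out[]
}

level_symbol <- function(code, k) {
  # binary measurements use +/- ; multilevel ones use [i]
  if (k == 2) c("-", "+")[code + 1] else sprintf("[%d]", code)
}

phenotype_label_rows <- function(codes, k) {
  nms <- colnames(codes)
  parts <- matrix("", nrow(codes), ncol(codes))
  for (j in seq_len(ncol(codes))) {
    set_ <- !is.na(codes[, j])
    parts[set_, j] <- paste0(nms[j], level_symbol(codes[set_, j], k[j]))
  }
  apply(parts, 1, paste0, collapse = "")
}

#' Canonical label of one phenotype code
#'
#' Measurements appear in panel order; binary levels render as `+`/`-`
#' (polygon filters as `filterName+`/`filterName-`), multilevel markers as
#' `name[level]`; neutral measurements are omitted.
#'
#' @param code Named integer vector (NA = neutral) over the measurements.
#' @param specs The measurement specs (for level counts and order).
#' @return The label string.
#' @export
phenotype_label <- function(code, specs) {
  nms <- vapply(specs, `[[`, "", "name")
  k <- vapply(specs, `[[`, 0L, "levels")
  code <- code[nms]
  if (all(is.na(code))) stop("a phenotype must constrain at least one measurement")
  if (any(code < 0 | code >= k, na.rm = TRUE)) stop("level code out of range")
  m <- matrix(code, nrow = 1, dimnames = list(NULL, nms))
  phenotype_label_rows(m, k)
}

#' Parse a phenotype label back to its code
#'
#' Inverse of [phenotype_label()].
#'
#' @param label Label string.
#' @param specs The measurement specs, in panel order.
#' @return Named integer code vector (NA = neutral).
#' @export
parse_phenotype_label <- function(label, specs) {
  nms <- vapply(specs, `[[`, "", "name")
  k <- vapply(specs, `[[`, 0L, "levels")
  code <- stats::setNames(rep(NA_integer_, length(nms)), nms)
  rest <- label
  for (j in seq_along(nms)) {
    if (!nzchar(rest)) break
    if (!startsWith(rest, nms[j])) next
    tail_ <- substring(rest, nchar(nms[j]) + 1)
    if (k[j] == 2 && (startsWith(tail_, "+") || startsWith(tail_, "-"))) {
      code[j] <- if (startsWith(tail_, "+")) 1L else 0L
      rest <- substring(tail_, 2)
    } else if (k[j] > 2 && startsWith(tail_, "[")) {
      close_ <- regexpr("]", tail_, fixed = TRUE)
      lev <- suppressWarnings(as.integer(substr(tail_, 2, close_ - 1)))
      if (is.na(lev) || lev < 0 || lev >= k[j]) {
        stop("parse error: bad level in '", label, "'")
      }
      code[j] <- lev
      rest <- substring(tail_, close_ + 1)
    }
  }
  if (nzchar(rest)) stop("parse error: unrecognized symbol near '", rest, "'")
  if (all(is.na(code))) stop("parse error: empty phenotype label")
  code
}

#' Bead-normalize and low-abundance-filter phenotype counts
#'
#' Raw per-sample phenotype event counts are converted to cells/ul with the
#' sample's counting-bead statistics; a phenotype is then dropped when its
#' concentration is below the panel minimum (20 cells/ul innate, 10
#' adaptive) in every sample (`rule = "all"`), or below it in the median
#' sample (`rule = "median"`).
#'
#' @param raw Numeric matrix, samples x phenotypes (event counts), row
#'   names = sample ids.
#' @param bead_events Named per-sample bead event counts.
#' @param beads_added Beads spiked per well.
#' @param volume_ul Stained blood volume.
#' @param min_cells_per_ul Panel minimum; or give `panel` instead.
#' @param panel Optional panel name to look the minimum up
#'   (innate = 20, adaptive = 10).
#' @param rule `"all"` or `"median"`.
#' @return List of class `PhenotypeCountMatrix`: `values` (cells/ul,
#'   filtered), `kept`, `dropped` phenotype names.
#' @export
normalize_and_filter <- function(raw, bead_events, beads_added, volume_ul,
                                 min_cells_per_ul = NULL, panel = NULL,
                                 rule = c("all", "median")) {
  rule <- match.arg(rule)
  if (is.null(min_cells_per_ul)) {
    if (is.null(panel)) stop("configuration error: give min_cells_per_ul or panel")
    min_cells_per_ul <- switch(panel, innate = 20, adaptive = 10,
                               stop("configuration error: unknown panel '",
                                    panel, "'"))
  }
  ids <- rownames(raw)
  if (is.null(ids) || !all(ids %in% names(bead_events))) {
    stop("bead statistics missing for some samples")
  }
  factors <- vapply(ids, function(s) {
    beads_normalize(1, bead_events[[s]], beads_added, volume_ul)
  }, 0)
  values <- raw * factors
  below <- values < min_cells_per_ul
  drop <- if (rule == "all") {
    apply(below, 2, all)
  } else {
    apply(values, 2, stats::median) < min_cells_per_ul
  }
  structure(list(values = values[, !drop, drop = FALSE],
                 kept = colnames(raw)[!drop],
                 dropped = colnames(raw)[drop],
                 min_cells_per_ul = min_cells_per_ul),
            class = "PhenotypeCountMatrix")
}
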