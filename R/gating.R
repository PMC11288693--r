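#' Density-based 1D gating threshold
#'
#' Kernel-density analogue of automated valley gating: a Gaussian KDE
#' (Silverman's rule times `bw_adjust`) is evaluated on a 512-point grid
#' spanning the 0.1-99.9 percentile range.  Peaks are local maxima rising
#' above `min_peak_frac` of the global maximum.  With at least two peaks the
#' threshold is the deepest valley between the two largest peaks; otherwise
#' it falls back to the `fallback_percentile` quantile.
#'
#' Two local maxima only count as separate peaks when a genuine valley lies
#' between them: the minimum density between the candidate and the main
#' peak must drop below `min_valley_ratio` times the smaller peak's height.
#' Without this, kernel wiggles on the flank of one mode masquerade as
#' second peaks and the "valley" lands inside the mode.
#'
#' @param values Numeric vector (at least 100 values).
#' @param fallback_percentile Quantile used when the density is unimodal.
#' @param bw_adjust Multiplier on the Silverman bandwidth.
#' @param min_peak_frac Minimum peak height as a fraction of the global
#'   maximum density.
#' @param min_valley_ratio Maximum dip-to-peak ratio for two maxima to
#'   count as separated peaks.
#' @return A list with `threshold` and `mode` (`"valley"` or `"fallback"`).
#' @export
density_threshold <- function(values, fallback_percentile = 0.95,
                              bw_adjust = 1, min_peak_frac = 0.05,
                              min_valley_ratio = 0.8) {
  if (length(values) < 100) {
    stop("insufficient data for density gating (need >= 100 values, got ",
         length(values), ")")
  }
  rng <- stats::quantile(values, c(0.001, 0.999), names = FALSE)
  if (diff(rng) <= 0) {
    return(list(threshold = rng[1], mode = "fallback"))
  }
  d <- stats::density(values, bw = "nrd0", adjust = bw_adjust, n = 512,
                      from = rng[1], to = rng[2])
  y <- d$y
  n <- length(y)
  is_peak <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE)
  peaks <- which(is_peak & y >= min_peak_frac * max(y))
  if (length(peaks) >= 2) {
    peaks <- peaks[order(y[peaks], decreasing = TRUE)]
    main <- peaks[1]
    # second peak = highest maximum with a real valley towards the main one
    for (cand in peaks[-1]) {
      lo <- min(main, cand); hi <- max(main, cand)
      dip <- min(y[lo:hi])
      if (dip <= min_valley_ratio * min(y[main], y[cand])) {
        valley <- lo + which.min(y[(lo + 1):(hi - 1)])
        return(list(threshold = d$x[valley], mode = "valley"))
      }
    }
  }
  list(threshold = stats::quantile(values, fallback_percentile, names = FALSE),
       mode = "fallback")
}

# ---- polygon gates -----------------------------------------------------

polygon_edges <- function(poly) {
  k <- nrow(poly)
  cbind(poly, poly[c(2:k, 1), , drop = FALSE])
}

segments_properly_intersect <- function(p1, p2, q1, q2) {
  o <- function(a, b, c) {
    v <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    sign(v)
  }
  o1 <- o(p1, p2, q1); o2 <- o(p1, p2, q2)
  o3 <- o(q1, q2, p1); o4 <- o(q1, q2, p2)
  o1 != o2 && o3 != o4 && o1 != 0 && o2 != 0 && o3 != 0 && o4 != 0
}

validate_polygon <- function(poly) {
  if (!is.matrix(poly) || ncol(poly) != 2 || nrow(poly) < 3) {
    stop("a polygon needs a matrix of >= 3 (x, y) vertices")
  }
  k <- nrow(poly)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j <= i + 1 || (i == 1 && j == k)) next
      if (segments_properly_intersect(poly[i, ], poly[i %% k + 1, ],
                                      poly[j, ], poly[j %% k + 1, ])) {
        stop("self-intersecting polygon (edges ", i, " and ", j, ")")
      }
    }
  }
  poly
}

#' Point-in-polygon membership
#'
#' Even-odd (ray casting) rule; points on the polygon boundary count as
#' inside.  The polygon must be simple (non-self-intersecting).
#'
#' @param points Numeric matrix (n x 2) of (x, y) points.
#' @param polygon Numeric matrix (k x 2) of ordered vertices.
#' @return Logical vector of length n.
#' @export
polygon_membership <- function(points, polygon) {
  polygon <- validate_polygon(polygon)
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  px <- points[, 1]; py <- points[, 2]
  inside <- logical(length(px))
  on_edge <- logical(length(px))
  k <- nrow(polygon)
  scale <- max(abs(polygon), 1)
  eps <- 1e-9 * scale
  for (i in seq_len(k)) {
    x1 <- polygon[i, 1]; y1 <- polygon[i, 2]
    j <- i %% k + 1
    x2 <- polygon[j, 1]; y2 <- polygon[j, 2]
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    within <- px >= pmin(x1, x2) - eps & px <= pmax(x1, x2) + eps &
      py >= pmin(y1, y2) - eps & py <= pmax(y1, y2) + eps
    on_edge <- on_edge | (abs(cross) <= eps * scale & within)
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  inside | on_edge
}

# ---- gate and tree specifications --------------------------------------

#' Gate specification
#'
#' @param kind `"threshold1d"`, `"rect2d"` or `"polygon"`.
#' @param channels One channel (threshold1d) or two (rect2d, polygon).
#' @param side For threshold1d: `"above"`, `"below"` or `"between"`.  For
#'   rect2d: one side per channel.
#' @param threshold Optional fixed threshold(s); when `NULL` they are
#'   estimated per sample on the parent's events by [density_threshold()].
#' @param vertices Polygon vertex matrix (polygon gates).
#' @param inside For polygon gates, keep events inside (`TRUE`) or outside.
#' @param fallback_percentile Passed to [density_threshold()].
#' @return A `GateSpec` list.
#' @export
gate_spec <- function(kind = c("threshold1d", "rect2d", "polygon"), channels,
                      side = "above", threshold = NULL, vertices = NULL,
                      inside = TRUE, fallback_percentile = 0.95,
                      min_peak_frac = 0.05) {
  kind <- match.arg(kind)
  if (kind == "threshold1d") {
    stopifnot(length(channels) == 1, side %in% c("above", "below", "between"))
    if (side == "between" && (is.null(threshold) || length(threshold) != 2)) {
      stop("side 'between' needs two fixed thresholds")
    }
  } else if (kind == "rect2d") {
    stopifnot(length(channels) == 2)
    side <- rep_len(side, 2)
    stopifnot(all(side %in% c("above", "below")))
  } else {
    stopifnot(length(channels) == 2)
    vertices <- validate_polygon(vertices)
  }
  structure(list(kind = kind, channels = channels, side = side,
                 threshold = threshold, vertices = vertices, inside = inside,
                 fallback_percentile = fallback_percentile,
                 min_peak_frac = min_peak_frac),
            class = "GateSpec")
}

#' Gating tree
#'
#' A named set of populations, each with a parent population and a
#' [gate_spec()].  The root population (all cleaned events) is implicit and
#' called `"All"`.  The tree must be acyclic with every parent defined.
#'
#' @param nodes Named list; each element has `parent` and `gate`.
#' @return A `GatingTree`.
#' @export
gating_tree <- function(nodes) {
  nms <- names(nodes)
  if (is.null(nms) || anyDuplicated(nms)) stop("gating tree nodes must have unique names")
  parents <- vapply(nodes, function(n) n$parent, "")
  unknown <- setdiff(parents, c("All", nms))
  if (length(unknown)) stop("undefined parent population(s): ",
                            paste(unknown, collapse = ", "))
  # topological order; cycles leave nodes unplaced
  placed <- "All"; order <- character()
  remaining <- nms
  while (length(remaining)) {
    ready <- remaining[parents[remaining] %in% placed]
    if (!length(ready)) stop("gating tree contains a cycle involving: ",
                             paste(remaining, collapse = ", "))
    order <- c(order, ready)
    placed <- c(placed, ready)
    remaining <- setdiff(remaining, ready)
  }
  structure(list(nodes = nodes, order = order), class = "GatingTree")
}

#' @export
print.GatingTree <- function(x, ...) {
  cat("GatingTree with", length(x$nodes), "populations\n")
  for (nm in x$order) {
    n <- x$nodes[[nm]]
    cat(sprintf("  %s <- %s [%s: %s]\n", nm, n$parent, n$gate$kind,
                paste(n$gate$channels, collapse = "/")))
  }
  invisible(x)
}

#' Read a gating tree from YAML or JSON
#'
#' The file holds a `nodes` map: each entry has `parent` and a `gate` block
#' mirroring the arguments of [gate_spec()] (polygon `vertices` as a list of
#' `[x, y]` pairs).
#'
#' @param path File ending in `.yaml`/`.yml` or `.json`.
#' @return A [gating_tree()].
#' @export
read_gating_tree <- function(path) {
  if (!file.exists(path)) stop("gating tree file not found: ", path)
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  nodes <- lapply(raw$nodes, function(n) {
    g <- n$gate
    vertices <- if (!is.null(g$vertices)) {
      do.call(rbind, lapply(g$vertices, as.numeric))
    }
    list(parent = n$parent,
         gate = gate_spec(kind = g$kind, channels = unlist(g$channels),
                          side = if (is.null(g$side)) "above" else unlist(g$side),
                          threshold = if (is.null(g$threshold)) NULL else unlist(g$threshold),
                          vertices = vertices,
                          inside = if (is.null(g$inside)) TRUE else g$inside,
                          fallback_percentile = if (is.null(g$fallback_percentile)) 0.95
                                                else g$fallback_percentile,
                          min_peak_frac = if (is.null(g$min_peak_frac)) 0.05
                                          else g$min_peak_frac))
  })
  gating_tree(nodes)
}

# ---- applying the tree -------------------------------------------------

evaluate_gate <- function(exprs, idx, gate, min_events = 100, cache = NULL,
                          parent = "") {
  # returns list(keep = logical over idx, thresholds = data.frame or NULL);
  # estimates are cached per (parent, channel) since sibling nodes share them
  thr_tab <- NULL
  n <- sum(idx)
  estimate <- function(channel) {
    key <- paste0(parent, "\r", channel)
    if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
    v <- exprs[idx, channel]
    est <- if (n >= min_events) {
      density_threshold(v, fallback_percentile = gate$fallback_percentile,
                        min_peak_frac = gate$min_peak_frac)
    } else {
      list(threshold = stats::quantile(v, gate$fallback_percentile, names = FALSE),
           mode = "fallback")
    }
    if (!is.null(cache)) cache[[key]] <- est
    est
  }
  if (gate$kind == "threshold1d") {
    ch <- gate$channels
    if (!is.null(gate$threshold)) {
      thr <- gate$threshold; mode <- "fixed"
    } else {
      est <- estimate(ch); thr <- est$threshold; mode <- est$mode
    }
    v <- exprs[idx, ch]
    keep <- switch(gate$side,
                   above = v > thr[1],
                   below = v <= thr[1],
                   between = v > thr[1] & v <= thr[2])
    thr_tab <- data.frame(channel = ch, threshold = thr[1], mode = mode)
  } else if (gate$kind == "rect2d") {
    keep <- rep(TRUE, n)
    thr_tab <- NULL
    for (j in 1:2) {
      ch <- gate$channels[j]
      if (!is.null(gate$threshold)) {
        thr <- gate$threshold[j]; mode <- "fixed"
      } else {
        est <- estimate(ch); thr <- est$threshold; mode <- est$mode
      }
      v <- exprs[idx, ch]
      keep <- keep & if (gate$side[j] == "above") v > thr else v <= thr
      thr_tab <- rbind(thr_tab, data.frame(channel = ch, threshold = thr, mode = mode))
    }
  } else {
    pts <- exprs[idx, gate$channels, drop = FALSE]
    keep <- polygon_membership(pts, gate$vertices)
    if (!gate$inside) keep <- !keep
  }
  list(keep = keep, thresholds = thr_tab)
}

#' Apply a gating tree to a sample
#'
#' Nodes are evaluated parent-first; data-driven thresholds are re-estimated
#' per sample on the parent population's events.  A node whose parent is
#' empty (or too small for estimation) is flagged and its descendants get
#' zero counts, mirroring the exclusion rule for empty or unusually small
#' parent populations.
#'
#' @param events A cleaned, transformed `EventTable`.
#' @param tree A [gating_tree()].
#' @param min_events Minimum parent events for density estimation.
#' @return A list of class `PopulationCounts` with per-node `counts`,
#'   realized `thresholds`, `flags`, and logical `membership` vectors over
#'   all events.
#' @export
apply_gating_tree <- function(events, tree, min_events = 100) {
  need <- unique(unlist(lapply(tree$nodes, function(n) n$gate$channels)))
  miss <- setdiff(need, events$channels)
  if (length(miss)) stop("gating tree channels absent from sample: ",
                         paste(miss, collapse = ", "))
  nev <- n_events(events)
  membership <- list(All = rep(TRUE, nev))
  counts <- c(All = nev)
  thresholds <- NULL
  flags <- character()
  cache <- new.env(parent = emptyenv())
  for (nm in tree$order) {
    node <- tree$nodes[[nm]]
    parent_idx <- membership[[node$parent]]
    np <- sum(parent_idx)
    if (np == 0) {
      membership[[nm]] <- rep(FALSE, nev)
      counts[nm] <- 0L
      flags <- c(flags, stats::setNames("empty_parent", nm))
      next
    }
    if (np < 10 && is.null(node$gate$threshold) && node$gate$kind != "polygon") {
      membership[[nm]] <- rep(FALSE, nev)
      counts[nm] <- 0L
      flags <- c(flags, stats::setNames("parent_too_small", nm))
      next
    }
    res <- evaluate_gate(events$exprs, parent_idx, node$gate, min_events,
                         cache = cache, parent = node$parent)
    keep <- rep(FALSE, nev)
    keep[which(parent_idx)[res$keep]] <- TRUE
    membership[[nm]] <- keep
    counts[nm] <- sum(keep)
    if (!is.null(res$thresholds)) {
      thresholds <- rbind(thresholds, cbind(population = nm, res$thresholds))
    }
  }
  structure(list(sample_id = events$sample_id, counts = counts,
                 thresholds = thresholds, flags = flags,
                 membership = membership),
            class = "PopulationCounts")
}

# ---- bead normalization ------------------------------------------------

#' Counting-bead normalization to absolute concentration
#'
#' `cells_per_ul = pop_events * (beads_added / bead_events) / volume_ul`.
#'
#' @param pop_events Gated event count(s) for a population.
#' @param bead_events Number of bead events seen in the sample.
#' @param beads_added Number of counting beads spiked into the well.
#' @param volume_ul Blood volume stained, in microliters.
#' @return Concentration(s) in cells per microliter.
#' @export
beads_normalize <- function(pop_events, bead_events, beads_added, volume_ul) {
  if (length(bead_events) != 1 || bead_events <= 0) {
    stop("normalization error: bead_events must be a single positive count")
  }
  if (volume_ul <= 0) stop("normalization error: volume_ul must be positive")
  if (any(pop_events < 0)) stop("population event counts must be non-negative")
  pop_events * (beads_added / bead_events) / volume_ul
}

#' Count bead events on the dedicated bead channel
#'
#' @param events An `EventTable` on the analysis scale.
#' @param channel Bead channel name; defaults to the channel with role
#'   `"bead"`.
#' @param threshold Events above this value count as beads.
#' @return Integer bead event count.
#' @export
count_bead_events <- function(events, channel = NULL, threshold = 4) {
  if (is.null(channel)) {
    channel <- channels_by_role(events, "bead")
    if (length(channel) != 1) stop("sample has no unique bead channel")
  }
  sum(events$exprs[, channel] > threshold)
}
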