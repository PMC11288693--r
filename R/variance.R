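#' PCA summary of a count matrix
#'
#' Centered (optionally unit-scaled) principal component analysis with an
#' explained-variance breakdown and a PC1 loading ranking, used to identify
#' the populations carrying the most variance.
#'
#' @param count_matrix Numeric matrix, samples x populations, no missing
#'   values.
#' @param scale_mode `"center"` or `"unit"` (center and scale to unit
#'   variance).
#' @return List with `scores`, `loadings` (orthonormal columns),
#'   `explained` (fractions summing to 1), and `pc1_ranking` (populations by
#'   absolute PC1 loading).
#' @export
pca_summary <- function(count_matrix, scale_mode = c("center", "unit")) {
  scale_mode <- match.arg(scale_mode)
  if (nrow(count_matrix) < 2 || ncol(count_matrix) < 2) {
    stop("PCA needs >= 2 samples and >= 2 populations")
  }
  if (anyNA(count_matrix)) stop("PCA input must not contain missing values")
  sds <- apply(count_matrix, 2, stats::sd)
  if (all(sds == 0)) stop("PCA undefined for a constant matrix")
  if (scale_mode == "unit" && any(sds == 0)) {
    stop("unit scaling undefined for constant populations: ",
         paste(colnames(count_matrix)[sds == 0], collapse = ", "))
  }
  pc <- stats::prcomp(count_matrix, center = TRUE, scale. = scale_mode == "unit")
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  ranking <- order(abs(pc$rotation[, 1]), decreasing = TRUE)
  list(scores = pc$x, loadings = pc$rotation, explained = expl,
       pc1_ranking = data.table::data.table(
         population = colnames(count_matrix)[ranking],
         pc1_loading = pc$rotation[ranking, 1]))
}

one_way_mom <- function(y, g, shrink = TRUE) {
  # method-of-moments one-way random-effect variance component, clipped at
  # 0 and (optionally) soft-thresholded at its null-sampling SD, which
  # shrinks components estimated from small or unbalanced groupings
  g <- as.factor(g)
  ns <- tapply(y, g, length)
  k <- length(ns); N <- length(y)
  if (k < 2) return(c(sigma_b = 0, sigma_e = stats::var(y)))
  ybar <- mean(y)
  means <- tapply(y, g, mean)
  ssb <- sum(ns * (means - ybar)^2)
  ssw <- sum((y - means[g])^2)
  msb <- ssb / (k - 1)
  msw <- if (N - k > 0) ssw / (N - k) else 0
  n0 <- (N - sum(ns^2) / N) / (k - 1)
  est <- max(0, (msb - msw) / n0)
  if (shrink) {
    tau <- msw * sqrt(2 / (k - 1)) / n0
    est <- max(0, est - tau)
  }
  c(sigma_b = est, sigma_e = msw)
}

#' Principal variance component analysis
#'
#' Attributes dataset variance to clinical/technical factors: PCs are
#' retained up to a cumulative explained-variance threshold; per retained
#' PC, each factor's between-group variance component of the PC scores is
#' estimated by a one-way ANOVA method-of-moments estimator (non-negative);
#' attributions are averaged over PCs weighted by eigenvalues, the
#' remainder is residual, and the output is normalized to sum to 1.
#' Continuous covariates must be binned by the caller.
#'
#' In a longitudinal design the age variable dominates and other covariates
#' may act in opposite directions at different ages (delayed breastfeeding
#' raises counts at birth but blunts the day-1 rise); a marginal grouping
#' would average those deviations away.  `condition_on` names a design
#' factor (typically day of life): its level means are removed from the PC
#' scores and the remaining factors' components are then estimated from the
#' age-by-factor interaction grouping, so age-specific effects accumulate
#' instead of cancelling.
#'
#' @param count_matrix Numeric matrix, samples x populations.
#' @param meta Metadata aligned with the rows of `count_matrix`.
#' @param factors Character vector of categorical metadata columns.
#' @param pc_var_threshold Cumulative explained-variance cut (default 0.6).
#' @param scale_mode Passed to [pca_summary()].
#' @param condition_on Optional design factor (must be among `factors`)
#'   conditioned on when estimating the other factors' components.
#' @return Named numeric proportions (class `VarianceComponents`) over the
#'   usable factors plus `residual`, summing to 1; single-level factors are
#'   excluded with a warning.
#' @export
pvca <- function(count_matrix, meta, factors, pc_var_threshold = 0.6,
                 scale_mode = "unit", condition_on = NULL) {
  meta <- data.table::as.data.table(meta)
  miss <- setdiff(factors, names(meta))
  if (length(miss)) stop("unknown metadata factor(s): ", paste(miss, collapse = ", "))
  usable <- character()
  for (f in factors) {
    if (length(unique(meta[[f]])) >= 2) usable <- c(usable, f)
    else warning("factor '", f, "' has one level; excluded from PVCA")
  }
  if (!length(usable)) stop("no usable factors for PVCA")
  pc <- pca_summary(count_matrix, scale_mode = scale_mode)
  cum <- cumsum(pc$explained)
  n_keep <- max(1, which(cum >= min(pc_var_threshold, max(cum)))[1])
  lambda <- pc$explained[seq_len(n_keep)]
  per_pc <- matrix(0, n_keep, length(usable) + 1,
                   dimnames = list(NULL, c(usable, "residual")))
  cond <- if (!is.null(condition_on) && condition_on %in% usable) condition_on
  for (i in seq_len(n_keep)) {
    y <- pc$scores[, i]
    vtot <- stats::var(y)
    yc <- y
    if (!is.null(cond)) {
      lv <- as.factor(meta[[cond]])
      yc <- y - tapply(y, lv, mean)[lv]
    }
    comp <- vapply(usable, function(f) {
      if (!is.null(cond) && f != cond) {
        g <- interaction(meta[[cond]], meta[[f]], drop = TRUE)
        one_way_mom(yc, g)["sigma_b"]
      } else {
        one_way_mom(y, meta[[f]])["sigma_b"]
      }
    }, 0)
    resid <- max(vtot - sum(comp), 0)
    per_pc[i, ] <- c(comp, resid) / (sum(comp) + resid)
  }
  out <- colSums(per_pc * lambda) / sum(lambda)
  out <- out / sum(out)
  structure(out, class = "VarianceComponents")
}

#' @export
print.VarianceComponents <- function(x, ...) {
  cat("Variance attributed (proportion of total):\n")
  v <- sort(unclass(x), decreasing = TRUE)
  for (nm in names(v)) cat(sprintf("  %-20s %6.2f%%\n", nm, 100 * v[nm]))
  invisible(x)
}

# ---- hierarchy best-path scoring ---------------------------------------

perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

subset_label <- function(code, idx, specs) {
  sub <- code
  sub[setdiff(seq_along(sub), idx)] <- NA_integer_
  phenotype_label(sub, specs)
}

#' Best root-to-target paths through the phenotype hierarchy
#'
#' Scores every way of building up a target phenotype one constraint at a
#' time: each intermediate phenotype is a node weighted by `-log10(p)`, and
#' a path's score is the sum of its node weights.  The `k` highest-scoring
#' paths are found exhaustively for targets of depth <= 6 and by beam
#' search beyond, and returned merged as a DAG with per-node scores and
#' significance bands.
#'
#' @param p_values Named numeric vector: p-value per phenotype label; every
#'   prefix of the target (any subset of its constraints) must be present.
#' @param target Target phenotype label.
#' @param specs Measurement specs (panel order).
#' @param k Number of best paths to return.
#' @param beam_width Beam width for targets deeper than 6.
#' @return List of class `HierarchyGraph`: `paths` (list of label vectors,
#'   root first), `scores`, and `graph` (an igraph DAG; node attributes
#'   `score` and `band`).
#' @export
hierarchy_best_paths <- function(p_values, target, specs, k = 3,
                                 beam_width = 200) {
  code <- parse_phenotype_label(target, specs)
  idx <- which(!is.na(code))
  d <- length(idx)
  node_score <- function(label) {
    if (label == "(root)") return(0)
    p <- p_values[label]
    if (is.na(p)) stop("missing p-value for prefix phenotype '", label, "'")
    -log10(max(p, 1e-300))
  }
  path_labels <- function(order_idx) {
    c("(root)", vapply(seq_along(order_idx), function(i) {
      subset_label(code, order_idx[seq_len(i)], specs)
    }, ""))
  }
  orders <- if (d <= 6) {
    perms(idx)
  } else {
    # beam search over partial constraint sets
    beam <- list(list(order = integer(), score = 0))
    for (step in seq_len(d)) {
      cand <- list()
      for (b in beam) {
        for (nxt in setdiff(idx, b$order)) {
          ord <- c(b$order, nxt)
          sc <- b$score + node_score(subset_label(code, ord, specs))
          cand[[length(cand) + 1]] <- list(order = ord, score = sc)
        }
      }
      sc <- vapply(cand, `[[`, 0, "score")
      keys <- vapply(cand, function(x) paste(sort(x$order), collapse = ","), "")
      keep <- order(sc, decreasing = TRUE)
      seen <- duplicated(keys[keep]) & duplicated(vapply(cand[keep], function(x)
        paste(x$order, collapse = ","), ""))
      beam <- cand[keep[!seen][seq_len(min(beam_width, sum(!seen)))]]
    }
    lapply(beam, `[[`, "order")
  }
  labels <- lapply(orders, path_labels)
  scores <- vapply(labels, function(l) sum(vapply(l, node_score, 0)), 0)
  best <- order(scores, decreasing = TRUE)[seq_len(min(k, length(scores)))]
  paths <- labels[best]
  path_scores <- scores[best]
  # merge into a DAG
  nodes <- unique(unlist(paths))
  edges <- unique(do.call(rbind, lapply(paths, function(p) {
    cbind(utils::head(p, -1), p[-1])
  })))
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges, stringsAsFactors = FALSE),
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  sc <- vapply(nodes, node_score, 0)
  pv <- ifelse(nodes == "(root)", 1, p_values[nodes])
  g <- igraph::set_vertex_attr(g, "score", value = sc)
  g <- igraph::set_vertex_attr(g, "band", value = significance_band(pv))
  structure(list(paths = paths, scores = path_scores, graph = g),
            class = "HierarchyGraph")
}

#' Export a hierarchy graph
#'
#' @param h A `HierarchyGraph`.
#' @param path Output file.
#' @param format `"dot"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_hierarchy <- function(h, path, format = c("dot", "graphml")) {
  format <- match.arg(format)
  igraph::write_graph(h$graph, path, format = format)
  invisible(path)
}
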