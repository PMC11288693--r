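# Independent brute-force oracles used across the suite.  These are written
# from the definitions and deliberately share no code with the package paths
# they check.

# phenotype counts: test every (event, phenotype) pair directly
oracle_phenotype_counts <- function(levels, k, max_depth = Inf) {
  m <- ncol(levels)
  grids <- lapply(seq_len(m), function(j) c(0:(k[j] - 1), NA))
  codes <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  depth <- rowSums(!is.na(codes))
  codes <- codes[depth >= 1 & depth <= max_depth, , drop = FALSE]
  counts <- apply(codes, 1, function(cd) {
    match_ <- rep(TRUE, nrow(levels))
    for (j in seq_len(m)) {
      if (!is.na(cd[j])) match_ <- match_ & (levels[, j] == cd[j])
    }
    sum(match_)
  })
  list(codes = codes, counts = counts)
}

# definitional BH step-up
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# exact two-sided rank-sum p by exhaustive enumeration (no ties)
oracle_rank_sum <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(n1 + n2, n1)
  w_all <- colSums(matrix(seq_len(n1 + n2)[combos], nrow = n1))
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

# exact two-sided signed-rank p by exhaustive sign enumeration (no ties/zeros)
oracle_signed_rank <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
}

# winding-number point-in-polygon (independent of the ray-casting path)
oracle_point_in_polygon <- function(px, py, poly) {
  k <- nrow(poly)
  total <- 0
  on_boundary <- FALSE
  for (i in seq_len(k)) {
    j <- i %% k + 1
    ax <- poly[i, 1] - px; ay <- poly[i, 2] - py
    bx <- poly[j, 1] - px; by <- poly[j, 2] - py
    cross <- ax * by - ay * bx
    dot <- ax * bx + ay * by
    if (abs(cross) < 1e-12 && dot <= 1e-12) on_boundary <- TRUE
    total <- total + atan2(cross, dot)
  }
  on_boundary || abs(total) > pi
}

# tiny event table helper
make_events <- function(m, roles = NULL, sample_id = "t") {
  if (is.null(roles)) {
    roles <- stats::setNames(rep("marker", ncol(m)), colnames(m))
  }
  event_table(m, colnames(m), roles, sample_id)
}
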