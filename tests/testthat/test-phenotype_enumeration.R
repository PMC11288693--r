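unit_square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))

simple_specs <- function() {
  list(measurement_spec("A", "marker_threshold", "A"),
       measurement_spec("B", "marker_threshold", "B"))
}

test_that("level assignment counts thresholds strictly below the value", {
  m <- cbind(A = c(1, 3), B = c(0, 2), Time = c(0, 1))
  ev <- make_events(m, c(A = "marker", B = "marker", Time = "time"))
  lev <- assign_levels(ev, simple_specs(), list(A = 2, B = 2))
  expect_equal(unname(lev[, "A"]), c(0L, 1L))
  expect_equal(unname(lev[, "B"]), c(0L, 0L))
  # value exactly at the threshold is on the negative side
  lev2 <- assign_levels(ev, simple_specs(), list(A = 3, B = 2))
  expect_equal(unname(lev2[, "A"]), c(0L, 0L))
  expect_error(assign_levels(ev, simple_specs(), list(A = 2)), "missing threshold")
})

test_that("a polygon filter contributes an inside/outside level", {
  m <- cbind(X = c(0.5, 2), Y = c(0.5, 2), Time = c(0, 1))
  ev <- make_events(m, c(X = "marker", Y = "marker", Time = "time"))
  sp <- list(measurement_spec("F", "polygon_filter", c("X", "Y"),
                              polygon = unit_square))
  lev <- assign_levels(ev, sp)
  expect_equal(unname(lev[, "F"]), c(1L, 0L))
})

test_that("two all-positive binary markers give the 3^2 - 1 phenotype table", {
  lev <- matrix(1L, 10, 2, dimnames = list(NULL, c("CDa", "CDb")))
  attr(lev, "levels") <- c(2L, 2L)
  out <- enumerate_phenotypes(lev)
  expect_equal(nrow(out), 8)
  expect_equal(out$count[out$phenotype == "CDa+"], 10)
  expect_equal(out$count[out$phenotype == "CDb+"], 10)
  expect_equal(out$count[out$phenotype == "CDa+CDb+"], 10)
  expect_true(all(out$count[grepl("-", out$phenotype, fixed = TRUE)] == 0))
})

test_that("depth-limited enumeration has sum C(m,i) 2^i phenotypes", {
  lev <- matrix(sample(0:1, 20 * 13, TRUE), 20, 13,
                dimnames = list(NULL, paste0("M", 1:13)))
  attr(lev, "levels") <- rep(2L, 13)
  out <- enumerate_phenotypes(lev, max_depth = 2)
  expect_equal(nrow(out), choose(13, 1) * 2 + choose(13, 2) * 4)  # 338
  expect_equal(nrow(out), 338)
  out1 <- enumerate_phenotypes(lev, max_depth = 1)
  expect_equal(nrow(out1), 26)
})

test_that("enumeration matches the per-(event, phenotype) oracle", {
  set.seed(40)
  for (trial in 1:10) {
    m <- sample(2:5, 1)
    k <- sample(2:3, m, TRUE)
    n <- sample(50:200, 1)
    lev <- sapply(seq_len(m), function(j) sample(0:(k[j] - 1), n, TRUE))
    colnames(lev) <- paste0("M", seq_len(m))
    attr(lev, "levels") <- as.integer(k)
    out <- enumerate_phenotypes(lev)
    orc <- oracle_phenotype_counts(lev, k)
    # align by code columns
    key <- function(cd) apply(cd, 1, paste, collapse = "|")
    expect_equal(nrow(out), nrow(orc$codes))
    expect_equal(out$count[match(key(orc$codes), key(as.matrix(out[, -(1:3)])))],
                 orc$counts)
  }
})

test_that("marginalizing any measurement sums its levels exactly", {
  set.seed(41)
  lev <- sapply(1:4, function(j) sample(0:1, 300, TRUE))
  colnames(lev) <- paste0("M", 1:4)
  attr(lev, "levels") <- rep(2L, 4)
  out <- enumerate_phenotypes(lev)
  codes <- as.matrix(out[, -(1:3)])
  key <- function(cd) apply(cd, 1, paste, collapse = "|")
  keys <- key(codes)
  all_na_key <- paste(rep(NA, 4), collapse = "|")
  for (j in 1:4) {
    set_ <- which(!is.na(codes[, j]))
    neutralized <- codes[set_, , drop = FALSE]
    neutralized[, j] <- NA
    agg <- tapply(out$count[set_], key(neutralized), sum)
    # the neutralized phenotype's count; the all-neutral root is the total
    target <- ifelse(names(agg) == all_na_key, nrow(lev),
                     out$count[match(names(agg), keys)])
    expect_equal(as.vector(agg), as.vector(target))
  }
  # adding a constraint never increases a count (depth monotonicity)
  for (i in sample(nrow(out), 50)) {
    cd <- codes[i, ]
    set_ <- which(!is.na(cd))
    if (length(set_) < 2) next
    parent <- cd; parent[set_[1]] <- NA
    expect_gte(out$count[match(key(rbind(parent)), keys)], out$count[i])
  }
})

test_that("labels round-trip through parse for random codes", {
  specs <- list(measurement_spec("CD66", "marker_threshold", "CD66"),
                measurement_spec("CD45", "marker_threshold", "CD45"),
                measurement_spec("gd", "marker_threshold", "gd"),
                measurement_spec("CD16", "marker_threshold", "CD16", n_thresholds = 2),
                measurement_spec("CD66CD45", "polygon_filter", c("CD45", "CD66"),
                                 polygon = unit_square))
  k <- vapply(specs, `[[`, 0L, "levels")
  expect_equal(phenotype_label(c(CD66 = 1, CD45 = 1, gd = NA, CD16 = NA,
                                 CD66CD45 = NA), specs), "CD66+CD45+")
  expect_equal(phenotype_label(c(CD66 = 1, CD45 = 1, gd = 0, CD16 = NA,
                                 CD66CD45 = 1), specs), "CD66+CD45+gd-CD66CD45+")
  set.seed(42)
  for (i in 1:1000) {
    code <- vapply(seq_along(k), function(j) {
      if (runif(1) < 0.5) NA_integer_ else sample(0:(k[j] - 1), 1)
    }, 1L)
    names(code) <- vapply(specs, `[[`, "", "name")
    if (all(is.na(code))) code["CD66"] <- 1L
    lbl <- phenotype_label(code, specs)
    expect_identical(parse_phenotype_label(lbl, specs), code)
  }
  expect_error(phenotype_label(c(CD66 = NA, CD45 = NA, gd = NA, CD16 = NA,
                                 CD66CD45 = NA), specs), "at least one")
  expect_error(parse_phenotype_label("CD66+XYZ-", specs), "parse error")
})

test_that("enumeration refuses to exceed the memory cap", {
  lev <- matrix(0L, 5, 15, dimnames = list(NULL, paste0("M", 1:15)))
  attr(lev, "levels") <- rep(2L, 15)
  expect_error(enumerate_phenotypes(lev, mem_cap = 1e5), "refused")
})

test_that("low-abundance filtering applies the panel minima", {
  raw <- matrix(c(9, 9, 9,    # phenotype P1 in 3 samples, events
                  25, 1, 1,
                  0, 0, 0),
                nrow = 3,
                dimnames = list(c("s1", "s2", "s3"), c("P1", "P2", "P3")))
  beads <- c(s1 = 100, s2 = 100, s3 = 100)
  # factor = (10000/100)/225 = 0.444 cells/ul per event; scale raw to land
  # P1 at 9 cells/ul and P2 at 25 cells/ul in one sample
  raw2 <- raw / ((10000 / 100) / 225)
  adapt <- normalize_and_filter(raw2, beads, 10000, 225, panel = "adaptive")
  expect_false("P1" %in% adapt$kept)          # 9 < 10 everywhere
  expect_equal(adapt$min_cells_per_ul, 10)
  innate <- normalize_and_filter(raw2, beads, 10000, 225, panel = "innate")
  expect_true("P2" %in% innate$kept)          # 25 >= 20 in one sample
  expect_false("P1" %in% innate$kept)
  nothing <- normalize_and_filter(raw2, beads, 10000, 225, min_cells_per_ul = 0)
  expect_equal(nothing$kept, c("P1", "P2", "P3"))
  expect_error(normalize_and_filter(raw2, beads, 10000, 225, panel = "plasma"),
               "unknown panel")
})
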