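test_that("rank-sum p-values match exhaustive enumeration", {
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4)), 2 / 6, tolerance = 1e-12)
  expect_equal(oracle_rank_sum(c(1, 2), c(3, 4)), 2 / 6)
  set.seed(10)
  for (i in 1:25) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- sample(100, n1); y <- sample(200:300, n2)  # no ties
    x <- x + runif(n1, 0, 0.4)
    expect_equal(wilcoxon_rank_sum(x, y), oracle_rank_sum(x, y),
                 tolerance = 1e-10)
  }
  expect_error(wilcoxon_rank_sum(numeric(), 1:3), "empty")
})

test_that("signed-rank p-values match exhaustive sign enumeration", {
  # five positive differences of distinct magnitude
  x <- c(11, 22, 33, 44, 55); y <- c(10, 20, 30, 40, 50)
  expect_equal(wilcoxon_signed_rank(x, y), 2 / 32, tolerance = 1e-12)
  expect_equal(oracle_signed_rank(x - y), 2 / 32)
  set.seed(11)
  for (i in 1:15) {
    n <- sample(4:9, 1)
    d <- sample(c(-1, 1), n, TRUE) * sample(50, n)
    expect_equal(wilcoxon_signed_rank(d, rep(0, n)), oracle_signed_rank(d),
                 tolerance = 1e-10)
  }
  z <- wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3))
  expect_equal(as.numeric(z), 1)
  expect_true(attr(z, "degenerate"))
  expect_error(wilcoxon_signed_rank(1:3, 1:4), "equal-length")
})

test_that("Kruskal-Wallis reproduces the closed-form H statistic", {
  groups <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  # H = 12/(N(N+1)) * sum n_i (rbar_i - rbar)^2 = 7.2 here
  rks <- rank(unlist(groups))
  n <- lengths(groups); N <- sum(n)
  rbar <- tapply(rks, rep(seq_along(groups), n), mean)
  H <- 12 / (N * (N + 1)) * sum(n * (rbar - (N + 1) / 2)^2)
  expect_equal(H, 7.2)
  expect_equal(kruskal_wallis(groups), pchisq(7.2, df = 2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(kruskal_wallis(list(c(2, 2), c(2, 2))), 1)  # no variation
  expect_error(kruskal_wallis(list(1:3)), ">= 2")
})

test_that("BH adjustment equals the definitional step-up oracle", {
  expect_equal(bh_adjust(c(0.04, 0.01, 0.03)), c(0.04, 0.03, 0.04))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(12)
  for (i in 1:1000) {
    p <- runif(sample(1:20, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
  # order-monotone
  p <- runif(15)
  a <- bh_adjust(p)
  expect_true(all(diff(a[order(p)]) >= -1e-12))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("Cohen's d uses the pooled SD and the decrease-positive convention", {
  expect_equal(cohens_d(c(3, 4, 5), c(1, 2, 3)), 2)
  expect_equal(cohens_d(c(1, 2, 3), c(3, 4, 5)), -2)   # antisymmetric
  expect_equal(cohens_d(c(5, 6, 7), c(5, 6, 7)), 0)
  # earlier mean smaller than later mean => negative d ("mean increasing")
  expect_lt(cohens_d(c(1, 2), c(10, 11)), 0)
  z <- cohens_d(c(2, 2), c(1, 1))
  expect_true(is.infinite(z) && z > 0 && attr(z, "undefined"))
  expect_error(cohens_d(1, c(1, 2)), ">= 2")
})

test_that("rank tests are invariant to strictly monotone transforms", {
  set.seed(13)
  x <- rlnorm(12); y <- rlnorm(15, 0.5)
  f <- function(v) log(v + 1) * 3 + 2
  expect_equal(wilcoxon_rank_sum(x, y), wilcoxon_rank_sum(f(x), f(y)))
  g <- list(rlnorm(6), rlnorm(7, 1), rlnorm(5, 2))
  expect_equal(kruskal_wallis(g), kruskal_wallis(lapply(g, f)))
})

test_that("significance bands follow the stated cutpoints", {
  expect_equal(significance_band(c(0.005, 0.03, 0.2, 0.05, 0.01)),
               c("high", "moderate", "ns", "moderate", "high"))
})

test_that("breastfeeding bins use half-open left edges and flag out-of-range", {
  expect_equal(assign_breastfeeding_bin(2.5), "0-3")
  expect_equal(assign_breastfeeding_bin(3.0), "3-5")
  expect_equal(assign_breastfeeding_bin(0), "0-3")
  expect_equal(assign_breastfeeding_bin(23), "5-23")
  expect_equal(assign_breastfeeding_bin(24), "out_of_range")
  expect_error(assign_breastfeeding_bin(-1), ">= 0")
  # tertile mode equalizes positive-delay group sizes
  set.seed(14)
  d <- c(rep(0, 50), runif(90, 0.1, 22))
  b <- assign_breastfeeding_bin(d, mode = "tertile")
  tab <- table(b[d > 0])
  expect_lte(diff(range(tab)), 2)
})

test_that("fold changes are per-subject ratios with missing visits omitted", {
  counts <- matrix(c(100, 150, 80, 0, 120, 60), ncol = 1,
                   dimnames = list(c("a1", "a2", "b1", "c1", "c2", "d1"), "P"))
  meta <- data.frame(sample_id = rownames(counts),
                     subject_id = c("A", "A", "B", "C", "C", "D"),
                     dol = c(0, 1, 0, 0, 1, 1))
  fc <- fold_change_table(counts, meta, day = 1)
  expect_equal(fc$fc[fc$subject_id == "A"], 1.5)
  expect_false("B" %in% fc$subject_id)   # no day-1 visit
  expect_false("C" %in% fc$subject_id)   # zero denominator
  expect_true("C" %in% attr(fc, "dropped"))
  expect_error(fold_change_table(counts, meta, day = 0), "later day")
})

test_that("pairwise day comparison is null on constant counts and fully shaped", {
  ids <- sprintf("s%02d", 1:24)
  meta <- data.frame(sample_id = ids, subject_id = rep(sprintf("P%d", 1:12), 2),
                     dol = rep(c(0, 1, 3, 7), 6))
  counts <- matrix(5, 24, 3, dimnames = list(ids, c("A", "B", "C")))
  out <- pairwise_day_comparison(counts, meta)
  expect_equal(nrow(out), 3 * 4)     # populations x (kruskal + 3 pairs)
  expect_true(all(out$cohens_d[out$contrast != "all_days"] == 0))
  expect_true(all(out$band == "ns"))
  expect_true(all(out$p_adjusted >= out$p_value - 1e-12))
  # paired variant compares day 0 against each later day within subjects
  paired <- pairwise_day_comparison(counts, meta, paired = TRUE)
  expect_true(all(grepl("DOL0_vs_|all_days", paired$contrast)))
})

test_that("balanced subsampling holds size under the null and power under shift", {
  set.seed(15)
  large <- rnorm(1000); small <- rnorm(70)
  res <- balanced_subsample_test(large, small, n_sims = 50, seed = 21)
  expect_length(res$p_values, 50)
  expect_lte(res$significant_fraction, 0.2)
  shifted <- rnorm(70, mean = 2)   # 2 pooled SDs
  res2 <- balanced_subsample_test(large, shifted, n_sims = 50, seed = 22)
  expect_equal(res2$significant_fraction, 1)
  expect_error(balanced_subsample_test(rnorm(10), rnorm(20)), "at least as big")
})

test_that("trend correlation handles exact, null and degenerate input", {
  x <- 1:20
  expect_equal(trend_correlation(x, 2 * x + 1)$r, 1)
  expect_error(trend_correlation(1:2, c(3, 4)), ">= 3")
  expect_error(trend_correlation(x, rep(5, 20)), "zero-variance")
  set.seed(16)
  hits <- mean(replicate(40, abs(trend_correlation(rnorm(100), rnorm(100))$r) < 0.3))
  expect_gte(hits, 0.95)
  # windowing restricts to (lo, hi]
  w <- trend_correlation(c(1:10, 100), c(2 * (1:10), -5), window = c(0, 24))
  expect_equal(w$n, 10)
})

test_that("stratification rules match the stated cutpoints", {
  meta <- data.frame(maternal_age_years = c(29.9, 30, 41),
                     time_of_birth_hr = c(7.5, 5.9, 12),
                     sex = c("F", "M", "F"),
                     season = c("dry", "wet", "dry"),
                     site = c("GAM", "PNG", "GAM"),
                     vaccine_arm = c("BCG", "none", "both"))
  expect_equal(stratify(meta, "maternal_age"), c("under_30", "30_plus", "30_plus"))
  expect_equal(stratify(meta, "time_of_birth"), c("morning", "night", "afternoon"))
  expect_equal(stratify(meta, "vaccine_vs_none"), c("BCG", "none", "both"))
  expect_error(stratify(meta, "shoe_size"), "unknown")
})
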