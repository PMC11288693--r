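test_that("configuration invariants are enforced", {
  expect_error(cohort_config(site_fractions = c(GAM = 0.7, PNG = 0.2)),
               "summing to 1")
  expect_error(cohort_config(n_subjects = 0), "n_subjects")
  expect_error(cohort_config(events_per_sample = 500), ">= 1000")
  expect_error(cohort_config(blood_volume_ul = 0), "blood_volume")
  expect_error(cohort_config(plate_size = 3), "layout error")
  expect_error(trajectory_spec("X", 100, peak_hour = 30), "peak_hour")
  expect_error(effect_spec("vaccine_arm", "BCG", "X", 2, 1.1), "visit_day")
  expect_error(effect_spec("vaccine_arm", "BCG", "X", 1, -1), "multiplier")
  expect_error(simulate_cohort(cohort_config(n_subjects = 2),
                               trajectories = list(), events = FALSE),
               "no trajectory")
  bad_eff <- list(effect_spec("shoe_size", "44", "MatureNeutrophils", 1, 2))
  expect_error(simulate_cohort(cohort_config(n_subjects = 2), effects = bad_eff,
                               events = FALSE),
               "not a metadata column")
})

test_that("every subject gets two visits, the first at day of life 0", {
  co <- simulate_cohort(cohort_config(n_subjects = 10, seed = 60), events = FALSE)
  expect_equal(nrow(co$meta), 20)
  expect_equal(sum(co$meta$dol == 0), 10)
  expect_true(all(table(co$meta$subject_id) == 2))
  expect_true(all(co$meta$dol[co$meta$visit == 1] == 0))
  expect_true(all(co$meta$dol[co$meta$visit == 2] %in% c(1, 3, 7)))
  v1 <- co$meta$hours_since_birth[co$meta$visit == 1]
  expect_true(all(v1 >= 0 & v1 < 24))
})

test_that("identical configuration and seed reproduce the cohort exactly", {
  cfg <- cohort_config(n_subjects = 3, events_per_sample = 1500, seed = 61)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$meta, b$meta)
  expect_identical(a$truth, b$truth)
  for (i in seq_along(a$samples)) {
    expect_identical(a$samples[[i]]$exprs, b$samples[[i]]$exprs)
  }
})

test_that("event realization conserves the configured event count", {
  cfg <- cohort_config(n_subjects = 2, events_per_sample = 4000, seed = 62,
                       events_cv = 0)
  co <- simulate_cohort(cfg)
  for (ev in co$samples) expect_equal(n_events(ev), 4000)
})

test_that("the programmed post-24h decline is recovered from recorded truth", {
  cfg <- cohort_config(n_subjects = 200, seed = 63)
  co <- simulate_cohort(cfg, events = FALSE)
  tru <- co$truth[co$truth$population == "MatureNeutrophils", ]
  h <- co$meta$hours_since_birth[match(tru$sample_id, co$meta$sample_id)]
  dol <- co$meta$dol[match(tru$sample_id, co$meta$sample_id)]
  peak <- median(tru$true_cells_per_ul[h >= 8 & h < 12])
  dol3 <- median(tru$true_cells_per_ul[dol == 3])
  expect_gte(dol3 / peak, 0.45)
  expect_lte(dol3 / peak, 0.55)
  # binned medians over the first day are maximal in the peak-hour bin
  b <- hour_bins(h[dol == 0])
  med <- tapply(tru$true_cells_per_ul[dol == 0], b, median)
  med <- med[!is.na(med)]
  expect_equal(names(which.max(med)), "8-12")
})

test_that("programmed effect multipliers are recovered within 5% at n = 500", {
  cfg <- cohort_config(n_subjects = 500, seed = 64)
  co <- simulate_cohort(cfg, events = FALSE)
  tru <- co$truth[co$truth$population == "MatureNeutrophils", ]
  m <- co$meta[match(tru$sample_id, co$meta$sample_id), ]
  bcg7 <- median(tru$true_cells_per_ul[m$vaccine_arm == "BCG" & m$dol == 7])
  none7 <- median(tru$true_cells_per_ul[m$vaccine_arm == "none" & m$dol == 7])
  expect_lte(abs(bcg7 / none7 - 1.22), 0.05 * 1.22)
  hbv1 <- median(tru$true_cells_per_ul[m$vaccine_arm == "HBV" & m$dol == 1 &
                                         m$bf_bin == "0-3"])
  none1 <- median(tru$true_cells_per_ul[m$vaccine_arm == "none" & m$dol == 1 &
                                          m$bf_bin == "0-3"])
  expect_lte(abs(hbv1 / none1 - 1.21), 0.05 * 1.21)
})

test_that("plate layout balances vaccine arms by block randomization", {
  cfg <- cohort_config(n_subjects = 180, plate_size = 90, seed = 65)
  co <- simulate_cohort(cfg, events = FALSE)
  subj <- unique(co$meta[, c("subject_id", "vaccine_arm", "plate")])
  expect_true(all(table(subj$plate) <= 45))
  # both visits of a subject share the plate
  expect_equal(nrow(unique(co$meta[, c("subject_id", "plate")])), 180)
  # arms spread across plates: each arm appears on every plate
  tab <- table(subj$vaccine_arm, subj$plate)
  expect_true(all(tab > 0))
})

test_that("breastfeeding delay has a point mass at birth and bounded delays", {
  co <- simulate_cohort(cohort_config(n_subjects = 400, seed = 66), events = FALSE)
  subj <- unique(co$meta[, c("subject_id", "breastfeeding_delay_hr")])
  frac0 <- mean(subj$breastfeeding_delay_hr == 0)
  expect_gt(frac0, 0.80); expect_lt(frac0, 0.94)   # around the 87% point mass
  expect_true(all(subj$breastfeeding_delay_hr <= 23))
})

test_that("QC failure injection is counted, labelled and disjoint", {
  cfg <- cohort_config(n_subjects = 10, events_per_sample = 2000, seed = 67)
  co <- simulate_cohort(cfg)
  same <- inject_qc_failures(co$samples, 0, 0, 0, seed = 1)
  expect_identical(same$samples[[3]]$exprs, co$samples[[3]]$exprs)
  expect_true(all(same$truth$failure == "none"))
  inj <- inject_qc_failures(co$samples, 0.1, 0.2, 0.1, seed = 2)
  expect_equal(sum(inj$truth$failure == "low_cells"), 2)
  expect_equal(sum(inj$truth$failure == "dead"), 4)
  expect_equal(sum(inj$truth$failure == "time_anomaly"), 2)
  low <- which(inj$truth$failure == "low_cells")
  for (i in low) {
    expect_lt(n_events(inj$samples[[i]]), 0.25 * 2000)
  }
  dead <- which(inj$truth$failure == "dead")
  for (i in dead) {
    frac_dead <- mean(asinh(inj$samples[[i]]$exprs[, "Viability"] / 150) > 2)
    expect_gte(frac_dead, 0.6)
  }
  expect_error(inject_qc_failures(list(), 0.1), "empty")
  expect_error(inject_qc_failures(co$samples, 0.7, 0.7), "sum <= 1")
})

test_that("internal controls share one subject state across plates", {
  cfg <- cohort_config(n_subjects = 2, events_per_sample = 3000, seed = 68)
  ic <- simulate_internal_control(5, cfg, seed = 3)
  expect_length(ic$samples, 5)
  expect_true(all(ic$meta$subject_id == "internal_control"))
  expect_equal(ic$meta$plate, 1:5)
  # replicate aliquots per plate
  ic3 <- simulate_internal_control(2, cfg, n_replicates = 3, seed = 4)
  expect_length(ic3$samples, 6)
  expect_error(simulate_internal_control(0), ">= 1")
})

test_that("control counts show no plate effect (Kruskal-Wallis p > 0.05)", {
  cfg <- cohort_config(n_subjects = 2, events_per_sample = 5000, seed = 69)
  pass <- vapply(1:5, function(s) {
    ic <- simulate_internal_control(4, cfg, n_replicates = 3, seed = s)
    counts <- data.table::rbindlist(lapply(seq_along(ic$samples), function(j) {
      ev <- transform_events(ic$samples[[j]],
                             default_transform_spec(ic$samples[[j]]))
      pc <- apply_gating_tree(ev, default_gating_tree("innate"))
      data.table::data.table(sample_id = ic$meta$sample_id[j],
                             plate = ic$meta$plate[j],
                             population = "MatureNeutrophils",
                             count = pc$counts[["MatureNeutrophils"]])
    }))
    all(control_stability_check(counts)$pass)
  }, TRUE)
  expect_gte(mean(pass), 0.8)
})
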