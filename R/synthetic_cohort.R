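#' Cohort generator configuration
#'
#' Defines the study conditions emulated by the synthetic neonatal cohort:
#' two samples per subject (birth plus one of day-of-life 1, 3 or 7), two
#' sites, randomized birth vaccines, a breastfeeding-initiation delay with a
#' point mass at zero hours, counting beads spiked into each well, and
#' block-randomized plate layout.
#'
#' @param n_subjects Number of newborns.
#' @param site_fractions Named proportions for sites `GAM` and `PNG`.
#' @param visit2_day_probs Named proportions for the second visit day
#'   (`"1"`, `"3"`, `"7"`).
#' @param vaccine_arm_probs Named proportions for arms `BCG`, `HBV`,
#'   `both`, `none`.
#' @param bf_delay_w0 Weight of the point mass at 0 hr delay (breastfed at
#'   birth); the remaining weight is spread over the delayed bins
#'   (0-3, 3-5, 5-23 hr) with equal probability, uniform within each bin.
#' @param events_per_sample Events acquired per sample (>= 1000).
#' @param blood_volume_ul Whole-blood volume stained, microliters.
#' @param beads_added Counting beads spiked per well.
#' @param plate_size Samples per plate (both visits of a subject share a
#'   plate, so it must be an even number >= 2).
#' @param events_cv Lognormal coefficient of variation of the acquired
#'   event count around `events_per_sample`.
#' @param debris_frac,dead_frac,doublet_frac Fixed event fractions of
#'   debris, dead cells and doublets.
#' @param subject_cv Lognormal coefficient of variation of the per-subject
#'   random level shared by both visits.
#' @param panel `"innate"` or `"adaptive"`.
#' @param seed Integer master seed.
#' @return A validated `CohortConfig` list.
#' @export
cohort_config <- function(n_subjects = 200,
                          site_fractions = c(GAM = 0.95, PNG = 0.05),
                          visit2_day_probs = c(`1` = 1/3, `3` = 1/3, `7` = 1/3),
                          vaccine_arm_probs = c(BCG = 0.23, HBV = 0.22,
                                                both = 0.23, none = 0.32),
                          bf_delay_w0 = 0.87,
                          events_per_sample = 20000,
                          blood_volume_ul = 225,
                          beads_added = 10000,
                          plate_size = 90,
                          events_cv = 0.10,
                          debris_frac = 0.05, dead_frac = 0.025,
                          doublet_frac = 0.03,
                          subject_cv = 0.06,
                          panel = "innate",
                          seed = 1) {
  chk_prop <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop("configuration error: ", what, " must be proportions summing to 1")
    }
  }
  chk_prop(site_fractions, "site_fractions")
  chk_prop(visit2_day_probs, "visit2_day_probs")
  chk_prop(vaccine_arm_probs, "vaccine_arm_probs")
  if (bf_delay_w0 < 0 || bf_delay_w0 > 1) {
    stop("configuration error: bf_delay_w0 must be in [0, 1]")
  }
  if (n_subjects < 1) stop("configuration error: n_subjects must be >= 1")
  if (events_per_sample < 1000) {
    stop("configuration error: events_per_sample must be >= 1000")
  }
  if (blood_volume_ul <= 0) stop("configuration error: blood_volume_ul must be > 0")
  if (plate_size < 2 || plate_size %% 2 != 0) {
    stop("layout error: plate_size must be an even number >= 2 ",
         "(both visits of a subject share a plate)")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 site_fractions = site_fractions,
                 visit2_day_probs = visit2_day_probs,
                 vaccine_arm_probs = vaccine_arm_probs,
                 bf_delay_w0 = bf_delay_w0,
                 events_per_sample = as.integer(events_per_sample),
                 blood_volume_ul = blood_volume_ul,
                 beads_added = as.integer(beads_added),
                 plate_size = as.integer(plate_size),
                 events_cv = events_cv,
                 debris_frac = debris_frac, dead_frac = dead_frac,
                 doublet_frac = doublet_frac,
                 subject_cv = subject_cv,
                 panel = panel, seed = as.integer(seed)),
            class = "CohortConfig")
}

#' Population concentration trajectory over the first week
#'
#' Concentrations rise from baseline to `peak_multiplier` x baseline at
#' `peak_hour`, decline after 24 hr, and stabilize at
#' `peak_multiplier * post24h_decline_ratio` x baseline over the plateau
#' window.  Interpolation between the knots is log-linear; the 24 hr level is
#' the geometric mean of the peak and plateau levels.
#'
#' @param population Population (gating tree node) name.
#' @param baseline_cells_per_ul Concentration at birth, cells/ul.
#' @param peak_hour Hour of the peak, within `[0, 24]`.
#' @param peak_multiplier Peak level as a multiple of baseline.
#' @param post24h_decline_ratio Plateau level divided by peak level.
#' @param plateau_window Hour interval of the stable late level, within
#'   `[24, 270]`.
#' @param noise_cv Lognormal coefficient of variation of per-sample noise.
#' @return A `TrajectorySpec` list.
#' @export
trajectory_spec <- function(population, baseline_cells_per_ul,
                            peak_hour = 10, peak_multiplier = 1,
                            post24h_decline_ratio = 1,
                            plateau_window = c(60, 270), noise_cv = 0.10) {
  stopifnot(baseline_cells_per_ul >= 0, peak_hour >= 0, peak_hour <= 24,
            peak_multiplier > 0, post24h_decline_ratio > 0,
            plateau_window[1] >= 24, plateau_window[2] <= 270,
            plateau_window[1] < plateau_window[2], noise_cv >= 0)
  structure(list(population = population,
                 baseline_cells_per_ul = baseline_cells_per_ul,
                 peak_hour = peak_hour, peak_multiplier = peak_multiplier,
                 post24h_decline_ratio = post24h_decline_ratio,
                 plateau_window = plateau_window, noise_cv = noise_cv),
            class = "TrajectorySpec")
}

#' Evaluate a trajectory's multiplicative factor at given hours since birth
#' @param spec A [trajectory_spec()].
#' @param hours Hours since birth.
#' @return Multiplier(s) relative to baseline.
#' @export
trajectory_factor <- function(spec, hours) {
  peak <- spec$peak_multiplier
  plateau <- peak * spec$post24h_decline_ratio
  knots_h <- c(0, spec$peak_hour, 24, spec$plateau_window[1],
               spec$plateau_window[2])
  knots_v <- log(c(1, peak, sqrt(peak * plateau), plateau, plateau))
  # guard degenerate knot layout (peak at 0 or 24)
  keep <- !duplicated(knots_h)
  f <- stats::approx(knots_h[keep], knots_v[keep],
                     xout = pmin(pmax(hours, 0), max(knots_h)),
                     rule = 2)$y
  exp(f)
}

#' Covariate effect on a population at one visit day
#'
#' @param factor Metadata column (`"vaccine_arm"`, `"bf_bin"`, `"site"`,
#'   `"time_of_birth_bin"`).
#' @param level Factor level the effect applies to.
#' @param population Population name.
#' @param visit_day Day of life the effect applies to (0, 1, 3 or 7).
#' @param multiplier Multiplicative effect on the true concentration.
#' @return An `EffectSpec` list.
#' @export
effect_spec <- function(factor, level, population, visit_day, multiplier) {
  stopifnot(multiplier > 0, visit_day %in% c(0, 1, 3, 7))
  structure(list(factor = factor, level = level, population = population,
                 visit_day = visit_day, multiplier = multiplier),
            class = "EffectSpec")
}

#' Default population trajectories
#'
#' Granulocyte subsets carry the early-life surge: a peak near 10 hr after
#' birth, decline after 24 hr, and a stable level from 60 hr onwards at half
#' the peak (mature neutrophils).  Monocytes move mildly; the remaining
#' populations are stationary.
#'
#' @param panel `"innate"` or `"adaptive"`.
#' @return Named list of [trajectory_spec()]s, one per generated population.
#' @export
default_trajectories <- function(panel = "innate") {
  if (panel == "innate") {
    specs <- list(
      trajectory_spec("MatureNeutrophils", 600, 10, 2.5, 0.5),
      trajectory_spec("ImmatureNeutrophils1", 120, 10, 1.6, 0.65),
      trajectory_spec("ImmatureNeutrophils2", 85, 10, 2.2, 0.45),
      trajectory_spec("CD11bposCD16negGranulocytes", 105, 10, 1.5, 0.7),
      trajectory_spec("Monocytes", 165, 12, 1.3, 0.8),
      trajectory_spec("HLADRposCD14neg", 37),
      trajectory_spec("NKcells", 97),
      trajectory_spec("Lymphocytes", 360))
  } else {
    specs <- list(
      trajectory_spec("Granulocytes", 930, 10, 2.5, 0.5),
      trajectory_spec("gdTcells", 100),
      trajectory_spec("gdNegTcells", 800),
      trajectory_spec("Bcells", 330),
      trajectory_spec("OtherLymphocytes", 530))
  }
  stats::setNames(specs, vapply(specs, `[[`, "", "population"))
}

#' Default covariate effects
#'
#' Birth-vaccine effects on mature neutrophils (BCG: +22% at day 7; HBV:
#' +21% at day 1; both vaccines together: no effect) and
#' breastfeeding-initiation effects: delayed initiation raises counts over
#' the first 24 hr and blunts the day-1 rise, so the day-1/day-0 fold change
#' falls with increasing delay.
#'
#' @param panel `"innate"` or `"adaptive"`.
#' @return List of [effect_spec()]s.
#' @export
default_effects <- function(panel = "innate") {
  neut <- if (panel == "innate") "MatureNeutrophils" else "Granulocytes"
  eff <- list(
    effect_spec("vaccine_arm", "BCG", neut, 7, 1.22),
    effect_spec("vaccine_arm", "HBV", neut, 1, 1.21),
    effect_spec("bf_bin", "0-3", neut, 1, 1.35),
    effect_spec("bf_bin", "3-5", neut, 1, 0.85),
    effect_spec("bf_bin", "5-23", neut, 1, 0.55),
    effect_spec("bf_bin", "3-5", neut, 0, 1.25),
    effect_spec("bf_bin", "5-23", neut, 0, 1.25))
  if (panel == "innate") {
    # delayed initiation also touches the other granulocyte subsets,
    # monocytes, and NK-like cells over the first day
    eff <- c(eff, list(
      effect_spec("bf_bin", "0-3", "Monocytes", 1, 1.35),
      effect_spec("bf_bin", "3-5", "Monocytes", 1, 0.90),
      effect_spec("bf_bin", "5-23", "Monocytes", 1, 0.60),
      effect_spec("bf_bin", "3-5", "Monocytes", 0, 1.25),
      effect_spec("bf_bin", "5-23", "Monocytes", 0, 1.25),
      effect_spec("bf_bin", "0-3", "ImmatureNeutrophils2", 1, 1.35),
      effect_spec("bf_bin", "3-5", "ImmatureNeutrophils2", 1, 0.85),
      effect_spec("bf_bin", "5-23", "ImmatureNeutrophils2", 1, 0.55),
      effect_spec("bf_bin", "3-5", "ImmatureNeutrophils2", 0, 1.25),
      effect_spec("bf_bin", "5-23", "ImmatureNeutrophils2", 0, 1.25),
      effect_spec("bf_bin", "0-3", "CD11bposCD16negGranulocytes", 1, 1.30),
      effect_spec("bf_bin", "3-5", "CD11bposCD16negGranulocytes", 1, 0.90),
      effect_spec("bf_bin", "5-23", "CD11bposCD16negGranulocytes", 1, 0.60),
      effect_spec("bf_bin", "3-5", "CD11bposCD16negGranulocytes", 0, 1.20),
      effect_spec("bf_bin", "5-23", "CD11bposCD16negGranulocytes", 0, 1.20),
      effect_spec("bf_bin", "3-5", "NKcells", 0, 1.20),
      effect_spec("bf_bin", "5-23", "NKcells", 0, 1.20)))
  }
  eff
}

# balanced randomized allocation: counts by largest remainder, order shuffled
balanced_assign <- function(levels, probs, n) {
  base <- floor(probs * n)
  rem <- probs * n - base
  short <- n - sum(base)
  if (short > 0) {
    top <- order(rem, decreasing = TRUE)[seq_len(short)]
    base[top] <- base[top] + 1
  }
  sample(rep(levels, times = base))
}

sample_seed_for <- function(seed, i) {
  as.integer((abs(seed) %% 1000003 * 1009 + i * 7919 + 17) %% 2147483647)
}

draw_bf_delay <- function(n, w0) {
  at_birth <- stats::runif(n) < w0
  bin <- sample(1:3, n, replace = TRUE)
  lo <- c(0, 3, 5)[bin]; hi <- c(3, 5, 23)[bin]
  delay <- stats::runif(n, lo, hi)
  ifelse(at_birth, 0, delay)
}

# block randomization: both visits of a subject go on one plate; subjects
# are dealt round-robin to plates within vaccine arm so arms stay balanced
assign_plates <- function(vaccine_arm, plate_size) {
  n <- length(vaccine_arm)
  per_plate <- plate_size %/% 2L
  n_plates <- ceiling(n / per_plate)
  plate <- integer(n)
  pos <- 0L
  for (arm in unique(vaccine_arm)) {
    idx <- sample(which(vaccine_arm == arm))
    plate[idx] <- ((pos + seq_along(idx) - 1L) %% n_plates) + 1L
    pos <- pos + length(idx)
  }
  load <- table(factor(plate, levels = seq_len(n_plates)))
  if (any(load > per_plate)) stop("layout error: plate capacity exceeded")
  plate
}

#' Simulate a synthetic neonatal cohort
#'
#' Draws subject covariates, two visits per subject (day of life 0 plus one
#' of 1/3/7), per-sample true concentrations (trajectory x effects x subject
#' level x lognormal noise), and, optionally, event-level samples realized
#' from the panel's population templates with counting beads, debris, dead
#' cells and doublets mixed in.  True concentrations are recorded alongside
#' the metadata for parameter-recovery testing.
#'
#' @param config A [cohort_config()].
#' @param trajectories Named list of [trajectory_spec()]s.
#' @param effects List of [effect_spec()]s.
#' @param events If `FALSE`, only metadata and truth are generated.
#' @return A list of class `neonflow_cohort` with `samples` (list of
#'   [event_table()]s or `NULL`s), `meta` and `truth` data.tables, plus the
#'   `config` and resolved `panel`.
#' @export
simulate_cohort <- function(config = cohort_config(),
                            trajectories = default_trajectories(config$panel),
                            effects = default_effects(config$panel),
                            events = TRUE) {
  panel <- panel_config(config$panel)
  pops <- names(panel$templates)
  miss <- setdiff(pops, names(trajectories))
  if (length(miss)) stop("configuration error: no trajectory for population(s): ",
                         paste(miss, collapse = ", "))
  set.seed(config$seed)
  n <- config$n_subjects

  subj <- data.table::data.table(
    subject_id = sprintf("S%04d", seq_len(n)),
    site = sample(names(config$site_fractions), n, TRUE, config$site_fractions),
    sex = sample(c("F", "M"), n, TRUE),
    maternal_age_years = round(pmin(pmax(stats::rnorm(n, 27, 5.5), 16), 45), 1),
    season = sample(c("dry", "wet"), n, TRUE),
    # vaccine arm and follow-up day are randomization groups: allocation is
    # balanced by design, not an independent draw per subject
    vaccine_arm = balanced_assign(names(config$vaccine_arm_probs),
                                  config$vaccine_arm_probs, n),
    breastfeeding_delay_hr = round(draw_bf_delay(n, config$bf_delay_w0), 2),
    time_of_birth_hr = round(stats::runif(n, 0, 24), 2))
  subj[, visit2_day := as.integer(stats::ave(
    seq_len(n), vaccine_arm,
    FUN = function(i) balanced_assign(names(config$visit2_day_probs),
                                      config$visit2_day_probs, length(i))))]
  subj[, bf_bin := assign_breastfeeding_bin(breastfeeding_delay_hr)]
  subj[, time_of_birth_bin := time_of_birth_label(time_of_birth_hr)]
  subj[, plate := assign_plates(vaccine_arm, config$plate_size)]

  # subject-level lognormal random effect per population, shared by visits
  sdl_subj <- sqrt(log(1 + config$subject_cv^2))
  subj_mult <- matrix(stats::rlnorm(n * length(pops), -sdl_subj^2 / 2, sdl_subj),
                      n, length(pops), dimnames = list(NULL, pops))

  meta <- data.table::rbindlist(list(
    data.table::data.table(subj, visit = 1L, dol = 0L,
                           hours_since_birth = round(stats::runif(n, 0, 24), 2)),
    data.table::data.table(subj, visit = 2L, dol = subj$visit2_day,
                           hours_since_birth = round(subj$visit2_day * 24 +
                                                       stats::runif(n, 0, 12), 2))))
  meta[, sample_id := sprintf("%s_V%d", subject_id, visit)]
  data.table::setkey(meta, subject_id, visit)

  # true concentrations
  truth <- list()
  conc <- matrix(0, nrow(meta), length(pops), dimnames = list(meta$sample_id, pops))
  for (p in pops) {
    tr <- trajectories[[p]]
    sdl <- sqrt(log(1 + tr$noise_cv^2))
    base <- tr$baseline_cells_per_ul *
      trajectory_factor(tr, meta$hours_since_birth)
    mult <- subj_mult[match(meta$subject_id, subj$subject_id), p]
    noise <- stats::rlnorm(nrow(meta), -sdl^2 / 2, sdl)
    conc[, p] <- base * mult * noise
  }
  for (e in effects) {
    if (!e$factor %in% names(meta)) {
      stop("configuration error: effect factor '", e$factor,
           "' is not a metadata column")
    }
    if (!e$population %in% pops) next
    idx <- meta[[e$factor]] == e$level & meta$dol == e$visit_day
    conc[idx, e$population] <- conc[idx, e$population] * e$multiplier
  }
  truth <- data.table::data.table(
    sample_id = rep(meta$sample_id, length(pops)),
    population = rep(pops, each = nrow(meta)),
    true_cells_per_ul = as.vector(conc))

  samples <- NULL
  if (events) {
    samples <- lapply(seq_len(nrow(meta)), function(i) {
      realize_sample_events(conc[i, ], config, panel, meta$sample_id[i],
                            sample_seed_for(config$seed, i))
    })
    names(samples) <- meta$sample_id
  }
  structure(list(samples = samples, meta = meta, truth = truth,
                 conc = conc, config = config, panel = panel),
            class = "neonflow_cohort")
}

draw_template_events <- function(nm, tpl, n, panel) {
  chans <- panel$channels
  cof <- panel$transform_cofactor
  loc <- sd <- stats::setNames(numeric(length(chans)), chans)
  loc["FSC-A"] <- tpl$fsc; sd["FSC-A"] <- if (nm == "Beads") 2000 else 8000
  fsch_frac <- if (nm == "Doublets") 0.22 else 0.5
  loc["FSC-H"] <- fsch_frac * tpl$fsc; sd["FSC-H"] <- 3000
  loc["SSC-A"] <- tpl$ssc; sd["SSC-A"] <- if (nm == "Beads") 2000 else 6000
  loc["Viability"] <- tpl$viability; sd["Viability"] <- tpl$msd
  loc["Beads"] <- tpl$bead; sd["Beads"] <- 0.3
  loc[names(tpl$markers)] <- tpl$markers
  sd[names(tpl$markers)] <- tpl$msd
  m <- matrix(stats::rnorm(n * length(chans),
                           mean = rep(loc, each = n),
                           sd = rep(sd, each = n)),
              n, length(chans), dimnames = list(NULL, chans))
  transf <- !(chans %in% c("FSC-A", "FSC-H", "SSC-A", "Time"))
  m[, transf] <- sinh(m[, transf]) * cof
  scat <- c("FSC-A", "FSC-H", "SSC-A")
  m[, scat] <- pmin(pmax(m[, scat], 0), 262144)
  m
}

#' Realize the event table of one sample from its true concentrations
#'
#' Debris, dead cells and doublets occupy fixed event fractions; the
#' remaining events are a multinomial draw over cell populations and beads
#' with probabilities proportional to well composition
#' (`concentration x volume` for cells, `beads_added` for beads), so
#' counting-bead normalization is unbiased for the true concentrations.
#'
#' @param conc Named vector of true cells/ul per population.
#' @param config A [cohort_config()].
#' @param panel A [panel_config()].
#' @param sample_id Sample identifier.
#' @param seed Integer seed for this sample.
#' @return An [event_table()] on the linear scale.
#' @export
realize_sample_events <- function(conc, config, panel, sample_id, seed) {
  set.seed(seed)
  n_ev <- config$events_per_sample
  if (config$events_cv > 0) {
    sdl <- sqrt(log(1 + config$events_cv^2))
    n_ev <- max(1000L, as.integer(round(n_ev * stats::rlnorm(1, -sdl^2 / 2, sdl))))
  }
  n_debris <- round(config$debris_frac * n_ev)
  n_dead <- round(config$dead_frac * n_ev)
  n_doub <- round(config$doublet_frac * n_ev)
  q <- n_ev - n_debris - n_dead - n_doub
  pops <- names(panel$templates)
  weights <- c(conc[pops] * config$blood_volume_ul, Beads = config$beads_added)
  counts <- as.vector(stats::rmultinom(1, q, weights))
  names(counts) <- names(weights)
  specials <- special_templates(names(panel$templates[[1]]$markers))
  blocks <- list()
  for (p in pops) {
    if (counts[p] > 0) {
      blocks[[p]] <- draw_template_events(p, panel$templates[[p]], counts[p], panel)
    }
  }
  if (counts["Beads"] > 0) {
    blocks[["Beads"]] <- draw_template_events("Beads", specials$Beads,
                                              counts[["Beads"]], panel)
  }
  for (s in c("Debris", "Dead", "Doublets")) {
    ns <- c(Debris = n_debris, Dead = n_dead, Doublets = n_doub)[[s]]
    if (ns > 0) blocks[[s]] <- draw_template_events(s, specials[[s]], ns, panel)
  }
  m <- do.call(rbind, blocks)
  m <- m[sample(nrow(m)), , drop = FALSE]
  m[, "Time"] <- sort(stats::runif(nrow(m), 0, 300))
  event_table(m, panel$channels, panel$roles, sample_id)
}

#' Inject quality-control failures into generated samples
#'
#' Flags disjoint random subsets of samples as (a) low-cell: events thinned
#' to 12% of the original (well under 25% of the cohort mean), (b) dead:
#' 75% of events moved to the viability-positive population, or (c) time
#' anomaly: one contiguous 10% stretch of events shifted by +5 transformed
#' units on one marker channel.
#'
#' @param samples List of [event_table()]s (linear scale).
#' @param fraction_low_cells,fraction_dead,fraction_time_anomaly Fractions
#'   of samples to corrupt; must sum to at most 1.
#' @param seed Integer seed.
#' @param cofactor asinh cofactor of the analysis scale (for the injected
#'   shifts).
#' @return List with modified `samples` and a `truth` data.table of
#'   `(sample_id, failure)` labels.
#' @export
inject_qc_failures <- function(samples, fraction_low_cells = 0,
                               fraction_dead = 0, fraction_time_anomaly = 0,
                               seed = 1, cofactor = 150) {
  if (!length(samples)) stop("empty sample list")
  fr <- c(fraction_low_cells, fraction_dead, fraction_time_anomaly)
  if (any(fr < 0) || sum(fr) > 1) stop("failure fractions must be in [0,1] and sum <= 1")
  set.seed(seed)
  n <- length(samples)
  counts <- round(fr * n)
  pick <- sample(n, sum(counts))
  idx_low <- pick[seq_len(counts[1])]
  idx_dead <- pick[counts[1] + seq_len(counts[2])]
  idx_time <- pick[counts[1] + counts[2] + seq_len(counts[3])]
  for (i in idx_low) {
    keep <- sort(sample(n_events(samples[[i]]),
                        max(1, round(0.12 * n_events(samples[[i]])))))
    samples[[i]] <- subset_events(samples[[i]], keep)
  }
  for (i in idx_dead) {
    ne <- n_events(samples[[i]])
    hit <- sample(ne, round(0.75 * ne))
    samples[[i]]$exprs[hit, "Viability"] <-
      sinh(stats::rnorm(length(hit), 4.5, 0.35)) * cofactor
  }
  for (i in idx_time) {
    ne <- n_events(samples[[i]])
    len <- max(10, round(0.1 * ne))
    start <- sample(ne - len + 1, 1)
    ch <- channels_by_role(samples[[i]], "marker")[1]
    seg <- start:(start + len - 1)
    x <- samples[[i]]$exprs[seg, ch]
    samples[[i]]$exprs[seg, ch] <- sinh(asinh(x / cofactor) + 5) * cofactor
  }
  truth <- data.table::data.table(
    sample_id = vapply(samples, `[[`, "", "sample_id"),
    failure = "none")
  truth$failure[idx_low] <- "low_cells"
  truth$failure[idx_dead] <- "dead"
  truth$failure[idx_time] <- "time_anomaly"
  list(samples = samples, truth = truth)
}

#' Simulate the frozen internal control run on every plate
#'
#' One aliquot of a single fixed subject state is "thawed" per plate: all
#' control samples share identical true concentrations and differ only by
#' event-sampling noise, mirroring a frozen pooled control used to monitor
#' batch effects.
#'
#' @param n_plates Number of plates (>= 1).
#' @param config A [cohort_config()].
#' @param trajectories Trajectories defining the control's fixed state
#'   (evaluated at 12 hours since birth).
#' @param n_replicates Control aliquots per plate.
#' @param seed Integer seed.
#' @return List with `samples` (list of [event_table()]s) and `meta`
#'   (sample, plate, shared subject id `"internal_control"`).
#' @export
simulate_internal_control <- function(n_plates, config = cohort_config(),
                                      trajectories = default_trajectories(config$panel),
                                      n_replicates = 1, seed = 1) {
  if (n_plates < 1) stop("n_plates must be >= 1")
  panel <- panel_config(config$panel)
  pops <- names(panel$templates)
  conc <- vapply(pops, function(p) {
    tr <- trajectories[[p]]
    tr$baseline_cells_per_ul * trajectory_factor(tr, 12)
  }, 0)
  ids <- as.vector(outer(seq_len(n_replicates), seq_len(n_plates),
                         function(r, p) sprintf("IC_P%02d_R%d", p, r)))
  plates <- rep(seq_len(n_plates), each = n_replicates)
  samples <- lapply(seq_along(ids), function(i) {
    realize_sample_events(conc, config, panel, ids[i],
                          sample_seed_for(seed, 100000 + i))
  })
  names(samples) <- ids
  list(samples = samples,
       meta = data.table::data.table(sample_id = ids, plate = plates,
                                     subject_id = "internal_control"))
}

time_of_birth_label <- function(hr) {
  cut(hr, breaks = c(0, 6, 12, 18, 24), right = FALSE, include.lowest = TRUE,
      labels = c("night", "morning", "afternoon", "evening"))
}
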