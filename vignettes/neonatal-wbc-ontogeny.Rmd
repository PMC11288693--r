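---
title: "Methods: automated cytometry analysis of neonatal WBC ontogeny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated cytometry analysis of neonatal WBC ontogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its methods: the models and
procedures each stage implements, the tunable parameters and why their
defaults are what they are, what the synthetic cohort generator does and
does not emulate, and the numerical choices made where the design was
genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The analysis chain

A cohort run proceeds sample by sample: read (or generate) events →
compensate and transform → remove time-localized acquisition anomalies →
gate down a predefined tree with per-sample density thresholds → count
beads and convert to cells/µl → enumerate marker-combination phenotypes;
then cohort-wide: exclude low-quality samples, test ontogeny and covariate
contrasts, and attribute variance to clinical factors.

## Preprocessing

**Compensation.** Spillover mixing is modelled as `observed = true %*% S`
with `S` square over the marker channels, unit diagonal. `compensate()`
solves `X' S = X`; a condition number above 1e10 is refused.

**Transforms.** Markers, viability and bead channels are mapped to an
analysis scale on which stained-positive and unstained populations are
approximately Gaussian. Two strictly increasing transforms are provided:

* *logicle* — the standard biexponential scale, linear through zero over a
  width of `w` decades and logarithmic near the top of scale `T`. The
  inverse is closed-form (`S(y) = a e^{by} − c e^{−dy} + f`); the forward
  map is computed by Newton iteration seeded from a monotone spline, giving
  round-trips accurate to ~1e−14 relative. Defaults `T = 262144`,
  `m = 4.5` decades. The width can be estimated per channel from data as
  `w = (m − log10(T/|r|))/2`, `r` the 5th percentile of negative events,
  clamped to `[0, m/2]`; channels without negatives get `w = 0`.
* *asinh* with cofactor 150 — the pipeline default. The generator also
  realizes events on this scale, so either transform yields well-separated
  mixtures; asinh is cheaper and parameter-light.

Scatter and time channels are never transformed.

## Event-level QC

`clean_time_anomalies()` is a deliberately simple surrogate for full
flow-rate QC batteries: events are cut into `max(8, events/2000)`
contiguous time segments; per segment and marker channel a robust z-score
of the segment mean against the median and MAD of all segment means is
computed, and segments with max |z| > 4 are removed. One refinement
matters in practice: the MAD of eight to ten segment means occasionally
collapses by chance, inflating z-scores and removing 10% chunks of clean
data. The denominator is therefore floored at the *expected sampling SE of
a segment mean* (channel SD / sqrt(segment size)); a genuine 5-unit shift
still scores z ≈ 100 while clean samples lose essentially nothing. A
shifted stretch that straddles a segment boundary removes both touched
segments — those events are genuinely contaminated.

## Gating

`density_threshold()` mirrors automated valley gating: a Gaussian KDE
(Silverman bandwidth, 512-point grid spanning the 0.1–99.9 percentile
range), peaks = local maxima above 5% of the global maximum, threshold =
deepest valley between the two largest peaks, falling back to a configured
quantile when unimodal. Two maxima only count as *separated* peaks when the
density between them dips below 0.8× the smaller peak's height; without
this prominence requirement, kernel wiggles on the flank of a single mode
masquerade as second peaks and the valley lands inside the mode. Thresholds are re-estimated per sample on each
node's parent population — the per-sample practice of automated gating —
and cached per (parent, channel) since sibling nodes share them.

Two boundary conventions are fixed package-wide: a value strictly greater
than a threshold is "+" (half-open on the left), and polygon boundaries
count as inside (even-odd rule).

The shipped innate tree (also in `inst/extdata/innate_tree.yaml`, the
published config schema) is *representative*: beads out → size (debris
valley on FSC-A) → singlets (polygon band around FSC-H ≈ 0.5 FSC-A) →
live (viability valley; the dead peak is small, so this gate's peak floor
is lowered to 1%) → CD45+ leukocytes (fixed threshold 2 on the asinh
scale — every retained event is a leukocyte by construction, and a
data-driven split would only shave real cells) → CD66 granulocyte split →
CD11b/CD16 neutrophil quadrants, HLA-DR/CD14 monocyte quadrants, CD56/CD16
NK split. An analogous adaptive tree (CD3/γδ/CD19/CD10) ships as well.
Node counts are configuration properties, not claims about any particular
study's trees.

**Bead normalization.** `cells/µl = events × (beads_added / bead_events) /
volume_µl`. Bead events are identified on a dedicated channel. Because the
bead count enters as a per-sample ratio, its Poisson noise (~6% CV at
roughly 300 bead events) is shared by all populations of a sample — exactly
as with physical counting beads.

## Phenotype enumeration

Each measurement is a marker with `k` thresholds (`k+1` levels; level =
number of thresholds strictly below the value) or a 2D polygon filter
(inside/outside). A phenotype constrains a subset of measurements; with
`m` binary measurements there are `3^m − 1` phenotypes (each measurement
−/+/neutral, minus the all-neutral root, which is the parent population,
not a phenotype).

Counting is exact and cheap: the joint level contingency cube is tabulated
once (`O(events)`), then each dimension is extended with a marginal
"neutral" slot (a zeta transform), so every phenotype count is read off one
array of `prod(k_i + 1)` cells. A configurable cap (default 5e6 cells)
refuses enumerations that would not fit. This reproduces per-(event,
phenotype) brute force exactly — the acceptance suite checks equality on
random panels — and makes the marginalization identity (neutralizing a
measurement sums its levels' counts) hold by construction.

Low-abundance filtering drops a phenotype only when it is below the panel
minimum (20 cells/µl innate, 10 adaptive) in *every* sample; the source
text does not quantify over samples, and the any-sample reading is the more
conservative (fewer false removals). A median-based rule is available via
`rule = "median"`.

## Sample-level QC

Exclusion thresholds are the cohort mean minus three sample (n−1) standard
deviations, computed separately for size-gate event counts and live-cell
counts — data-dependent outputs, not constants. They are computed after
event cleaning and before any exclusion. Sex-mismatch checking is a pure
metadata cross-check against externally supplied calls; no sequence data is
processed. Plate stability is monitored with a frozen internal control run
on every plate and a Kruskal–Wallis test per population across plates
(pass: p > 0.05). Note that with few controls per plate the chi-square
approximation saturates — one wild plate among five with three controls
each cannot reach p ≤ 0.05 — so several aliquots per plate are needed for
a sensitive check.

## Statistics

The rank-test battery wraps the standard R implementations (exact
small-sample p-values without ties, normal approximation with tie
correction otherwise), with two documented edge policies: all-identical
data returns p = 1, and all-zero paired differences return p = 1 with a
degenerate flag. BH adjustment is applied within one contrast family — one
contrast across all populations for the day comparisons, and one vaccine
arm's day contrasts for the vaccine table (each vaccine is its own panel)
— because the alternative (global) family is not identifiable from the
source description; it is selectable. Interpretation
bands: p ≤ 0.01 "high", (0.01, 0.05] "moderate".

Cohen's d uses the pooled-SD form with the earlier group first, so a
*positive* d is a decrease over time. Fold changes are per-subject ratios
`DOL_d / DOL0`; subjects missing either visit, or with a zero denominator,
are omitted (no imputation) and logged. Breastfeeding-delay bins default to
0–3, 3–5, 5–23 hours, half-open on the left with the final bin closed (a
deterministic assignment at printed boundaries); an empirical-tertile mode
equalizes group sizes. Maternal age stratifies at 30 years; time of birth
into 6-hour windows with morning = [6, 12). For grossly unequal groups,
`balanced_subsample_test()` draws the small group's size from the large
group repeatedly (default 50 draws) and reports the p-value spread and the
fraction significant.

## Variance attribution

PVCA retains PCs up to a cumulative explained-variance threshold, estimates
per PC a one-way method-of-moments variance component per factor (clipped
at zero), averages over PCs weighted by eigenvalues, and normalizes with
the remainder as residual. Two refinements:

* **Shrinkage.** Each component is soft-thresholded at its null sampling SD
  (`MSW · sqrt(2/(k−1)) / n0`). Without it, small or unbalanced groupings —
  a 5% site group, say — draw several percent of phantom attribution under
  the null.
* **Design-factor conditioning.** In a longitudinal design, covariates can
  act in opposite directions at different ages: delayed breastfeeding
  raises counts at birth and blunts the day-1 rise, so a marginal grouping
  averages the two deviations to nearly zero. With `condition_on = "dol"`
  the day-of-life means are removed from the PC scores and the remaining
  factors are grouped by the (day × factor) interaction, so age-specific
  effects accumulate instead of cancelling. The `pvca()` default threshold
  is 0.6; the pipeline's statistics plan uses 0.9, because with only ~11
  populations the top two PCs are the overall level and the
  granulocyte-versus-rest axis, and trajectory-shape effects sit in
  mid-rank PCs. Eigenvalue weighting keeps their contribution conservative.

The hierarchy scorer ranks root→target paths through the phenotype lattice
by cumulative −log10(p) (p floored at 1e−300), exhaustively for targets of
depth ≤ 6 and by beam search beyond, and returns the k best merged as a
DAG with per-node significance bands — a pragmatic replacement for full
dynamic-programming hierarchy optimization, adequate at desk scale.

## The synthetic cohort generator

The generator exists so that every stage above is testable against known
truth. Its defaults encode the study conditions the analysis assumes:

* 200 subjects, two visits each — birth (hours uniform on [0, 24)) and one
  of day 1/3/7 (uniform; the assignment split is not documented, so uniform
  is the neutral choice), ~20,000 events/sample — a desk-scale stand-in
  for a real cohort several times larger.
* Sites 95% / 5% (a large West-African and a small Melanesian arm), vaccine
  arms BCG/HBV/both/none at 23/22/23/32%.
* Mature neutrophils rise from baseline ×1 at birth to ×2.5 at 10 h,
  decline after 24 h, and stabilize at ×1.25 (half the peak) over 60–270 h;
  log-linear interpolation between knots, with the 24-h level the geometric
  mean of peak and plateau. Immature-neutrophil and monocyte subsets move
  with smaller amplitudes; HLA-DR+CD14− cells, NK cells and lymphocytes
  are stationary controls.
* Vaccine effects: BCG ×1.22 at day 7, HBV ×1.21 at day 1, both-vaccines
  ×1.0 — generator inputs, not claims.
* Breastfeeding delay: point mass at 0 h (weight 0.87), else uniform within
  a uniformly chosen bin (0–3, 3–5, 5–23 h). Delayed initiation raises
  granulocyte/monocyte/NK counts ×1.2–1.25 over the first day and blunts
  the day-1 level (mature neutrophils ×1.35/×0.85/×0.55 by bin), so the
  day-1/day-0 fold change falls with delay; the other granulocyte subsets,
  monocytes and NK-like cells carry smaller versions of the same pattern.
* Noise: per-sample lognormal CV 0.10 per population, a per-subject
  lognormal level (CV 0.06) shared by both visits, a lognormal acquired-
  event count (CV 0.10) around the configured events per sample, plus
  multinomial event sampling and bead-ratio noise. These dispersions are deliberately modest:
  they are calibrated so that ~20% multiplicative effects are recoverable
  by rank tests at 200 subjects, which is what the generator's consumers
  (the tests) need. Real neonatal cohorts show substantially larger
  interindividual spread; recovering such effects there takes hundreds of
  subjects per arm, which is precisely why the desk-scale generator cannot
  also emulate realistic population variance. This is the generator's main
  known limitation, along with: no spillover in generated events (the
  compensation path is tested separately), no instrument drift beyond the
  injected anomalies, independent Gaussian clusters per channel (no
  correlated marker continua), and a fixed debris/dead/doublet anatomy
  (5% / 2.5% / 3%).
* Concentrations are scaled so ~10,000 spiked beads yield ~300 bead events
  per 20,000-event sample, keeping bead statistics informative; absolute
  cells/µl values are therefore lower than typical clinical neutrophil
  counts, by design.
* Plates hold 45 subjects (90 samples, both visits together), dealt
  round-robin within vaccine arm — block randomization balancing arms
  across plates — with a frozen internal control (one fixed subject state,
  sampling noise only) run on every plate.

Passing tests on this generator demonstrate that the *pipeline* recovers
programmed structure — thresholds land at valleys, exclusions flag exactly
the corrupted samples, effect signs and magnitudes survive gating and
normalization, PVCA ranks the programmed factors. They do not demonstrate
performance on real instruments' artifacts, spectral overlap, or
population-level biological variance.

## Degenerate inputs and tie-breaks

Parents with fewer than 100 events fall back to quantile thresholds
(fewer than 10: the node is flagged and its descendants zeroed, mirroring
the exclusion rule for unusually small parent populations); empty parents
flag the sample for review. Zero bead events is a normalization error, not
a zero. Ties in rank tests use midranks with tie correction. KDE grids
collapse gracefully when a channel is constant. All randomness flows from
explicit integer seeds; per-sample substreams are derived from the master
seed so streaming and batch generation agree event-for-event.

## Problem sizes used by the checks

The test suite and acceptance script run the full chain at 200 subjects ×
2 visits × ~20,000 events (one cohort plus a 10-seed gating-level sweep for
the PVCA ranking check), oracle comparisons on panels of up to 5
measurements × 1,000 events × 100 seeds, and kernel checks on exhaustive
enumerations up to n = 20. These sizes were chosen so the full suite
completes on a single CPU in well under half an hour while leaving every
qualitative recovery target overdetermined.
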