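# neonflow

Automated flow-cytometry analysis of white-blood-cell ontogeny over the
first week of human life.

## What this package is for

The days right after birth are the most dynamic period of human immune
development. Charting it by flow cytometry at cohort scale requires an
*automated* analysis chain: manual gating of thousands of samples is slow
and subjective, and rare-phenotype discovery needs every marker combination
enumerated, not just a predefined hierarchy. `neonflow` implements such a
chain end to end, for computational cytometrists and biostatisticians
working with longitudinal neonatal (or other) cohorts:

- **Event-level IO** — an FCS 3.0 subset (32-bit float, `$PnN`/`$PnS`
  keywords) and a documented CSV dialect; spillover compensation
  (`X' S = X`) and logicle (biexponential) or asinh transformation, with
  data-driven estimation of the logicle linearization width
  `w = (m − log10(T/|r|))/2` from the 5th percentile `r` of negative
  events.
- **Event QC** — time-segmented anomaly removal: per segment and marker
  channel, a robust z-score of the segment mean against the median/MAD of
  all segment means; segments with max |z| > 4 are dropped.
- **Density-based gating** — per-sample 1D valley thresholds from kernel
  density estimates (deepest valley between the two largest peaks, quantile
  fallback when unimodal), rectangle and polygon gates (even-odd rule,
  boundary inside), applied down a configurable gating tree.
- **Absolute counts** — counting-bead normalization:
  `cells/µl = events × (beads_added / bead_events) / volume`.
- **Combinatorial immunophenotypes** — every marker-combination phenotype
  (with polygon-filter membership as an extra binary dimension) counted
  exactly via a marginalized contingency cube (`3^m − 1` phenotypes for `m`
  binary measurements), then filtered at the panel's low-abundance minimum
  (20 cells/µl innate, 10 adaptive).
- **Ontogeny statistics** — Kruskal–Wallis across days of life, Wilcoxon
  rank-sum/signed-rank between days and clinical subgroups,
  Benjamini–Hochberg adjustment per contrast family, signed Cohen's d
  (`d = (mean_early − mean_late)/pooled SD`; positive = decrease over
  time), per-subject fold changes `FC = DOL_d / DOL0`, breastfeeding-delay
  bins (0–3, 3–5, 5–23 h), balanced subsampling for very unequal groups,
  and Pearson trend tests.
- **Variance attribution** — PCA summaries and principal variance component
  analysis (PVCA) with a method-of-moments estimator, plus a best-gating-
  path scorer that ranks root→phenotype paths by cumulative −log10(p).
- **A synthetic neonatal cohort generator** with recorded ground truth
  (two visits per subject, an hour-resolved neutrophil surge peaking near
  10 h and declining after 24 h, birth-vaccine and breastfeeding-delay
  effects, plates with a frozen internal control, counting beads, debris,
  dead cells, QC failures), so the entire chain is testable without any
  real data.

## Worked example

```r
library(neonflow)

cfg <- run_config(out_dir = "demo_run",
                  cohort = cohort_config(n_subjects = 50, seed = 7))
run <- run_pipeline(cfg)
print(run)
```

```
simulated cohort: 50 subjects, 100 samples
gated 100 samples (17 populations)
sample QC: excluded 0 of 100 samples (t_size=13144, t_live=12368)
internal control: 11/11 populations stable across 2 plates
phenotypes: 2186 enumerated, 627 above 20 cells/ul
statistics: 44 population x contrast rows, 21 significant
PVCA: top modelled factors dol, bf_bin
neonflow run: 100 samples, 0 excluded, 11 analysis populations
  phenotypes kept: 627 (min 20 cells/ul)
  PVCA top: residual (53.4%)
  elapsed: 25.1 s
```

Reading the output: 50 subjects were sampled twice (birth plus day 1, 3 or
7), each sample realized as ~20,000 events, cleaned, gated down the innate
tree and bead-normalized. No sample fell below the mean − 3 SD exclusion
thresholds on the size-gate or live-cell counts. All 3^7 − 1 = 2,186
marker-combination phenotypes were enumerated per sample and 627 exceeded
20 cells/µl somewhere in the cohort. The day-of-life contrast dominates the
significant rows (the programmed neutrophil surge and decline), and PVCA
ranks day of life first and the breastfeeding-delay bin second among the
modelled clinical factors:

```r
run$comparisons[population == "MatureNeutrophils" & contrast == "DOL1_vs_DOL3"]
#>           population     contrast              test     p_value cohens_d ...
#> 1: MatureNeutrophils DOL1_vs_DOL3 wilcoxon_rank_sum 1.76e-09        3.37
```

A positive Cohen's d means counts *decreased* from day 1 to day 3 — the
programmed halving of mature neutrophils after the first day.

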