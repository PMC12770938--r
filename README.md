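# mdmscreen

Methylated DNA marker (MDM) panels and chromosome-arm aneuploidy
scoring for esophageal neoplasia screening.

Barrett's esophagus is surveyed by endoscopy because some patients
progress to high-grade dysplasia (HGD) and esophageal adenocarcinoma
(EAC). A molecular test on non-endoscopic specimens (esophageal
brushings or swallowed sponge capsules) could triage that surveillance.
`mdmscreen` implements the two readouts such a test combines and the
statistics around them:

* **MDM discovery and filtering** — per-region overdispersed binomial
  logistic regression (Pearson dispersion φ̂ floored at 1 inflates the
  Wald SE by √φ̂), Mann–Whitney AUC with ties counted ½, fold change
  %M<sub>case</sub>/%M<sub>control</sub> with a floored denominator, a
  filter cascade (AUC ≥ 0.60, FC ≥ 3, control background < 5%),
  read-level epiallele concordance filtering (reads ≥ 80% methylated
  vs ≤ 20%), 500-base cross-platform locus matching, and ranked panel
  supplementation.
* **Validation marker reduction** — control-sample R² of methylated
  vs total reads (least squares, or a penalized regression spline for
  CpG-dense regions), retention of the top 20% with ties kept, and
  per-region strand resolution.
* **Aneuploidy score (AS)** — pooled-control reference fractions,
  per-bin log2 ratios from 1-Mb shallow WGS counts, optional GC-decile
  normalization, a three-state Gaussian HMM (Viterbi) keeping events
  ≥ 5 Mb, segment-length weighted-median arm copy numbers, gain/loss
  calls at CN ≥ 2.5 / ≤ 1.5, AS = Σ|call| ∈ [0, 44], and six
  recurrent-alteration flags (1q+, 9p−, 12p+, 17p−, 20q+, 8q24+).
* **Classification and evaluation** — stratified cross-validated
  random forests (MDM with/without AS), sensitivity at fixed
  specificity, DeLong AUC variance/CI and stratum comparison,
  exhaustive 4-marker logistic models with Harrell bootstrap optimism
  correction, rule-out thresholds at 90% sensitivity, and screening
  NPV/PPV projection.
* **Synthetic cohorts** — a generator with planted marker and
  arm-event truth (paired brush/sponge samples, epiallele mixing,
  sponge dilution, grade-dependent aneuploidy) so the full pipeline is
  testable without patient data.

## Worked example

```r
library(mdmscreen)

cfg <- sim_config(seed = 4,
                  n_per_cohort = c(NE = 6, NDBE = 12, LGD = 4,
                                   HGD = 8, EAC = 10),
                  n_regions = 60, n_true_markers = 8,
                  genome = toy_genome(), platforms = "brush")
cohort <- generate_cohort(cfg)
cohort
#> Synthetic cohort: 40 samples, 60 regions ( 8 planted markers ), 102 planted arm events
#>       platform
#> cohort brush
#>   EAC     10
#>   HGD      8
#>   LGD      4
#>   NDBE    12
#>   NE       6

metrics <- marker_metrics(cohort$methylation, cohort$samples)
filter_cascade(metrics)
#> Panel selection: 16 records retained
#>   stage counts: input=120 -> auc=24 -> fc=16 -> noise=16

score_aneuploidy(cohort$bin_counts, cohort$samples, cfg$genome)
#> Aneuploidy scores for 40 samples
#>                                  EAC                                  HGD
#> "n=10, median AS=1.0, any-event=80%"  "n=8, median AS=0.0, any-event=38%"
#>                                  LGD                                 NDBE
#>   "n=4, median AS=0.0, any-event=0%"  "n=12, median AS=0.0, any-event=0%"
#>                                   NE
#>   "n=6, median AS=0.0, any-event=0%"

pr <- screening_projection(sens = 0.90, spec = 0.56,
                           prevalence = 0.05, n = 10000)
pr$confusion
#>          case control
#> test_pos  450    4180
#> test_neg   50    5320
pr$npv_pct
#> [1] 99
```

The full pipeline (simulate → discover → filter → aneuploidy →
classify → evaluate) runs from a single config; every stage writes its
outputs plus a checksum manifest, and identical seeds reproduce
identical artifacts:

```r
cfg <- pipeline_config(list(dir = tempfile(), seed = 1))
run_pipeline(cfg)
```

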