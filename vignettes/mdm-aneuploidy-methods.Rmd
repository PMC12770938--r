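---
title: "Methods: methylated DNA marker panels and arm-level aneuploidy scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methylated DNA marker panels and arm-level aneuploidy scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdmscreen)
```

## Scientific problem

Barrett's esophagus (BE) is surveyed by endoscopy because a minority of
patients progress through low- and high-grade dysplasia (LGD, HGD) to
esophageal adenocarcinoma (EAC). A molecular test on non-endoscopic
specimens (esophageal brushings or swallowed sponge capsules) could
triage surveillance: patients negative at a high-sensitivity cutoff
might safely defer endoscopy. `mdmscreen` implements the two molecular
readouts such a test combines and the statistics used to discover,
reduce and evaluate them:

1. **Methylated DNA markers (MDMs)** — genomic regions whose
   methylation distinguishes HGD/EAC from nondysplastic BE (NDBE), read
   out as region-level beta values
   $\beta = \text{methylated reads} / \text{total reads}$.
2. **Arm-level aneuploidy score (AS)** — the number of chromosome arms
   gained or lost, estimated from shallow whole-genome sequencing
   binned at 1 Mb. On the 44 human autosomal arms, $AS \in [0, 44]$.

Because real cohorts are access-restricted, the package ships a
synthetic cohort generator with planted truth, so every stage can be
exercised and audited end to end.

## Marker discovery

### Differential methylation with overdispersion

For each region and strand, `fit_overdispersed_logistic()` regresses
the per-sample methylated/unmethylated read counts on case status with
a binomial logistic model. Sequencing of patient specimens is
overdispersed relative to the binomial, so the Wald standard error is
inflated by the square root of the Pearson dispersion
$\hat\phi = \chi^2_{\text{Pearson}} / (n - 2)$, floored at 1 so that
under-dispersion never shrinks an error bar. Complete separation is
flagged rather than fatal.

### Ranking and the filter cascade

Each candidate is summarized by:

* the Mann–Whitney **AUC** of its beta values (ties count 1/2), an
  effect-size measure insensitive to scale;
* the **fold change** FC = %M~case~ / %M~control~, with the control
  denominator floored at 0.1 %M so background-free markers remain
  finite;
* the **control background**, the mean control beta.

`filter_cascade()` applies, in order, AUC ≥ 0.60, FC ≥ 3, and control
background < 0.05. The surviving set is order-invariant and the count
after each stage is reported.

### Read-level epiallele concordance

A usable marker should present as fully methylated molecules in cases
over an unmethylated background, not as diffuse partial methylation.
Per read, the fraction of covered CpGs that are methylated classifies
the read as concordantly methylated (≥ 0.8) or concordantly
unmethylated (≤ 0.2). `read_level_filter()` keeps a marker when the
mean concordant-methylated fraction across case samples is ≥ 0.05 and
across control samples ≤ 0.05.

### Cross-platform matching and panel supplementation

Markers discovered on different assays are reconciled by
`match_cross_platform()`: loci on the same chromosome within a 500-base
gap are paired (half-open intervals; nearest partner; ties to the
smaller start). When fewer markers survive than the target panel size
(default 200), `supplement_panel()` appends the best remaining
candidates ranked by AUC, then FC.

## Validation marker reduction

On control (NDBE) samples, a well-behaved marker's methylated read
count should track its total read depth tightly; markers with erratic
control behaviour are noise-prone. `control_r2()` fits methylated reads
against total reads on controls — ordinary least squares for short
regions, and a penalized regression spline (via `mgcv::gam`, GCV
smoothness selection) for regions with ≥ 30 CpGs, where saturation
bends the relationship — and reports $R^2$. `percentile_filter()`
retains the top 20% of markers by control $R^2$ (ties at the cutoff
are kept), and `resolve_strands()` keeps the better strand per region.

## Aneuploidy scoring

`score_aneuploidy()` chains:

1. **Pooled reference** — each NDBE sample's bin counts are normalized
   to its total; the reference fraction per bin is their mean.
2. **Log2 ratios** — $\log_2$ of the sample's normalized bin fraction
   over the reference fraction; optional GC-decile median
   normalization removes smooth coverage waves first.
3. **Segmentation** — a three-state (loss/neutral/gain) Gaussian HMM
   decoded by Viterbi per chromosome, with fixed means at one-copy
   log2 ratios (−0.58, 0, +0.58), a shared robust emission SD
   (`mad(diff)/√2`, floored at 0.05) and sticky transitions.
   Non-neutral segments shorter than 5 Mb are reassigned to neutral:
   the score counts large-scale events only.
4. **Arm calls** — each arm takes the segment-length weighted median
   (lower-median rule) of segment copy numbers
   $CN = 2 \cdot 2^{\overline{\log_2 R}}$; gain if $CN \ge 2.5$, loss
   if $CN \le 1.5$ (boundaries inclusive).
5. **Score and flags** — $AS = \sum_{\text{arms}} |\text{call}|$, plus
   six recurrent-alteration flags (1q, 12p, 20q gains; 9p, 17p losses;
   gain overlapping the 8q24 window).

Two physical facts shape the tests: a *uniform* change across the whole
genome is invisible to fraction normalization (only relative imbalance
is observable), and a single-copy event diluted to tumor fraction $t$
presents at $CN = 2 \pm t$, so it crosses the ±0.5 call boundary only
at $t \ge 0.5$ — diluted specimens legitimately score lower.

## Classification and evaluation

* `cv_random_forest()` — stratified k-fold cross-validation of a
  500-tree random forest on the marker matrix, with or without AS as an
  extra feature; pooled out-of-fold scores give the AUC, its DeLong
  95% CI and sensitivity at fixed specificity.
* `sensitivity_at_specificity()` — smallest cutoff (score ≥ cutoff
  positive) whose control specificity reaches the target (default 80%).
* `delong_variance()` / `delong_compare_strata()` — DeLong structural
  components give the AUC variance; independent strata are compared by
  a two-sided z-test with added variances.
* `enumerate_4mdm()` — exhaustive logistic models over all
  ${n \choose 4}$ marker quadruples (20,475 for a 28-marker panel),
  optionally with AS as a fifth covariate; a weak ridge penalty
  stabilizes separated fits.
* `optimism_correct()` — Harrell's bootstrap: refit on each resample,
  score on resample and on the original data, and subtract the mean
  difference (the optimism) from the apparent metric.
* `rule_out_threshold()` — largest cutoff retaining ≥ 90% case
  sensitivity, with the control specificity there and optional
  application to held-out scores.
* `screening_projection()` — rounded confusion matrix, NPV and PPV on
  a hypothetical screening population. At sensitivity 90%, specificity
  56%, prevalence 5% and $n = 10{,}000$: 5,320 true negatives, 50
  false negatives, NPV 99%.

## The synthetic cohort generator

`sim_config()`/`generate_cohort()` produce paired brush/sponge samples
per patient across five cohorts (NE, NDBE, LGD, HGD, EAC) with planted
truth. The defaults are the generator's study conditions; the notable
choices and their rationale:

* **Background methylation** ~ Beta with mean 0.01: discovery-grade
  MDMs are chosen for near-zero control background, so the null regions
  emulate that regime. The region-level mean is shared across strands
  (hemimethylation co-occurs) with a mild log-normal strand jitter.
* **Case signal as epiallele mixing** — a case sample's reads at a
  planted marker are a mixture: a fraction (mean 0.3, Beta-distributed
  across patients) of fully methylated molecules over background. This
  mirrors how neoplastic DNA presents in a specimen and is what the
  read-level filter keys on. Per-marker case positivity is drawn from
  U(0.55, 0.9) — real markers fire in most but not all cases — and LGD
  signal is attenuated (×0.6) as an intermediate grade.
* **Sponge dilution** U(2, 10) — swallowed-capsule specimens collect
  material from the whole esophagus, diluting both the epiallele
  fraction and the copy-number tumor fraction relative to a targeted
  brushing.
* **Read depth** NB(mean 25, size 5) per region/strand: shallow,
  overdispersed coverage, matching the dispersion floor in the
  discovery model.
* **Arm events** — per-cohort probability of any event (0 / 0.28 /
  0.5 / 0.78 / 0.94 for NE/NDBE/LGD/HGD/EAC) with Poisson-distributed
  extra arms increasing by grade, copy numbers in {1, 3}, recurrent
  arms 3× more likely, and bin counts scaled by
  $1 + t\,(CN - 2)/2$ at tumor fraction $t$. `count_noise = "none"`
  yields exact expectations for oracle tests; the default adds
  negative-binomial noise.

The generator does **not** emulate assay chemistry (bisulfite
conversion error, mapping bias), inter-region correlation beyond the
shared strand background, or focal (sub-arm) copy-number events other
than through the 8q24 window of whole-arm events.

## Worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(list(dir = tempfile(), seed = 1))
run_pipeline(cfg)
jsonlite::read_json(file.path(cfg$dir, "evaluation.json"))
```

Each stage writes its outputs plus a manifest (input/output checksums,
seed, configuration), so identical configurations reproduce identical
artifacts byte for byte.

## Limitations

* Synthetic cohorts are deliberately easier to separate than patient
  data; cross-validated AUCs near 1 on generated data say the
  machinery works, not that any assay would achieve them.
* The HMM uses fixed one-copy emission means; subclonal events between
  the call boundaries are intentionally not called.
* DeLong stratum comparison assumes independent strata; it does not
  apply to paired designs.
* NPV/PPV projections inherit the rounding of the inputs and assume
  transportability of sensitivity and specificity to the screening
  population.
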