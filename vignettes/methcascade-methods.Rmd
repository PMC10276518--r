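---
title: "Methods: models, defaults, and design decisions in methcascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, defaults, and design decisions in methcascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methcascade)
```

# Scope

`methcascade` implements the computational backbone of a staged cfDNA
methylation assay development program: quantification of region-level
methylation, a two-stage marker funnel, two differently tuned panel
classifiers joined in a sequential cascade, and a diagnostic-accuracy
layer. This vignette records the statistical models, every tunable that
matters, and the choices made where the design was genuinely open. It is
the companion to the README's worked example; nothing here claims an
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

# The quantification model

The unit of signal is the **average methylation fraction** (AMF) of a
genomic region in a sample: total methylated CpG observations divided by
total detected CpG observations. AMF is undefined (NA) when nothing was
detected; it is never imputed at quantification time.

**Coverage rule.** A common depth floor for region-level bisulfite panels
is 100×. "At least 100× coverage" underdetermines the aggregation across
samples, so the package makes a two-part rule: a *region* is retained if
its **median** detected-CpG count across samples reaches `min_coverage`
(default 100), and an individual *cell* inside a retained region is set
to NA if its own count is below the threshold. The median keeps a region
with a few failed libraries; the per-cell mask keeps those failures from
contributing unreliable AMFs. The filter is idempotent, which the suite
verifies.

**qPCR.** For PCR readouts the relative signal is the standard
reference-gene transform `2^(ct_reference − ct_marker)`; reactions
censored at cycle 40 (the conventional detection limit) report signal 0,
and a missing or censored reference reaction fails QC for the record
rather than silently producing a value. The transform is one documented
convention among several; it enters only through
`qpcr_relative_signal()`, so swapping it is local.

# The synthetic cohort generator

The generator exists so that every downstream stage can be tested under a
known truth. It emulates the statistical structure the analysis assumes,
not raw sequencing:

- **Counts.** Detected CpGs per cell are Poisson with mean
  `coverage_mean` (default 200). Methylated CpGs are **beta-binomial**
  with intra-class correlation `healthy_beta_dispersion` (default 0.1):
  overdispersion is the norm in bisulfite data, and a plain binomial
  would make every test unrealistically easy.
- **Signal.** Each cancer plasma sample carries a latent tumor fraction
  `f_i ~ Uniform(tumor_fraction_range)`; at an informative region the
  latent level is the dilution mixture
  `(1 − f_i)·b_r + f_i·tumor_beta_mean`, where `b_r` is the region's
  healthy background. This is the standard ctDNA framing: plasma signal
  is tumor signal diluted into a healthy background. Benign samples
  receive the same effect scaled by `benign_effect_scale` (default 0.25)
  — benign inflammation genuinely elevates some markers, which is what
  makes the diagnostic contrast hard and the two-model design necessary.
  Tumor tissue sits at `tumor_beta_mean` (default 0.6), white blood
  cells at the background.
- **Backgrounds.** Region backgrounds are Beta-distributed around
  `healthy_beta_mean` (default 0.02) with a tight spread (concentration
  300), because the regions model a *pre-designed* hypermethylation
  panel already screened to be quiet in healthy plasma; wide background
  variation would describe an unscreened panel, which is out of scope.
- **Defaults as study conditions.** The default group sizes (190/135/188
  cancer/benign/healthy plasma, 20 tumor + 20 WBC tissue, 165 regions
  with 15 informative) mirror a realistic model-building phase of a
  staged case-control design; `simulate_study()` adds discovery
  (209/97/123), plasma verification (88/81), and independent validation
  (64/45/63) phases sharing one region panel. Default tumor fractions of
  1–20% make desk-scale runs informative; a stress preset at 0.1–1% is
  one argument away (`tumor_fraction_range = c(0.001, 0.01)`) but is not
  the default because at realistic sequencing depth it mostly measures
  the coverage model, not the pipeline.
- **Clinical covariates.** TNM stages follow a multinomial weighted to
  early disease (42.5% stage I), tumor diameters are log-normal with
  median 2 cm, and serum CEA is log-normal per group with parameters
  calibrated so its standalone AUC sits just under 0.6 — a deliberately
  weak, partially independent covariate, which is the interesting regime
  for the combination analysis.

What the generator does **not** emulate: read-level bisulfite error,
batch and center effects, fragment-length biology, correlated regions,
age/sex/smoking confounding of methylation, and assay dropout beyond
coverage. Green tests therefore demonstrate that the pipeline's logic and
statistics behave as designed under the assumed model; they do not
certify performance on real plasma.

**Randomness.** One RNG stream per cohort, seeded explicitly from the
config; `simulate_study()` and `run_pipeline()` derive phase- and
stage-specific seeds by fixed offsets from the single global seed. The
suite checks that identical configs give byte-identical cohorts and
reports. Per-sample sub-streams were considered and dropped: nothing in
the package consumes partial cohorts, so the extra machinery bought
nothing.

# The marker funnel

Stage 1 (discovery, plasma cancer vs healthy) keeps regions satisfying
all of: BH-adjusted two-sided Mann–Whitney `q ≤ 0.05`, fold change of
group mean AMFs `> 1`, and healthy background `≤ 0.05` AMF; survivors are
ranked by single-region AUC, then fold change, and the top 50 are kept.
Choices worth recording:

- **Test.** Mann–Whitney with tie correction (normal approximation), the
  same rank test used for score comparisons later; AMF distributions are
  bounded and skewed, so a t-test would be the wrong default.
- **Multiplicity.** Benjamini–Hochberg across regions at discovery, where
  a hundred-plus regions are tested; the verification stage uses raw
  `p < 0.05` because only a curated handful of candidates reach it.
- **Fold change** uses a pseudocount of 1e-4 on both means, so a
  zero-background region yields a large finite ratio instead of
  infinity.
- **Ranking key.** "Separation power plus fold change" is made concrete
  as the lexicographic key (AUC desc, fold change desc, region id) — AUC
  first because it is the quantity the next stage optimizes; the region
  id makes ties deterministic.
- **Degenerate regions** (all values identical) are defined as AUC 0.5,
  `p = 1`, flagged, and thereby excluded — not errors.
- **Curation.** The manual 50→15 narrowing by gene annotation and primer
  designability is judgment, not computation; it is represented as an
  explicit user-supplied allowlist intersected before the verification
  rules.

Stage 2 (verification) is the conjunction `log2 FC(plasma) > 1` and
`p < 0.05` and `log10 FC(tumor vs WBC) > 1`. Conjunctions are
order-independent and idempotent, which the suite tests.

# The classifier

A ridge-penalized logistic model on standardized marker AMFs, penalty 1.0
on the sum-log-likelihood scale. The ridge matters: panels are small but
cohorts are too, and near-separable training sets otherwise drive
coefficients to infinity. The solver is a dozen lines of Newton
iterations, cross-checked in the suite against `glm()` as the penalty
vanishes.

**Forward selection.** The anchor is the marker with the highest
single-marker CV AUC; each addition is evaluated by repeated stratified
k-fold CV (default 10 × 4) in which repetition *r* draws its folds from
`seed + r` — so every candidate subset is scored on *identical folds*,
and greedy-vs-exhaustive comparisons are apples to apples. The full
greedy path is walked and the returned subset is the **global argmax**
over path sizes (not a first-decline stop), with ties broken toward the
smaller subset and then panel order. On 6-marker panels the suite checks
the greedy optimum lands within 0.02 AUC of the exhaustive best over all
63 subsets.

**Leakage discipline.** Imputation medians and standardization moments
are computed inside training folds only; a permutation-label run is part
of the suite and must keep CV AUC in [0.4, 0.6]. Missing AMFs are imputed
by training(-fold) medians — never across the train/validation boundary.

**Two scores, never mixed.** Each training sample has (a) its
repeat-averaged out-of-fold score, used for cutoff calibration and
training operating points, and (b) its final-refit deployment score, used
for new data. The model object keeps both, labelled.

**Cutoffs.** Screen mode: the largest cutoff whose training sensitivity
reaches `target` (default 0.90) — the most specific cutoff that still
meets the sensitivity floor. Diagnostic mode: the smallest cutoff whose
training specificity against the benign contrast reaches `target`
(default 0.95). The floors are configurable; the defaults express the
screening/diagnostic asymmetry the two modes exist for. Candidate
cutoffs are the observed score values plus a boundary just above the
maximum, so a full-specificity cutoff always exists; an unattainable
floor yields the boundary cutoff with a warning rather than an error.

**Training contrasts.** The screen model trains cancer vs healthy and
treats benign as a held-out test group; the diagnostic model trains
cancer vs benign and treats healthy as held out. Each model is calibrated
against the contrast that defines its clinical job.

# Evaluation

AUC is the tie-corrected rank statistic (probability a random positive
outscores a random negative, ties half); the suite pins it to brute-force
pair enumeration on all fixtures up to n = 50 and to an independent ROC
implementation. Confidence intervals are percentile intervals from 1000
class-stratified bootstrap resamples, seeded; stratification keeps both
classes present in every resample. Displayed percentages are rounded
half-up to one decimal, the usual table convention (base `round()` would
round half to even).

The cascade is a conjunction — final positive iff screen-positive *and*
diagnostic-positive — so its true and false positives can never exceed
the screen stage's; the suite asserts these inequalities on every run.
Prevalence adjustment is Bayes' rule on (sensitivity, specificity,
prevalence); at the sample prevalence it reproduces the raw predictive
values exactly (a consistency identity in the suite). One subtlety is
recorded rather than resolved: a published summary of this kind of
cascade can print prevalence-adjusted values computed from the
diagnostic stage's operating point rather than the combined cascade
point; the function takes whichever operating point the caller supplies,
and the acceptance script documents its inputs explicitly.

CEA enters the combination model as `log10(CEA + 1)` (tumor-marker
distributions are right-skewed); the combined model is a bivariate
logistic fit, and a constant CEA column falls back to the score alone
with a warning instead of a singular fit.

# Problem sizes in the test suite

The suite favors many small seeded batteries over few large ones: null
calibration uses 1000 regions at 50 + 50 samples; recovery and S/D
asymmetry use 20-seed batteries at 40–100 samples per group and 12–50
regions; greedy-vs-exhaustive uses a 6-marker panel at 60 + 60 samples
with the full 10 × 4 CV; the end-to-end pipeline tests run a scaled
study (50/40/50 training) while the acceptance script runs the full
default design (190/135/188 training, 64/45/63 validation). These sizes
are the package's chosen desk-scale study conditions; the generator makes
larger runs a config change, not a code change.

# Known limitations

- The generator's independence assumptions (regions independent, noise
  exchangeable) understate real-world correlation; panel-level AUCs on
  synthetic data are optimistic relative to patient cohorts.
- The forward-selection procedure inherits greedy selection's usual
  caveat: it is compared against the exhaustive optimum only at small
  panel sizes, where the comparison is computable.
- Calibration of predicted probabilities is out of scope; scores are
  used only through cutoffs, so only their ranking and the calibrated
  operating points are meaningful.
- The qPCR model covers relative quantification against a single
  reference gene; multi-reference normalization and efficiency
  correction per amplicon are not modelled.
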