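# methcascade

Development and evaluation toolkit for **region-level cfDNA methylation
classifiers** in cancer early detection, built as a classic R modelling
package around one fitting function, `panel_classifier()`.

## The problem

Tumors shed DNA into plasma, but circulating tumor DNA (ctDNA) is a tiny
fraction of cell-free DNA — often well below 1% — so single-locus assays
are noisy and screening tests must squeeze signal out of a small panel of
differentially methylated regions (DMRs). A practical blood test is
developed in stages: quantify region-level methylation from bisulfite
counts or qPCR, funnel a designed panel of candidate DMRs down to the few
markers that are elevated in cancer plasma and quiet in healthy plasma and
white blood cells, train a compact classifier, and report honest
diagnostic accuracy for the intended clinical use. Crucially, *two*
differently tuned models serve two different uses: a **screening** model
that must not miss cancers (sensitivity-first) and a **diagnostic** model
that must not mislabel benign disease (specificity-first), applied
sequentially as a cascade.

`methcascade` implements that whole development pipeline, plus a
beta-binomial synthetic cohort generator so every stage is testable end to
end without patient data.

## The model

Per region *r* and sample *i*, the signal is the average methylation
fraction, AMF = methylated CpG observations / detected CpG observations
(regions below 100× median coverage are dropped; low-coverage cells are
masked). Marker selection is a two-stage funnel:

1. **Discovery** (plasma): keep regions with BH-adjusted Mann–Whitney
   *q* ≤ 0.05, fold change (cancer mean / healthy mean) > 1, and healthy
   background AMF ≤ 0.05; rank by single-region AUC then fold change; keep
   the top 50.
2. **Verification** (tissue + plasma): keep markers with
   log₂FC(cancer vs healthy plasma) > 1, *p* < 0.05, and
   log₁₀FC(tumor vs WBC) > 1, after an optional curated allowlist.

The classifier is a ridge-penalized logistic model
σ(β₀ + Σⱼ βⱼ xⱼ) on standardized marker AMFs, built by **anchor-based
greedy forward selection**: the marker with the highest single-marker
cross-validated AUC anchors the model, each further addition is evaluated
by 10 × 4-fold stratified cross-validation on identical folds, and the
final subset is the global AUC argmax along the greedy path. The decision
cutoff is calibrated on repeat-averaged out-of-fold scores — largest
cutoff reaching 90% sensitivity (screen mode) or smallest cutoff reaching
95% specificity (diagnostic mode). The cascade calls a sample positive iff
**both** models do; screen-negatives are never re-tested.

The evaluation layer provides tie-corrected rank AUC with 1000-rep
stratified bootstrap CIs, sensitivity/specificity/PPV/NPV,
prevalence-adjusted predictive values (Bayes' rule), Mann–Whitney
covariate association, and combination of the diagnostic score with serum
CEA. `required_sample_size(P, d, confidence)` gives the classic
n = ⌈z²·P(1−P)/d²⌉ design size.

## Worked example

```r
library(methcascade)
cfg <- read_pipeline_config(system.file("extdata", "demo_config.yaml",
                                        package = "methcascade"))
report <- run_pipeline(cfg)
report
```

```
pipeline_report (seed 4)
  verified panel: 5 markers
  screen model: 5 markers, CV AUC 0.910; validation AUC 0.922
  diagnostic model: 4 markers, CV AUC 0.852; validation AUC 0.837
  cascade: sensitivity 53.1%, specificity 90.7%
  at 10% prevalence: PPV 38.9%, NPV 94.6%
```

The demo study plants 6 informative DMRs among 40 regions; the funnel
recovers 5, the screen model separates cancer from healthy plasma in the
held-out validation cohort with AUC 0.92, the diagnostic model separates
cancer from benign disease with AUC 0.84, and the sequential cascade
trades sensitivity (53.1%) for high combined specificity (90.7%).
`summary(report$s_model)` prints the forward-selection path:

```
  forward-selection path (mean CV AUC by size):
     1  +region_033   0.859
     2  +region_004   0.885
     3  +region_012   0.900
     4  +region_032   0.910
     5  +region_014   0.910  <- selected
  training (out-of-fold) sensitivity 90.0%, specificity 78.0%
```

Individual stages are ordinary functions — `marker_stats()`,
`select_discovery_markers()`, `verify_markers()`, `panel_classifier()`,
`cascade_classify()`, `performance_report()` — and work the same on real
count tables read with `read_counts()` / `read_sample_sheet()` /
`read_bed()`.

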