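# Shared fixture builders; everything is generated in code at test time.

# meth_matrix whose AMF values are exactly `frac` (detected fixed).
counts_from_amf <- function(frac, detected = 100) {
  frac <- as.matrix(frac)
  if (is.null(rownames(frac))) {
    rownames(frac) <- sprintf("s%02d", seq_len(nrow(frac)))
  }
  if (is.null(colnames(frac))) {
    colnames(frac) <- sprintf("r%02d", seq_len(ncol(frac)))
  }
  d <- matrix(detected, nrow(frac), ncol(frac), dimnames = dimnames(frac))
  meth_matrix(round(frac * d), d)
}

sheet_for <- function(counts, groups) {
  data.frame(sample = rownames(counts$methylated), group = groups,
             stringsAsFactors = FALSE)
}

# Small two-group plasma cohort with planted DMRs, for selection/training
# tests. Defaults keep the signal strong and the run fast.
small_cohort <- function(seed, n_cancer = 50, n_healthy = 50, n_benign = 0,
                         n_regions = 20, n_true_dmr = 4,
                         tumor_fraction_range = c(0.1, 0.2),
                         coverage_mean = 150, ...) {
  simulate_cohort(cohort_config(
    n_cancer = n_cancer, n_benign = n_benign, n_healthy = n_healthy,
    n_tumor_tissue = 0, n_wbc = 0, n_regions = n_regions,
    n_true_dmr = n_true_dmr, tumor_fraction_range = tumor_fraction_range,
    coverage_mean = coverage_mean, seed = seed, ...))
}

# Brute-force AUC: enumerate every case-control pair, ties worth half.
brute_auc <- function(scores, pos) {
  sp <- scores[pos]
  sn <- scores[!pos]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}
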