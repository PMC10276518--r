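# Diagnostic-accuracy layer: AUC, confusion metrics, bootstrap CIs,
# the two-model cascade, prevalence-adjusted predictive values.

as_positive <- function(labels, positive = NULL) {
  if (is.logical(labels)) return(labels)
  if (is.null(positive)) {
    stop("'positive' must name the positive class for non-logical labels",
         call. = FALSE)
  }
  as.character(labels) == positive
}

#' Rank-based AUC with tie correction
#'
#' Probability that a randomly chosen positive outscores a randomly chosen
#' negative, ties counted half — the Mann-Whitney U statistic scaled to
#' \[0, 1\]. Computed from midranks, so ties are handled exactly.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels logical vector (TRUE = positive), or a factor/character
#'   vector with `positive` naming the positive class.
#' @param positive positive class label for non-logical `labels`.
#' @return AUC in \[0, 1\].
#' @examples
#' rank_auc(c(0.9, 0.4, 0.6, 0.5), c(TRUE, TRUE, FALSE, FALSE))  # 0.5
#' @export
rank_auc <- function(scores, labels, positive = NULL) {
  pos <- as_positive(labels, positive)
  ok <- !is.na(scores) & !is.na(pos)
  scores <- scores[ok]
  pos <- pos[ok]
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present to compute an AUC", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified (within-class) bootstrap indices.
boot_index <- function(pos) {
  ip <- which(pos)
  im <- which(!pos)
  c(sample(ip, length(ip), replace = TRUE),
    sample(im, length(im), replace = TRUE))
}

#' AUC with a bootstrap confidence interval
#'
#' Percentile interval from `n_boot` class-stratified bootstrap resamples
#' (default 1000), seeded for reproducibility.
#'
#' @inheritParams rank_auc
#' @param n_boot bootstrap resamples (default 1000).
#' @param conf confidence level (default 0.95).
#' @param seed RNG seed for resampling.
#' @return list with `auc`, `ci_low`, `ci_high`, `n_boot`.
#' @export
auc_ci <- function(scores, labels, positive = NULL, n_boot = 1000,
                   conf = 0.95, seed = 1L) {
  pos <- as_positive(labels, positive)
  ok <- !is.na(scores) & !is.na(pos)
  scores <- scores[ok]
  pos <- pos[ok]
  point <- rank_auc(scores, pos)
  reps <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    idx <- boot_index(pos)
    rank_auc(scores[idx], pos[idx])
  }, numeric(1)))
  qs <- stats::quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE, type = 7)
  list(auc = point, ci_low = qs[1], ci_high = qs[2], n_boot = n_boot)
}

#' Confusion counts from calls and truth
#'
#' @param truth logical (TRUE = diseased) or labels plus `positive`.
#' @param call logical test result (TRUE = positive call).
#' @param positive positive class label for non-logical `truth`.
#' @return named integer vector `c(tp, fp, tn, fn)`.
#' @export
confusion_counts <- function(truth, call, positive = NULL) {
  pos <- as_positive(truth, positive)
  stopifnot(is.logical(call), length(call) == length(pos))
  c(tp = sum(pos & call), fp = sum(!pos & call),
    tn = sum(!pos & !call), fn = sum(pos & !call))
}

#' Sensitivity, specificity, PPV and NPV from confusion counts
#'
#' Exact ratios: sensitivity = TP/(TP+FN), specificity = TN/(TN+FP),
#' PPV = TP/(TP+FP), NPV = TN/(TN+FN). A metric whose denominator is zero
#' is NA with the reason recorded in the `"undefined"` attribute rather
#' than an error.
#'
#' @param tp,fp,tn,fn non-negative integer counts, or a named vector from
#'   [confusion_counts()] as the first argument.
#' @return list with `sensitivity`, `specificity`, `ppv`, `npv`.
#' @examples
#' m <- confusion_metrics(tp = 32, fp = 6, tn = 102, fn = 32)
#' as_percent(m$ppv)   # 84.2
#' as_percent(m$npv)   # 76.1
#' @export
confusion_metrics <- function(tp, fp = NULL, tn = NULL, fn = NULL) {
  if (length(tp) == 4 && !is.null(names(tp))) {
    fp <- tp[["fp"]]; tn <- tp[["tn"]]; fn <- tp[["fn"]]; tp <- tp[["tp"]]
  }
  for (v in c(tp, fp, tn, fn)) check_count(v, "confusion count")
  safe <- function(num, den, what) {
    if (den == 0) {
      structure(NA_real_, undefined = sprintf("%s undefined: empty denominator", what))
    } else num / den
  }
  list(
    sensitivity = safe(tp, tp + fn, "sensitivity"),
    specificity = safe(tn, tn + fp, "specificity"),
    ppv = safe(tp, tp + fp, "PPV"),
    npv = safe(tn, tn + fn, "NPV")
  )
}

#' Full diagnostic performance report at a cutoff
#'
#' Applies `score >= cutoff` as the positive call, then reports confusion
#' counts, sensitivity/specificity/PPV/NPV, and AUC, each with a
#' class-stratified percentile bootstrap confidence interval
#' (1000 resamples by default).
#'
#' @inheritParams rank_auc
#' @param cutoff decision threshold on the score.
#' @param n_boot bootstrap resamples (default 1000).
#' @param conf confidence level (default 0.95).
#' @param seed RNG seed.
#' @return object of class `performance_report`: list with `counts`,
#'   `metrics` (point estimates), `ci` (per-metric low/high), `auc`,
#'   `cutoff`, `n`, `n_boot`.
#' @export
performance_report <- function(scores, labels, cutoff, positive = NULL,
                               n_boot = 1000, conf = 0.95, seed = 1L) {
  pos <- as_positive(labels, positive)
  ok <- !is.na(scores) & !is.na(pos)
  scores <- scores[ok]
  pos <- pos[ok]
  call <- scores >= cutoff
  counts <- confusion_counts(pos, call)
  metrics <- confusion_metrics(counts)

  one_rep <- function(idx) {
    cm <- confusion_metrics(confusion_counts(pos[idx], call[idx]))
    c(sensitivity = cm$sensitivity[[1]], specificity = cm$specificity[[1]],
      ppv = cm$ppv[[1]], npv = cm$npv[[1]],
      auc = rank_auc(scores[idx], pos[idx]))
  }
  reps <- with_seed(seed, vapply(seq_len(n_boot),
                                 function(b) one_rep(boot_index(pos)),
                                 numeric(5)))
  probs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  ci <- apply(reps, 1, stats::quantile, probs = probs, na.rm = TRUE,
              names = FALSE, type = 7)
  ci <- as.data.frame(t(ci))
  names(ci) <- c("low", "high")

  structure(list(
    counts = counts,
    metrics = metrics,
    auc = rank_auc(scores, pos),
    ci = ci,
    cutoff = cutoff,
    n = length(pos),
    n_boot = n_boot,
    conf = conf
  ), class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("performance_report (n = %d, cutoff = %.3f)\n", x$n, x$cutoff))
  cat(sprintf("  counts: tp=%d fp=%d tn=%d fn=%d\n",
              x$counts["tp"], x$counts["fp"], x$counts["tn"], x$counts["fn"]))
  rows <- c("sensitivity", "specificity", "ppv", "npv", "auc")
  vals <- c(unlist(x$metrics, use.names = FALSE), x$auc)
  for (i in seq_along(rows)) {
    if (is.na(vals[i])) {
      cat(sprintf("  %-11s NA\n", rows[i]))
    } else {
      cat(sprintf("  %-11s %5.1f%%  (%.1f-%.1f%%, %d-rep bootstrap)\n",
                  rows[i], 100 * vals[i],
                  100 * x$ci$low[i], 100 * x$ci$high[i], x$n_boot))
    }
  }
  invisible(x)
}

#' Prevalence-adjusted predictive values
#'
#' Bayes' rule for PPV/NPV at an intended-use prevalence that differs from
#' the study's case-control mix:
#' \deqn{PPV = \frac{se \cdot \pi}{se \cdot \pi + (1-sp)(1-\pi)}, \quad
#'       NPV = \frac{sp (1-\pi)}{sp (1-\pi) + (1-se)\pi}}
#'
#' @param sensitivity,specificity test operating point, in \[0, 1\].
#' @param prevalence disease prevalence of the target population.
#' @return list with `ppv` and `npv`; a value whose denominator is zero is
#'   NA with an `"undefined"` attribute.
#' @examples
#' # a triage test at 51.6% sensitivity / 93.3% specificity, 10% prevalence
#' p <- prevalence_adjust(0.516, 0.933, 0.10)
#' as_percent(p$ppv)  # 46.1
#' as_percent(p$npv)  # 94.6
#' @export
prevalence_adjust <- function(sensitivity, specificity, prevalence) {
  check_fraction(sensitivity, "sensitivity")
  check_fraction(specificity, "specificity")
  check_fraction(prevalence, "prevalence")
  num_p <- sensitivity * prevalence
  den_p <- num_p + (1 - specificity) * (1 - prevalence)
  num_n <- specificity * (1 - prevalence)
  den_n <- num_n + (1 - sensitivity) * prevalence
  ppv <- if (den_p == 0) {
    structure(NA_real_, undefined = "PPV undefined: no positive calls expected")
  } else num_p / den_p
  npv <- if (den_n == 0) {
    structure(NA_real_, undefined = "NPV undefined: no negative calls expected")
  } else num_n / den_n
  list(ppv = ppv, npv = npv)
}

#' Compare model scores across covariate groups
#'
#' Two-sided tie-corrected Mann-Whitney tests of the score distribution
#' between every pair of covariate levels, Benjamini-Hochberg adjusted when
#' there is more than one comparison. Levels with fewer than 2 scored
#' samples are skipped with a warning.
#'
#' @param scores numeric model scores.
#' @param groups covariate labels, same length as `scores`.
#' @return data.frame with `group1`, `group2`, `n1`, `n2`, `p_value`,
#'   `q_value`.
#' @export
covariate_association <- function(scores, groups) {
  stopifnot(length(scores) == length(groups))
  ok <- !is.na(scores) & !is.na(groups)
  scores <- scores[ok]
  groups <- as.character(groups[ok])
  tab <- table(groups)
  small <- names(tab)[tab < 2]
  if (length(small)) {
    warning("skipping group(s) with < 2 samples: ",
            paste(small, collapse = ", "), call. = FALSE)
  }
  lev <- names(tab)[tab >= 2]
  if (length(lev) < 2) {
    stop("need at least 2 covariate groups with >= 2 samples each",
         call. = FALSE)
  }
  pairs <- utils::combn(lev, 2)
  out <- data.frame(
    group1 = pairs[1, ], group2 = pairs[2, ],
    n1 = as.integer(tab[pairs[1, ]]), n2 = as.integer(tab[pairs[2, ]]),
    p_value = apply(pairs, 2, function(pr) {
      stats::wilcox.test(scores[groups == pr[1]], scores[groups == pr[2]],
                         exact = FALSE)$p.value
    }),
    stringsAsFactors = FALSE
  )
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Combine a model score with serum CEA
#'
#' Fits a bivariate logistic model on the diagnostic score and
#' log10(CEA + 1) (tumour-marker distributions are right-skewed), and
#' reports the in-sample AUC of CEA alone, the score alone, and the
#' combination. Pairs with missing CEA are dropped pairwise-complete with
#' the retained count reported; a constant CEA column falls back to the
#' score alone with a warning.
#'
#' @param scores diagnostic model scores.
#' @param cea CEA values (ng/mL), NA allowed.
#' @param labels class labels; see [rank_auc()].
#' @param positive positive class for non-logical labels.
#' @return list with `auc_cea`, `auc_score`, `auc_combined`, `model`
#'   (the fitted `glm`, or NULL on fallback), `n_used`.
#' @export
combine_with_cea <- function(scores, cea, labels, positive = NULL) {
  pos <- as_positive(labels, positive)
  ok <- !is.na(scores) & !is.na(cea) & !is.na(pos)
  n_used <- sum(ok)
  scores <- scores[ok]
  cea <- cea[ok]
  pos <- pos[ok]
  log_cea <- log10(cea + 1)
  auc_score <- rank_auc(scores, pos)
  if (length(unique(log_cea)) < 2) {
    warning("CEA is constant; falling back to the score alone",
            call. = FALSE)
    return(list(auc_cea = NA_real_, auc_score = auc_score,
                auc_combined = auc_score, model = NULL, n_used = n_used))
  }
  fit <- stats::glm(pos ~ scores + log_cea, family = stats::binomial())
  combined <- stats::fitted(fit)
  list(
    auc_cea = rank_auc(log_cea, pos),
    auc_score = auc_score,
    auc_combined = rank_auc(combined, pos),
    model = fit,
    n_used = n_used
  )
}
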