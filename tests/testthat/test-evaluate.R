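test_that("confusion metrics are exact ratios with missing-with-reason", {
  m <- confusion_metrics(tp = 32, fp = 6, tn = 102, fn = 32)
  expect_equal(m$ppv, 32 / 38)
  expect_equal(m$npv, 102 / 134)
  expect_equal(as_percent(m$ppv), 84.2)
  expect_equal(as_percent(m$npv), 76.1)
  expect_equal(confusion_metrics(tp = 58, fp = 0, tn = 0, fn = 6)$sensitivity,
               58 / 64)
  all_right <- confusion_metrics(tp = 10, fp = 0, tn = 10, fn = 0)
  expect_equal(unlist(all_right, use.names = FALSE), rep(1, 4))
  # no negatives at all: NPV undefined, with the reason attached
  und <- confusion_metrics(tp = 5, fp = 5, tn = 0, fn = 0)
  expect_true(is.na(und$npv))
  expect_match(attr(und$npv, "undefined"), "NPV")
  # counts vector from calls round-trips
  cc <- confusion_counts(c(TRUE, TRUE, FALSE, FALSE),
                         c(TRUE, FALSE, TRUE, FALSE))
  expect_identical(cc, c(tp = 1L, fp = 1L, tn = 1L, fn = 1L))
})

test_that("rank AUC equals brute-force pair enumeration, ties included", {
  expect_equal(rank_auc(c(0.9, 0.4, 0.6, 0.5),
                        c(TRUE, TRUE, FALSE, FALSE)), 0.5)
  expect_equal(rank_auc(c(1, 1, 0, 0), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(rank_auc(rep(0.3, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  set.seed(101)
  for (i in 1:25) {
    n <- sample(4:50, 1)
    pos <- rep(FALSE, n)
    pos[sample(n, sample(2:(n - 2), 1))] <- TRUE
    # coarse grid forces plenty of ties
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    expect_equal(rank_auc(s, pos), brute_auc(s, pos))
  }
  expect_error(rank_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("bootstrap CI brackets the point estimate and tightens with n", {
  set.seed(5)
  mk <- function(n) {
    pos <- rep(c(TRUE, FALSE), each = n / 2)
    list(s = rnorm(n, ifelse(pos, 1, 0)), pos = pos)
  }
  small <- mk(60)
  r1 <- auc_ci(small$s, small$pos, n_boot = 500, seed = 3)
  expect_gte(r1$auc, r1$ci_low)
  expect_lte(r1$auc, r1$ci_high)
  big <- mk(240)
  r2 <- auc_ci(big$s, big$pos, n_boot = 500, seed = 3)
  expect_lt(r2$ci_high - r2$ci_low, r1$ci_high - r1$ci_low)
  # seeded: identical reruns
  expect_identical(r1, auc_ci(small$s, small$pos, n_boot = 500, seed = 3))
})

test_that("performance report is consistent with its own confusion counts", {
  set.seed(8)
  pos <- rep(c(TRUE, FALSE), c(40, 60))
  s <- plogis(rnorm(100, ifelse(pos, 1.5, -1)))
  rep1 <- performance_report(s, pos, cutoff = 0.5, n_boot = 300, seed = 2)
  cc <- rep1$counts
  expect_equal(rep1$metrics$sensitivity, cc["tp"] / (cc["tp"] + cc["fn"]),
               ignore_attr = TRUE)
  expect_true(all(rep1$ci$low <= rep1$ci$high))
  # prevalence consistency identity: adjusting at the sample prevalence
  # reproduces the raw predictive values
  prev <- mean(pos)
  adj <- prevalence_adjust(rep1$metrics$sensitivity[[1]],
                           rep1$metrics$specificity[[1]], prev)
  expect_equal(adj$ppv[[1]], rep1$metrics$ppv[[1]], tolerance = 1e-12)
  expect_equal(adj$npv[[1]], rep1$metrics$npv[[1]], tolerance = 1e-12)
})

test_that("prevalence adjustment matches a brute-force expected population", {
  adj <- prevalence_adjust(0.516, 0.933, 0.10)
  # oracle: expected confusion counts in a 1e6-subject population
  N <- 1e6
  tp <- 0.516 * 0.1 * N; fn <- (1 - 0.516) * 0.1 * N
  tn <- 0.933 * 0.9 * N; fp <- (1 - 0.933) * 0.9 * N
  expect_equal(adj$ppv[[1]], tp / (tp + fp))
  expect_equal(adj$npv[[1]], tn / (tn + fn))
  expect_equal(as_percent(adj$ppv[[1]]), 46.1)
  expect_equal(as_percent(adj$npv[[1]]), 94.6)
  # algebraic identities
  p1 <- prevalence_adjust(1, 1, 0.3)
  expect_equal(c(p1$ppv, p1$npv), c(1, 1))
  p2 <- prevalence_adjust(0.5, 0.5, 0.17)
  expect_equal(p2$ppv[[1]], 0.17)  # uninformative test: PPV = prevalence
})

test_that("the cascade is a conjunction: screen-negatives stay negative", {
  co <- small_cohort(seed = 71, n_benign = 30)
  markers <- co$regions$region[co$regions$informative]
  cvc <- cv_config(n_repeats = 3, seed = 6)
  s_m <- panel_classifier(co$counts, co$samples, markers, mode = "screen",
                          cv = cvc)
  d_m <- panel_classifier(co$counts, co$samples, markers,
                          mode = "diagnostic", cv = cvc)
  cas <- cascade_classify(s_m, d_m, co$counts, co$samples)
  calls <- cas$calls
  expect_true(all(!calls$final_call[!calls$s_call]))
  expect_true(all(is.na(calls$d_call[!calls$s_call])))
  expect_true(all(calls$final_call == (calls$s_call & !is.na(calls$d_call) &
                                         calls$d_call)))
  # conjunction inequalities against the screen-only rule
  truth <- co$samples$group[match(calls$sample, co$samples$sample)] == "cancer"
  cc_s <- confusion_counts(truth, calls$s_call)
  cc_f <- confusion_counts(truth, calls$final_call)
  expect_lte(cc_f["tp"], cc_s["tp"])
  expect_lte(cc_f["fp"], cc_s["fp"])
  m_s <- confusion_metrics(cc_s)
  m_f <- confusion_metrics(cc_f)
  expect_gte(m_f$specificity, m_s$specificity)
  expect_lte(m_f$sensitivity, m_s$sensitivity)
  # audit table accounts for every sample
  expect_equal(sum(cas$audit$n), nrow(calls))
  expect_equal(sum(cas$audit$final_positive), sum(calls$final_call))
})

test_that("covariate association is calibrated under the null and detects shifts", {
  # null: p-values uniform over seeds (KS)
  set.seed(44)
  pnull <- replicate(200, {
    covariate_association(rnorm(30), rep(c("a", "b"), 15))$p_value
  })
  expect_gt(suppressWarnings(ks.test(pnull, "punif"))$p.value, 0.01)
  # clean shift: tiny p
  p <- covariate_association(c(1:10, 101:110) / 200,
                             rep(c("lo", "hi"), each = 10))
  expect_lt(p$p_value, 0.001)
  # three groups -> three BH-adjusted pairwise tests
  g3 <- covariate_association(rnorm(30), rep(c("I", "II", "III"), 10))
  expect_identical(nrow(g3), 3L)
  expect_true(all(g3$q_value >= g3$p_value - 1e-12))
  # agreement with the exact permutation distribution at tiny n
  x <- c(0.1, 0.4, 0.22, 0.31, 0.9, 0.55, 0.61, 0.48)
  g <- rep(c("a", "b"), each = 4)
  ours <- covariate_association(x, g)$p_value
  ranks <- rank(x)
  obs <- sum(ranks[g == "a"])
  perms <- combn(8, 4, function(i) sum(ranks[i]))
  exact_p <- mean(abs(perms - mean(perms)) >= abs(obs - mean(perms)))
  expect_lt(abs(ours - exact_p), 0.05)
  # undersized groups are skipped with a warning
  expect_warning(covariate_association(rnorm(5), c("a", "a", "b", "b", "c")),
                 "skipping")
})

test_that("CEA combination adds what the covariate carries", {
  # CEA duplicating the label drives the combined AUC to 1
  set.seed(12)
  pos <- rep(c(TRUE, FALSE), each = 40)
  d <- plogis(rnorm(80, ifelse(pos, 1, -1)))
  dup <- ifelse(pos, 50, 1) + rnorm(80, 0, 0.01)
  res <- combine_with_cea(d, dup, pos)
  expect_gt(res$auc_combined, 0.99)
  # constant CEA falls back to the score alone
  expect_warning(fb <- combine_with_cea(d, rep(2, 80), pos), "constant")
  expect_equal(fb$auc_combined, fb$auc_score)
  # missing CEA handled pairwise-complete with the count reported
  cea_na <- dup; cea_na[1:5] <- NA
  expect_equal(combine_with_cea(d, cea_na, pos)$n_used, 75)
})

test_that("the default CEA preset is a weak but real standalone signal", {
  cfg <- cohort_config()
  set.seed(90)
  n <- 20000
  cea_c <- rlnorm(n, cfg$cea_params$cancer[1], cfg$cea_params$cancer[2])
  cea_h <- rlnorm(n, cfg$cea_params$healthy[1], cfg$cea_params$healthy[2])
  a <- rank_auc(c(cea_c, cea_h), rep(c(TRUE, FALSE), each = n))
  expect_gt(a, 0.54)
  expect_lt(a, 0.62)
})

test_that("weak independent CEA usually improves the in-sample combined AUC", {
  cfg <- cohort_config()
  wins <- vapply(1:20, function(s) {
    set.seed(7000 + s)
    pos <- rep(c(TRUE, FALSE), each = 60)
    d <- plogis(rnorm(120, ifelse(pos, 1.2, -0.2)))
    cea <- ifelse(pos,
                  rlnorm(120, cfg$cea_params$cancer[1],
                         cfg$cea_params$cancer[2]),
                  rlnorm(120, cfg$cea_params$healthy[1],
                         cfg$cea_params$healthy[2]))
    res <- combine_with_cea(d, cea, pos)
    res$auc_combined > res$auc_score
  }, logical(1))
  expect_gte(sum(wins), 16)
})

test_that("percent rounding is half-up at one decimal", {
  expect_equal(round_half_up(94.55, 1), 94.6)
  expect_equal(round_half_up(94.54, 1), 94.5)
  expect_equal(round_half_up(-1.25, 1), -1.3)
  expect_equal(as_percent(58 / 64), 90.6)
})

test_that("rank AUC agrees with an independent ROC implementation", {
  set.seed(55)
  pos <- rep(c(TRUE, FALSE), c(30, 45))
  s <- round(rnorm(75, ifelse(pos, 0.8, 0)), 1)  # ties included
  ours <- rank_auc(s, pos)
  theirs <- as.numeric(pROC::auc(pROC::roc(pos, s, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs)
})
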