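test_that("ridge logistic matches glm as the penalty vanishes", {
  set.seed(42)
  n <- 200
  X <- cbind(a = rnorm(n), b = rnorm(n))
  y <- runif(n) < plogis(0.5 + 0.8 * X[, 1] - 0.4 * X[, 2])
  Xs <- scale(X)
  fit <- methcascade:::ridge_logistic(Xs, y, lambda = 1e-8)
  ref <- glm(y ~ Xs, family = binomial())
  expect_equal(fit$intercept, unname(coef(ref)[1]), tolerance = 1e-5)
  expect_equal(unname(fit$coef), unname(coef(ref)[-1]), tolerance = 1e-5)
  # with separation the penalty keeps coefficients finite
  ysep <- X[, 1] > 0
  fit_sep <- methcascade:::ridge_logistic(Xs, ysep, lambda = 1)
  expect_true(all(is.finite(fit_sep$coef)))
  expect_lt(max(abs(fit_sep$coef)), 20)
})

test_that("cross-validated AUC hits the extremes and stays null-calibrated", {
  set.seed(7)
  n <- 80
  y <- rep(c(TRUE, FALSE), each = n / 2)
  X <- cbind(perfect = ifelse(y, 1, 0) + runif(n, 0, 0.01),
             noise1 = rnorm(n), noise2 = rnorm(n))
  rownames(X) <- sprintf("s%02d", 1:n)
  cvc <- cv_config(n_repeats = 5, seed = 3)
  expect_equal(cv_auc(X, y, "perfect", cv = cvc)$mean_auc, 1.0)
  # permuted labels: the leakage detector stays near chance
  for (s in 1:3) {
    yp <- sample(y)  # fresh permutation per repeat
    res <- cv_auc(X[, c("noise1", "noise2")], yp, cv = cvc)
    expect_gte(res$mean_auc, 0.4)
    expect_lte(res$mean_auc, 0.6)
  }
})

test_that("informative markers beat noise markers under CV across seeds", {
  wins <- vapply(1:20, function(s) {
    co <- small_cohort(seed = 800 + s, n_cancer = 40, n_healthy = 40,
                       n_regions = 12, n_true_dmr = 3, coverage_mean = 100)
    a <- amf(co$counts)
    y <- co$samples$group == "cancer"
    cvc <- cv_config(n_repeats = 3, seed = s)
    inf <- co$regions$region[co$regions$informative]
    noise <- setdiff(co$regions$region, inf)[1:3]
    cv_auc(a, y, inf, cv = cvc)$mean_auc >
      cv_auc(a, y, noise, cv = cvc)$mean_auc
  }, logical(1))
  expect_identical(sum(wins), 20L)
})

test_that("forward selection honors anchors, tie-breaks and the global argmax", {
  set.seed(15)
  n <- 120
  y <- rep(c(TRUE, FALSE), each = n / 2)
  X <- cbind(perfect = as.numeric(y) + runif(n, 0, 0.01),
             matrix(rnorm(n * 9), n, dimnames = list(NULL, paste0("n", 1:9))))
  rownames(X) <- sprintf("s%03d", 1:n)
  cvc <- cv_config(n_repeats = 5, seed = 2)
  sel <- forward_select(X, y, colnames(X), cv = cvc)
  # a perfect marker plus pure noise: smaller subset wins the tie
  expect_identical(sel$markers, "perfect")
  expect_equal(sel$cv_auc, 1.0)
  # panel of one: that marker is the model
  sel1 <- forward_select(X, y, "n1", cv = cvc)
  expect_identical(sel1$markers, "n1")
  expect_identical(nrow(sel1$path), 1L)
})

test_that("complementary markers are jointly selected when neither suffices", {
  set.seed(33)
  n <- 160
  u <- rnorm(n); v <- rnorm(n)
  y <- (u + v) > 0                      # each marker is half the signal
  X <- cbind(half1 = u, half2 = v,
             noise = rnorm(n))
  rownames(X) <- sprintf("s%03d", 1:n)
  cvc <- cv_config(n_repeats = 5, seed = 4)
  sel <- forward_select(X, y, colnames(X), cv = cvc)
  expect_true(all(c("half1", "half2") %in% sel$markers))
  both <- cv_auc(X, y, c("half1", "half2"), cv = cvc)$mean_auc
  singles <- c(cv_auc(X, y, "half1", cv = cvc)$mean_auc,
               cv_auc(X, y, "half2", cv = cvc)$mean_auc)
  expect_gt(both, max(singles))
})

test_that("fold construction is stratified, exact, and fails loudly otherwise", {
  y <- rep(c(TRUE, FALSE), c(12, 20))
  fold <- methcascade:::make_fold_ids(y, 4, TRUE, seed = 1)
  expect_identical(sort(unique(fold)), 1:4)
  for (k in 1:4) expect_identical(sum(fold == k & y), 3L)
  expect_error(methcascade:::make_fold_ids(rep(c(TRUE, FALSE), c(2, 30)),
                                           4, TRUE, seed = 1),
               "stratified")
})

test_that("cutoff calibration meets its floors on both modes", {
  scores <- c(0.9, 0.85, 0.8, 0.7, 0.3, 0.2, 0.15, 0.1)
  y <- scores > 0.5
  # perfect separation: the largest valid cutoff is the lowest case score
  cut_s <- calibrate_cutoff(scores, y, "screen", target = 1.0)
  expect_equal(cut_s, 0.7)
  expect_equal(mean(scores[y] >= cut_s), 1.0)
  # diagnostic: smallest cutoff with full specificity sits just above controls
  cut_d <- calibrate_cutoff(scores, y, "diagnostic", target = 1.0)
  expect_equal(mean(scores[!y] < cut_d), 1.0)
  expect_lte(cut_d, 0.7)
  expect_gt(cut_d, 0.3)
  # a seeded cohort calibrated at 0.90 lands in [0.90, 1] by construction
  co <- small_cohort(seed = 61)
  fit <- panel_classifier(co$counts, co$samples,
                          co$regions$region[co$regions$informative],
                          mode = "screen", cv = cv_config(n_repeats = 3,
                                                          seed = 8))
  y_tr <- fit$training_labels
  sens <- mean(fit$cv_scores[y_tr] >= fit$cutoff)
  expect_gte(sens, 0.90)
  expect_lte(sens, 1.0)
})

test_that("deployment scoring is the stored affine-logistic map", {
  co <- small_cohort(seed = 62, n_cancer = 30, n_healthy = 30,
                     n_regions = 8, n_true_dmr = 3)
  fit <- panel_classifier(co$counts, co$samples,
                          region_ids(co$counts)[1:6],
                          cv = cv_config(n_repeats = 3, seed = 5))
  # all features at the training means -> plogis(intercept)
  at_mean <- matrix(fit$center, 1, dimnames = list("x", fit$markers))
  expect_equal(unname(predict(fit, at_mean)),
               plogis(fit$intercept))
  # monotonicity in a positively weighted marker
  j <- names(which.max(fit$coefficients))
  up <- at_mean; up[, j] <- up[, j] + 0.1
  if (fit$coefficients[j] > 0) {
    expect_gt(predict(fit, up), predict(fit, at_mean))
  }
  # absent marker is a hard error naming the marker
  expect_error(predict(fit, at_mean[, -1, drop = FALSE]), fit$markers[1])
  # score_samples is deployment scoring
  expect_identical(score_samples(fit, co$counts),
                   predict(fit, co$counts, type = "response"))
  expect_true(all(score_samples(fit, co$counts) >= 0 &
                    score_samples(fit, co$counts) <= 1))
})

test_that("fits are reproducible under a fixed CV seed", {
  co <- small_cohort(seed = 63, n_cancer = 40, n_healthy = 40,
                     n_regions = 10, n_true_dmr = 3)
  cvc <- cv_config(n_repeats = 3, seed = 9)
  f1 <- panel_classifier(co$counts, co$samples, region_ids(co$counts)[1:5],
                         cv = cvc)
  f2 <- panel_classifier(co$counts, co$samples, region_ids(co$counts)[1:5],
                         cv = cvc)
  expect_identical(f1$markers, f2$markers)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-12)
  expect_identical(f1$cutoff, f2$cutoff)
})

test_that("screen and diagnostic tunings produce the intended asymmetry", {
  res <- vapply(1:20, function(s) {
    cfg <- cohort_config(n_cancer = 60, n_benign = 45, n_healthy = 60,
                         n_tumor_tissue = 0, n_wbc = 0, n_regions = 12,
                         n_true_dmr = 5, tumor_fraction_range = c(0.03, 0.2),
                         seed = 3000 + s)
    tr <- simulate_cohort(cfg, seed = cfg$seed)
    va <- simulate_cohort(cfg, regions = tr$regions, seed = cfg$seed + 1L,
                          id_prefix = "v_")
    markers <- tr$regions$region[tr$regions$informative]
    cvc <- cv_config(n_repeats = 5, seed = s)
    s_m <- panel_classifier(tr$counts, tr$samples, markers, mode = "screen",
                            cv = cvc)
    d_m <- panel_classifier(tr$counts, tr$samples, markers,
                            mode = "diagnostic", cv = cvc)
    grp <- va$samples$group
    s_call <- predict(s_m, va$counts, type = "class")
    d_call <- predict(d_m, va$counts, type = "class")
    sens <- function(call) mean(call[grp == "cancer"])
    ben_spec <- function(call) mean(!call[grp == "benign"])
    c(sens(s_call) >= sens(d_call), ben_spec(d_call) >= ben_spec(s_call))
  }, logical(2))
  expect_gte(sum(res[1, ]), 18)
  expect_gte(sum(res[2, ]), 18)
})
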