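#' Repeated cross-validation configuration
#'
#' @param n_repeats number of CV repetitions (default 10).
#' @param n_folds folds per repetition (default 4).
#' @param stratified stratify fold assignment by class (default TRUE).
#' @param seed base RNG seed; repetition `r` draws its folds from
#'   `seed + r`, so the fold layout is identical for every candidate
#'   marker subset evaluated under the same config.
#' @return list of class `cv_config`.
#' @export
cv_config <- function(n_repeats = 10, n_folds = 4, stratified = TRUE,
                      seed = 1L) {
  structure(list(
    n_repeats = check_count(n_repeats, "n_repeats", min = 1L),
    n_folds = check_count(n_folds, "n_folds", min = 2L),
    stratified = isTRUE(stratified),
    seed = check_count(seed, "seed")
  ), class = "cv_config")
}

# Fold ids 1..n_folds for each sample; stratified keeps class balance.
make_fold_ids <- function(y, n_folds, stratified, seed) {
  n <- length(y)
  fold <- integer(n)
  with_seed(seed, {
    if (stratified) {
      for (cls in unique(y)) {
        idx <- which(y == cls)
        if (length(idx) < n_folds) {
          stop(sprintf(
            "class with %d samples cannot be stratified into %d folds",
            length(idx), n_folds), call. = FALSE)
        }
        fold[idx] <- rep_len(seq_len(n_folds), length(idx))[sample.int(length(idx))]
      }
    } else {
      fold <- rep_len(seq_len(n_folds), n)[sample.int(n)]
      for (k in seq_len(n_folds)) {
        if (length(unique(y[fold == k])) < 2) {
          stop("non-stratified fold lacks both classes; use stratified CV",
               call. = FALSE)
        }
      }
    }
  })
  fold
}

impute_cols <- function(X, medians) {
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (any(miss)) X[miss, j] <- medians[j]
  }
  X
}

# Ridge-penalized logistic regression by Newton iterations.
# Minimizes  -loglik(beta) + lambda/2 * ||coef||^2  (intercept unpenalized)
# on already-standardized features; the penalty keeps small-n fits stable
# and bounded under perfect separation.
ridge_logistic <- function(X, y, lambda = 1, maxit = 100, tol = 1e-9) {
  X1 <- cbind(`(Intercept)` = 1, X)
  p <- ncol(X1)
  pen <- diag(c(0, rep(lambda, p - 1)), p, p)
  beta <- numeric(p)
  for (it in seq_len(maxit)) {
    eta <- drop(X1 %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(X1, y - mu)) - drop(pen %*% beta)
    H <- crossprod(X1 * w, X1) + pen
    delta <- solve(H, grad)
    beta <- beta + delta
    if (max(abs(delta)) < tol) break
  }
  list(intercept = unname(beta[1]), coef = unname(beta[-1]))
}

# Precompute, per repeat x fold, the imputed+standardized train/test blocks
# (per-column operations, so every candidate subset reuses them). All
# imputation medians and standardization moments come from the training
# fold only -- nothing crosses the fold boundary.
prep_cv <- function(X, y, cv) {
  lapply(seq_len(cv$n_repeats), function(r) {
    fold <- make_fold_ids(y, cv$n_folds, cv$stratified, cv$seed + r)
    lapply(seq_len(cv$n_folds), function(k) {
      tr <- fold != k
      Xtr <- X[tr, , drop = FALSE]
      med <- apply(Xtr, 2, stats::median, na.rm = TRUE)
      med[is.na(med)] <- 0
      Xtr <- impute_cols(Xtr, med)
      Xte <- impute_cols(X[!tr, , drop = FALSE], med)
      ctr <- colMeans(Xtr)
      sc <- apply(Xtr, 2, stats::sd)
      sc[!is.finite(sc) | sc == 0] <- 1
      list(test = which(!tr),
           Xtr = scale(Xtr, ctr, sc),
           ytr = y[tr],
           Xte = scale(Xte, ctr, sc))
    })
  })
}

# Out-of-fold score matrix (samples x repeats) for one marker subset.
oof_scores <- function(prep, n, cols, lambda) {
  vapply(prep, function(rep_folds) {
    s <- numeric(n)
    for (f in rep_folds) {
      fit <- ridge_logistic(f$Xtr[, cols, drop = FALSE], f$ytr, lambda)
      eta <- fit$intercept +
        drop(f$Xte[, cols, drop = FALSE] %*% fit$coef)
      s[f$test] <- stats::plogis(eta)
    }
    s
  }, numeric(n))
}

subset_cv_auc <- function(prep, y, cols, lambda) {
  sc <- oof_scores(prep, length(y), cols, lambda)
  per_repeat <- apply(sc, 2, rank_auc, labels = y)
  list(mean_auc = mean(per_repeat), per_repeat = per_repeat,
       oof_mean = rowMeans(sc))
}

#' Cross-validated AUC of a marker subset
#'
#' Mean out-of-fold AUC over repeated stratified k-fold cross-validation
#' (10 x 4-fold by default) of a ridge-logistic model on the given
#' markers. Each repetition re-randomizes the fold assignment from its own
#' derived seed; the AUC of a repetition is computed on its pooled
#' out-of-fold scores. Imputation (training-fold medians) and
#' standardization are fit within training folds only.
#'
#' @param x a [meth_matrix()] or a numeric samples-x-features matrix
#'   (AMF or qPCR relative signal).
#' @param labels logical (TRUE = case) or labels plus `positive`.
#' @param markers columns to use (default: all).
#' @param cv a [cv_config()].
#' @param positive positive class for non-logical labels.
#' @param lambda ridge penalty on standardized features (default 1).
#' @return list with `mean_auc`, `per_repeat`, and `oof_mean` (per-sample
#'   scores averaged over repetitions).
#' @export
cv_auc <- function(x, labels, markers = NULL, cv = cv_config(),
                   positive = NULL, lambda = 1) {
  X <- feature_matrix(x)
  y <- as_positive(labels, positive)
  if (is.null(markers)) markers <- colnames(X)
  miss <- setdiff(markers, colnames(X))
  if (length(miss)) {
    stop("marker(s) absent from the matrix: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(y)) < 2) stop("both classes required", call. = FALSE)
  prep <- prep_cv(X[, markers, drop = FALSE], y, cv)
  subset_cv_auc(prep, y, seq_along(markers), lambda)
}

feature_matrix <- function(x) {
  if (inherits(x, "meth_matrix")) return(amf(x))
  x <- as.matrix(x)
  if (is.null(colnames(x))) stop("feature matrix needs column names",
                                 call. = FALSE)
  storage.mode(x) <- "double"
  x
}

#' Anchor-based greedy forward marker selection
#'
#' The marker with the highest single-marker cross-validated AUC is the
#' anchor; remaining markers are added greedily, each addition evaluated
#' by repeated k-fold CV on the identical fold layout. The full greedy
#' path is walked to the panel size, and the returned subset is the global
#' AUC argmax along the path — ties broken toward the smaller subset, then
#' toward panel order.
#'
#' @inheritParams cv_auc
#' @param markers candidate marker ids, in panel order (tie-break order).
#' @return list with `markers` (selected subset, in addition order),
#'   `cv_auc` (its mean CV AUC), `path` (data.frame of size, added marker,
#'   mean CV AUC per greedy step), and `oof_mean` (repeat-averaged
#'   out-of-fold scores of the selected subset).
#' @export
forward_select <- function(x, labels, markers, cv = cv_config(),
                           positive = NULL, lambda = 1) {
  X <- feature_matrix(x)
  y <- as_positive(labels, positive)
  miss <- setdiff(markers, colnames(X))
  if (length(miss)) {
    stop("marker(s) absent from the matrix: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!length(markers)) stop("empty candidate panel", call. = FALSE)
  X <- X[, markers, drop = FALSE]
  prep <- prep_cv(X, y, cv)
  K <- length(markers)

  chosen <- integer(0)
  remaining <- seq_len(K)
  path_auc <- numeric(K)
  path_marker <- character(K)
  results <- vector("list", K)
  for (size in seq_len(K)) {
    cand_auc <- vapply(remaining, function(j) {
      subset_cv_auc(prep, y, c(chosen, j), lambda)$mean_auc
    }, numeric(1))
    best <- remaining[which.max(cand_auc)]  # ties: first in panel order
    chosen <- c(chosen, best)
    remaining <- setdiff(remaining, best)
    res <- subset_cv_auc(prep, y, chosen, lambda)
    results[[size]] <- list(markers = markers[chosen], res = res)
    path_auc[size] <- res$mean_auc
    path_marker[size] <- markers[best]
  }
  best_size <- which.max(path_auc)  # ties: smallest subset
  sel <- results[[best_size]]
  list(
    markers = sel$markers,
    cv_auc = sel$res$mean_auc,
    per_repeat = sel$res$per_repeat,
    oof_mean = stats::setNames(sel$res$oof_mean, rownames(X)),
    path = data.frame(size = seq_len(K), added = path_marker,
                      cv_auc = path_auc, stringsAsFactors = FALSE)
  )
}

#' Calibrate a decision cutoff on training scores
#'
#' Screening mode (`"screen"`) returns the largest cutoff whose training
#' sensitivity reaches `target` (favoring specificity subject to the
#' sensitivity floor); diagnostic mode (`"diagnostic"`) returns the
#' smallest cutoff whose training specificity reaches `target` (favoring
#' sensitivity subject to the specificity floor). Calls are
#' `score >= cutoff`. Scores should be the repeat-averaged out-of-fold
#' scores, so the operating point is honest for training data.
#'
#' @param scores training scores in \[0, 1\].
#' @param labels logical (TRUE = case) or labels plus `positive`.
#' @param mode `"screen"` or `"diagnostic"`.
#' @param target sensitivity (screen) or specificity (diagnostic) floor.
#' @param positive positive class for non-logical labels.
#' @return cutoff in (0, 1); if the target is unattainable the boundary
#'   cutoff is returned with a warning.
#' @export
calibrate_cutoff <- function(scores, labels, mode = c("screen", "diagnostic"),
                             target = NULL, positive = NULL) {
  mode <- match.arg(mode)
  if (is.null(target)) target <- if (mode == "screen") 0.90 else 0.95
  check_fraction(target, "target")
  y <- as_positive(labels, positive)
  ok <- !is.na(scores) & !is.na(y)
  scores <- scores[ok]
  y <- y[ok]
  u <- sort(unique(scores))
  above <- u[length(u)] + min(1e-9, (1 - u[length(u)]) / 2)
  cand <- c(u, above)
  if (mode == "screen") {
    sens <- vapply(cand, function(c) mean(scores[y] >= c), numeric(1))
    valid <- cand[sens >= target]
    if (!length(valid)) {
      warning("target sensitivity unattainable; using boundary cutoff",
              call. = FALSE)
      valid <- min(cand)
    }
    cutoff <- max(valid)
  } else {
    spec <- vapply(cand, function(c) mean(scores[!y] < c), numeric(1))
    valid <- cand[spec >= target]
    if (!length(valid)) {
      warning("target specificity unattainable; using boundary cutoff",
              call. = FALSE)
      valid <- max(cand)
    }
    cutoff <- min(valid)
  }
  min(max(cutoff, .Machine$double.eps), 1 - .Machine$double.eps)
}

#' Fit a panel methylation classifier
#'
#' The central fitting function: given a verified marker panel and a
#' labelled training cohort, runs anchor-based greedy forward selection
#' under repeated stratified cross-validation ([forward_select()]),
#' refits the ridge-logistic model on the full training set with the
#' selected subset, and calibrates a decision cutoff on the
#' repeat-averaged out-of-fold scores.
#'
#' Two tunings mirror two clinical intents: `mode = "screen"` trains
#' cancer vs healthy and calibrates for high sensitivity (default floor
#' 0.90); `mode = "diagnostic"` trains cancer vs benign disease and
#' calibrates for high specificity (default floor 0.95).
#'
#' @param counts a [meth_matrix()] (or numeric feature matrix) covering
#'   the training samples.
#' @param samples sample sheet with columns `sample` and `group`.
#' @param panel a `marker_panel` or character vector of marker ids.
#' @param mode `"screen"` (sensitivity-tuned, alias `"S"`) or
#'   `"diagnostic"` (specificity-tuned, alias `"D"`).
#' @param case case group label (default `"cancer"`).
#' @param control control group label; defaults to `"healthy"` for screen
#'   mode and `"benign"` for diagnostic mode.
#' @param cv a [cv_config()].
#' @param target operating-point floor passed to [calibrate_cutoff()].
#' @param lambda ridge penalty (default 1).
#' @return object of class `panel_classifier` with the selected markers
#'   (in addition order), refit coefficients and intercept,
#'   standardization and imputation parameters, cutoff, CV AUC and path,
#'   and the out-of-fold training scores (kept separate from deployment
#'   scores — see [predict.panel_classifier()]).
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(cohort_config(
#'   n_cancer = 40, n_benign = 0, n_healthy = 40, n_tumor_tissue = 0,
#'   n_wbc = 0, n_regions = 12, n_true_dmr = 4, seed = 7))
#' fit <- panel_classifier(cohort$counts, cohort$samples,
#'   panel = region_ids(cohort$counts)[1:6], mode = "screen",
#'   cv = cv_config(n_repeats = 3, seed = 7))
#' summary(fit)
#' }
#' @export
panel_classifier <- function(counts, samples, panel,
                             mode = c("screen", "diagnostic", "S", "D"),
                             case = "cancer", control = NULL,
                             cv = cv_config(), target = NULL, lambda = 1) {
  mode <- match.arg(mode)
  mode <- c(screen = "screen", S = "screen",
            diagnostic = "diagnostic", D = "diagnostic")[[mode]]
  if (is.null(control)) {
    control <- if (mode == "screen") "healthy" else "benign"
  }
  markers <- if (inherits(panel, "marker_panel")) panel$markers else
    as.character(panel)

  X <- feature_matrix(counts)
  samples <- check_sample_sheet(samples)
  grp <- samples$group[match(rownames(X), samples$sample)]
  use <- !is.na(grp) & grp %in% c(case, control)
  if (sum(use) < 4) stop("too few case/control samples", call. = FALSE)
  X <- X[use, , drop = FALSE]
  y <- grp[use] == case

  sel <- forward_select(X, y, markers, cv = cv, lambda = lambda)

  # final deployment model: refit on all training samples
  Xm <- X[, sel$markers, drop = FALSE]
  med <- apply(Xm, 2, stats::median, na.rm = TRUE)
  med[is.na(med)] <- 0
  Xm <- impute_cols(Xm, med)
  ctr <- colMeans(Xm)
  sc <- apply(Xm, 2, stats::sd)
  sc[!is.finite(sc) | sc == 0] <- 1
  fit <- ridge_logistic(scale(Xm, ctr, sc), y, lambda)

  target_used <- target %||% (if (mode == "screen") 0.90 else 0.95)
  cutoff <- calibrate_cutoff(sel$oof_mean, y, mode, target_used)

  structure(list(
    mode = mode,
    case = case,
    control = control,
    markers = sel$markers,
    coefficients = stats::setNames(fit$coef, sel$markers),
    intercept = fit$intercept,
    center = ctr,
    scale = sc,
    impute_medians = med,
    lambda = lambda,
    cutoff = cutoff,
    target = target_used,
    cv = cv,
    cv_auc = sel$cv_auc,
    cv_auc_per_repeat = sel$per_repeat,
    path = sel$path,
    cv_scores = sel$oof_mean,
    training_labels = stats::setNames(y, rownames(X))
  ), class = "panel_classifier")
}

#' Score samples with a fitted panel classifier
#'
#' Deployment scoring: missing marker values are imputed with the
#' training medians stored in the model, features are standardized with
#' the stored training moments, and the linear log-odds model maps to a
#' probability score. These are the final-refit scores; the out-of-fold
#' training scores live in `object$cv_scores` and are never mixed in.
#'
#' @param object a `panel_classifier`.
#' @param newdata a [meth_matrix()] or numeric feature matrix containing
#'   every model marker as a column.
#' @param type `"response"` (probability, default), `"link"` (log-odds),
#'   or `"class"` (logical call at the stored cutoff).
#' @param ... unused.
#' @return named vector of scores or calls.
#' @export
predict.panel_classifier <- function(object, newdata,
                                     type = c("response", "link", "class"),
                                     ...) {
  type <- match.arg(type)
  X <- feature_matrix(newdata)
  miss <- setdiff(object$markers, colnames(X))
  if (length(miss)) {
    stop("marker(s) missing from new data: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  Xm <- impute_cols(X[, object$markers, drop = FALSE], object$impute_medians)
  eta <- object$intercept +
    drop(scale(Xm, object$center, object$scale) %*% object$coefficients)
  names(eta) <- rownames(X)
  switch(type,
         link = eta,
         response = stats::plogis(eta),
         class = stats::plogis(eta) >= object$cutoff)
}

#' @rdname predict.panel_classifier
#' @param model a `panel_classifier`.
#' @param counts new data to score.
#' @export
score_samples <- function(model, counts) {
  predict(model, counts, type = "response")
}

#' @export
coef.panel_classifier <- function(object, ...) {
  c(`(Intercept)` = object$intercept, object$coefficients)
}

#' @export
print.panel_classifier <- function(x, ...) {
  cat(sprintf("panel_classifier [%s]: %s vs %s\n", x$mode, x$case, x$control))
  cat(sprintf("  markers (%d): %s\n", length(x$markers),
              paste(x$markers, collapse = ", ")))
  cat(sprintf("  training CV AUC: %.3f  (%dx%d-fold)\n",
              x$cv_auc, x$cv$n_repeats, x$cv$n_folds))
  cat(sprintf("  cutoff: %.3f (%s floor %.2f)\n", x$cutoff,
              if (x$mode == "screen") "sensitivity" else "specificity",
              x$target))
  invisible(x)
}

#' @export
summary.panel_classifier <- function(object, ...) {
  y <- object$training_labels
  call <- object$cv_scores >= object$cutoff
  cm <- confusion_metrics(confusion_counts(y, call))
  out <- list(model = object, training_operating_point = cm)
  class(out) <- "summary.panel_classifier"
  out
}

#' @export
print.summary.panel_classifier <- function(x, ...) {
  print(x$model)
  cat("  forward-selection path (mean CV AUC by size):\n")
  p <- x$model$path
  for (i in seq_len(nrow(p))) {
    cat(sprintf("    %2d  +%-12s %.3f%s\n", p$size[i], p$added[i],
                p$cv_auc[i],
                if (p$size[i] == length(x$model$markers)) "  <- selected" else ""))
  }
  cm <- x$training_operating_point
  cat(sprintf("  training (out-of-fold) sensitivity %.1f%%, specificity %.1f%%\n",
              100 * cm$sensitivity, 100 * cm$specificity))
  invisible(x)
}

#' Plot a fitted panel classifier
#'
#' Score distributions of the two training classes (repeat-averaged
#' out-of-fold scores) with the decision cutoff.
#'
#' @param x a `panel_classifier`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.panel_classifier <- function(x, ...) {
  s <- x$cv_scores
  y <- x$training_labels
  d1 <- stats::density(s[y], from = 0, to = 1)
  d0 <- stats::density(s[!y], from = 0, to = 1)
  graphics::plot(d1, col = "firebrick", lwd = 2, xlab = "model score",
                 main = sprintf("%s model: training score distributions",
                                x$mode), ...)
  graphics::lines(d0, col = "steelblue", lwd = 2)
  graphics::abline(v = x$cutoff, lty = 2)
  graphics::legend("topright", bty = "n", lwd = 2,
                   col = c("firebrick", "steelblue"),
                   legend = c(x$case, x$control))
  invisible(x)
}

#' Two-model sequential cascade classification
#'
#' Screening-then-triage rule: every sample is scored by the screening
#' model; only screen-positives are re-tested by the diagnostic model, and
#' the final call is positive iff both are positive. Screen-negatives are
#' final negatives and their diagnostic call is NA (not tested).
#'
#' @param s_model screening-mode `panel_classifier`.
#' @param d_model diagnostic-mode `panel_classifier`.
#' @param counts a [meth_matrix()] or feature matrix scorable by both.
#' @param samples optional sample sheet; when given, per-group audit
#'   counts are attached.
#' @return object of class `cascade_result`: data.frame `calls` (sample,
#'   s_score, s_call, d_score, d_call, final_call) plus `audit` (per-group
#'   stage-wise counts) when `samples` is supplied.
#' @export
cascade_classify <- function(s_model, d_model, counts, samples = NULL) {
  stopifnot(inherits(s_model, "panel_classifier"),
            inherits(d_model, "panel_classifier"))
  s_score <- predict(s_model, counts)
  d_score <- predict(d_model, counts)
  s_call <- s_score >= s_model$cutoff
  d_call <- ifelse(s_call, d_score >= d_model$cutoff, NA)
  final <- s_call & !is.na(d_call) & d_call
  calls <- data.frame(
    sample = names(s_score),
    s_score = unname(s_score),
    s_call = unname(s_call),
    d_score = unname(d_score),
    d_call = unname(d_call),
    final_call = unname(final),
    stringsAsFactors = FALSE
  )
  audit <- NULL
  if (!is.null(samples)) {
    samples <- check_sample_sheet(samples)
    grp <- samples$group[match(calls$sample, samples$sample)]
    audit <- do.call(rbind, lapply(split(seq_len(nrow(calls)), grp), function(i) {
      data.frame(group = grp[i[1]],
                 n = length(i),
                 s_positive = sum(calls$s_call[i]),
                 d_reclassified = sum(calls$s_call[i] & !calls$final_call[i]),
                 final_positive = sum(calls$final_call[i]),
                 stringsAsFactors = FALSE)
    }))
    rownames(audit) <- NULL
  }
  structure(list(calls = calls, audit = audit), class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  cat(sprintf("cascade_result: %d samples, %d screen-positive, %d final-positive\n",
              nrow(x$calls), sum(x$calls$s_call), sum(x$calls$final_call)))
  if (!is.null(x$audit)) print(x$audit)
  invisible(x)
}
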