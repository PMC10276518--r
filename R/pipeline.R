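#' Configuration for an end-to-end study run
#'
#' One object holding every tunable of the staged pipeline: the synthetic
#' study generator (or a pre-built study), quantification and
#' marker-selection thresholds, cross-validation settings, the two
#' operating-point floors, and the prevalence grid for predictive-value
#' adjustment. A single `seed` propagates deterministically to every
#' stochastic stage (simulation, fold assignment, bootstrap).
#'
#' @param sim a [cohort_config()] for [simulate_study()]; its group sizes
#'   define the model-building cohort.
#' @param min_coverage region coverage floor (default 100).
#' @param top_k,p_max,max_healthy_background discovery-stage thresholds
#'   (see [select_discovery_markers()]).
#' @param allowlist optional curated candidate ids applied before
#'   verification (see [verify_markers()]).
#' @param cv a [cv_config()]; its seed is overridden by `seed`.
#' @param s_target,d_target sensitivity/specificity floors for the
#'   screening and diagnostic cutoffs.
#' @param prevalence prevalences at which to adjust predictive values
#'   (default 0.10).
#' @param n_boot bootstrap resamples for confidence intervals.
#' @param out_dir optional directory; when set, [run_pipeline()] writes
#'   the report JSON, both model JSONs, the verified panel TSV and BED.
#' @param seed global seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = cohort_config(), min_coverage = 100,
                            top_k = 50, p_max = 0.05,
                            max_healthy_background = 0.05, allowlist = NULL,
                            cv = cv_config(), s_target = 0.90,
                            d_target = 0.95, prevalence = 0.10,
                            n_boot = 1000, out_dir = NULL, seed = 1L) {
  seed <- check_count(seed, "seed")
  sim$seed <- seed
  cv$seed <- seed + 100L
  structure(list(
    sim = sim, min_coverage = min_coverage, top_k = top_k, p_max = p_max,
    max_healthy_background = max_healthy_background, allowlist = allowlist,
    cv = cv, s_target = s_target, d_target = d_target,
    prevalence = prevalence, n_boot = n_boot, out_dir = out_dir, seed = seed
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level keys: any [cohort_config()] field under `sim`, and
#' any [pipeline_config()] scalar (`min_coverage`, `top_k`, `p_max`,
#' `max_healthy_background`, `allowlist`, `s_target`, `d_target`,
#' `prevalence`, `n_boot`, `out_dir`, `seed`); `cv` takes `n_repeats`,
#' `n_folds`, `stratified`.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- do.call(cohort_config, y$sim %||% list())
  cvargs <- y$cv %||% list()
  cv <- do.call(cv_config, cvargs)
  args <- y[setdiff(names(y), c("sim", "cv"))]
  args$sim <- sim
  args$cv <- cv
  do.call(pipeline_config, args)
}

#' Run the full marker-development study
#'
#' Executes the staged design end to end on a synthetic study: simulate
#' (discovery, tissue, verification, training, validation cohorts sharing
#' one region panel) -> coverage filter -> discovery marker selection ->
#' tissue/plasma verification -> screening and diagnostic classifier
#' training -> held-out evaluation (single models, sequential cascade,
#' prevalence-adjusted predictive values, covariate association, CEA
#' combination). Reruns with the same config are byte-identical.
#'
#' Real cohorts can be analysed with the same stage functions directly
#' ([marker_stats()], [select_discovery_markers()], [verify_markers()],
#' [panel_classifier()], [cascade_classify()]); `run_pipeline` drives the
#' synthetic study design.
#'
#' @param config a [pipeline_config()].
#' @param study optional pre-built `synthetic_study`; simulated from
#'   `config$sim` when NULL.
#' @return list of class `pipeline_report` with elements `seed`, `panel`
#'   (verified `marker_panel`), `s_model`, `d_model`, `validation`
#'   (performance reports, cascade result and metrics, prevalence
#'   adjustments), `covariates`, `cea`, and `log` (per-stage row counts
#'   and parameters).
#' @export
run_pipeline <- function(config = pipeline_config(), study = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- list(seed = config$seed)

  if (is.null(study)) study <- simulate_study(config$sim)
  stopifnot(inherits(study, "synthetic_study"))
  log$groups <- lapply(study[c("discovery", "tissue", "verification",
                               "training", "validation")],
                       function(ph) as.list(table(ph$samples$group)))

  filt <- function(cohort) {
    cohort$counts <- coverage_filter(cohort$counts, config$min_coverage)
    cohort
  }
  study$discovery <- filt(study$discovery)
  study$tissue <- filt(study$tissue)
  study$verification <- filt(study$verification)
  study$training <- filt(study$training)
  study$validation <- filt(study$validation)
  log$min_coverage <- config$min_coverage
  log$n_regions_used <- ncol(study$discovery$counts$methylated)

  # Phase I: plasma discovery
  disc_stats <- marker_stats(study$discovery$counts,
                             study$discovery$samples)
  panel0 <- select_discovery_markers(
    disc_stats, top_k = config$top_k, p_max = config$p_max,
    max_healthy_background = config$max_healthy_background)
  log$n_discovery_markers <- length(panel0$markers)

  # Phase II: tissue + plasma verification
  tissue_stats <- marker_stats(study$tissue$counts, study$tissue$samples,
                               case = "tumor", control = "wbc")
  ver_stats <- marker_stats(study$verification$counts,
                            study$verification$samples)
  panel <- verify_markers(panel0, ver_stats, tissue_stats,
                          allowlist = config$allowlist)
  log$n_verified_markers <- length(panel$markers)

  # Phase III: model building on the training cohort
  cv_s <- config$cv; cv_s$seed <- config$seed + 200L
  cv_d <- config$cv; cv_d$seed <- config$seed + 300L
  s_model <- panel_classifier(study$training$counts, study$training$samples,
                              panel, mode = "screen", cv = cv_s,
                              target = config$s_target)
  d_model <- panel_classifier(study$training$counts, study$training$samples,
                              panel, mode = "diagnostic", cv = cv_d,
                              target = config$d_target)

  # Phase IV: held-out validation
  val <- study$validation
  vgrp <- val$samples$group
  s_scores <- predict(s_model, val$counts)
  d_scores <- predict(d_model, val$counts)
  is_cancer <- vgrp == "cancer"

  sel <- vgrp %in% c("cancer", "healthy")
  s_report <- performance_report(s_scores[sel], is_cancer[sel],
                                 s_model$cutoff, n_boot = config$n_boot,
                                 seed = config$seed + 400L)
  sel_d <- vgrp %in% c("cancer", "benign")
  d_report <- performance_report(d_scores[sel_d], is_cancer[sel_d],
                                 d_model$cutoff, n_boot = config$n_boot,
                                 seed = config$seed + 401L)

  cascade <- cascade_classify(s_model, d_model, val$counts, val$samples)
  casc_counts <- confusion_counts(is_cancer, cascade$calls$final_call)
  casc_metrics <- confusion_metrics(casc_counts)

  prevalence <- lapply(config$prevalence, function(p) {
    adj <- prevalence_adjust(casc_metrics$sensitivity[[1]],
                             casc_metrics$specificity[[1]], p)
    list(prevalence = p, ppv = adj$ppv[[1]], npv = adj$npv[[1]])
  })

  cov_assoc <- NULL
  stage_groups <- val$samples$stage[is_cancer]
  if (length(unique(stats::na.omit(stage_groups))) >= 2) {
    cov_assoc <- tryCatch(
      covariate_association(s_scores[is_cancer], stage_groups),
      error = function(e) NULL, warning = function(w) NULL)
  }

  cea <- combine_with_cea(d_scores[sel_d], val$samples$cea[sel_d],
                          is_cancer[sel_d])

  report <- structure(list(
    seed = config$seed,
    panel = panel,
    s_model = s_model,
    d_model = d_model,
    validation = list(
      s_report = s_report,
      d_report = d_report,
      cascade = cascade,
      cascade_counts = casc_counts,
      cascade_metrics = casc_metrics,
      prevalence = prevalence
    ),
    covariates = cov_assoc,
    cea = cea[c("auc_cea", "auc_score", "auc_combined", "n_used")],
    log = log
  ), class = "pipeline_report")

  if (!is.null(config$out_dir)) write_pipeline_report(report, config$out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("pipeline_report (seed %d)\n", x$seed))
  cat(sprintf("  verified panel: %d markers\n", length(x$panel$markers)))
  cat(sprintf("  screen model: %d markers, CV AUC %.3f; validation AUC %.3f\n",
              length(x$s_model$markers), x$s_model$cv_auc,
              x$validation$s_report$auc))
  cat(sprintf("  diagnostic model: %d markers, CV AUC %.3f; validation AUC %.3f\n",
              length(x$d_model$markers), x$d_model$cv_auc,
              x$validation$d_report$auc))
  cm <- x$validation$cascade_metrics
  cat(sprintf("  cascade: sensitivity %.1f%%, specificity %.1f%%\n",
              100 * cm$sensitivity, 100 * cm$specificity))
  for (p in x$validation$prevalence) {
    cat(sprintf("  at %.0f%% prevalence: PPV %.1f%%, NPV %.1f%%\n",
                100 * p$prevalence, 100 * p$ppv, 100 * p$npv))
  }
  invisible(x)
}

# Flatten a pipeline report into JSON-friendly structures and write the
# run's artifacts (report.json, model JSONs, panel TSV + BED).
write_pipeline_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_model(report$s_model, file.path(out_dir, "model_screen.json"))
  write_model(report$d_model, file.path(out_dir, "model_diagnostic.json"))
  utils::write.table(report$panel$stats,
                     file.path(out_dir, "panel_verified.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  perf <- function(r) list(
    counts = as.list(r$counts),
    sensitivity = r$metrics$sensitivity[[1]],
    specificity = r$metrics$specificity[[1]],
    ppv = r$metrics$ppv[[1]], npv = r$metrics$npv[[1]],
    auc = r$auc,
    ci = list(metric = c("sensitivity", "specificity", "ppv", "npv", "auc"),
              low = r$ci$low, high = r$ci$high),
    cutoff = r$cutoff, n = r$n, n_boot = r$n_boot)
  obj <- list(
    format = "methcascade_pipeline_report",
    seed = report$seed,
    panel = report$panel$markers,
    s_model = list(markers = report$s_model$markers,
                   cv_auc = report$s_model$cv_auc,
                   cutoff = report$s_model$cutoff),
    d_model = list(markers = report$d_model$markers,
                   cv_auc = report$d_model$cv_auc,
                   cutoff = report$d_model$cutoff),
    validation = list(
      screen = perf(report$validation$s_report),
      diagnostic = perf(report$validation$d_report),
      cascade = list(
        counts = as.list(report$validation$cascade_counts),
        sensitivity = report$validation$cascade_metrics$sensitivity[[1]],
        specificity = report$validation$cascade_metrics$specificity[[1]],
        audit = report$validation$cascade$audit),
      prevalence = report$validation$prevalence),
    cea = report$cea,
    log = report$log
  )
  jsonlite::write_json(obj, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(out_dir)
}
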