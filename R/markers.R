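#' Per-region differential methylation statistics
#'
#' For every region, compares the AMF distribution of a case group against
#' a control group: group means, fold change of means (with a pseudocount
#' guarding against a zero background), a two-sided Mann-Whitney p-value
#' with tie correction, Benjamini-Hochberg q-values across regions, and the
#' single-region AUC (probability a random case outscores a random control,
#' ties counted half). Degenerate regions whose values are all identical
#' are reported as AUC 0.5, p = 1 and flagged.
#'
#' @param counts a [meth_matrix()].
#' @param samples sample sheet data.frame with columns `sample` and `group`.
#' @param case,control group labels to contrast (defaults cancer vs
#'   healthy; use `"tumor"` vs `"wbc"` for tissue verification).
#' @param pseudocount added to both means before the ratio (default 1e-4).
#' @return data.frame with one row per region: `region`, `mean_case`,
#'   `mean_control`, per-group means for all groups present, `fold_change`,
#'   `log2_fc`, `log10_fc`, `p_value`, `q_value`, `auc_single`,
#'   `control_background`, `degenerate`.
#' @export
marker_stats <- function(counts, samples, case = "cancer",
                         control = "healthy", pseudocount = 1e-4) {
  stopifnot(inherits(counts, "meth_matrix"))
  samples <- check_sample_sheet(samples)
  a <- amf(counts)
  grp <- samples$group[match(rownames(a), samples$sample)]
  if (anyNA(grp)) {
    stop("samples in the matrix missing from the sample sheet: ",
         paste(utils::head(rownames(a)[is.na(grp)], 3), collapse = ", "),
         call. = FALSE)
  }
  for (g in c(case, control)) {
    if (sum(grp == g) < 2) {
      stop(sprintf("group '%s' needs at least 2 samples", g), call. = FALSE)
    }
  }
  x_case <- a[grp == case, , drop = FALSE]
  x_ctrl <- a[grp == control, , drop = FALSE]

  mean_case <- colMeans(x_case, na.rm = TRUE)
  mean_ctrl <- colMeans(x_ctrl, na.rm = TRUE)
  fc <- (mean_case + pseudocount) / (mean_ctrl + pseudocount)

  nr <- ncol(a)
  p <- numeric(nr)
  auc <- numeric(nr)
  degenerate <- logical(nr)
  for (j in seq_len(nr)) {
    xc <- x_case[, j]
    xh <- x_ctrl[, j]
    xc <- xc[!is.na(xc)]
    xh <- xh[!is.na(xh)]
    vals <- c(xc, xh)
    if (length(xc) < 2 || length(xh) < 2 || length(unique(vals)) < 2) {
      p[j] <- 1
      auc[j] <- 0.5
      degenerate[j] <- TRUE
      next
    }
    p[j] <- stats::wilcox.test(xc, xh, exact = FALSE)$p.value
    auc[j] <- rank_auc(vals, c(rep(TRUE, length(xc)), rep(FALSE, length(xh))))
  }
  p[is.na(p)] <- 1

  out <- data.frame(
    region = colnames(a),
    mean_case = mean_case,
    mean_control = mean_ctrl,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  for (g in unique(grp)) {
    out[[paste0("mean_", g)]] <- colMeans(a[grp == g, , drop = FALSE],
                                          na.rm = TRUE)
  }
  out$fold_change <- fc
  out$log2_fc <- log2(fc)
  out$log10_fc <- log10(fc)
  out$p_value <- p
  out$q_value <- stats::p.adjust(p, method = "BH")
  out$auc_single <- auc
  out$control_background <- mean_ctrl
  out$degenerate <- degenerate
  attr(out, "contrast") <- c(case = case, control = control)
  out
}

new_marker_panel <- function(markers, stats, stage, allowlist = NULL) {
  structure(list(markers = markers, stats = stats, stage = stage,
                 allowlist = allowlist),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("marker_panel (%s): %d markers\n", x$stage, length(x$markers)))
  if (length(x$markers)) {
    cat("  ", paste(utils::head(x$markers, 10), collapse = ", "),
        if (length(x$markers) > 10) "..." else "", "\n")
  }
  invisible(x)
}

#' Discovery-stage marker selection
#'
#' Plasma discovery funnel for hypermethylated markers: keep regions that
#' are significant after BH adjustment, elevated in cases (fold change
#' above 1), and quiet in healthy plasma (background AMF at or below
#' `max_healthy_background`); rank survivors by single-region AUC, then
#' fold change; return the top `top_k`.
#'
#' @param stats output of [marker_stats()] on the discovery cohort
#'   (cancer vs healthy).
#' @param top_k panel size cap (default 50).
#' @param p_max q-value threshold (default 0.05).
#' @param max_healthy_background maximum mean healthy AMF (default 0.05).
#' @return a `marker_panel` (stage `"discovery"`). Fewer than `top_k`
#'   survivors is a warning, not an error.
#' @export
select_discovery_markers <- function(stats, top_k = 50, p_max = 0.05,
                                     max_healthy_background = 0.05) {
  check_count(top_k, "top_k", min = 1L)
  check_fraction(p_max, "p_max")
  keep <- !stats$degenerate &
    stats$q_value <= p_max &
    stats$fold_change > 1 &
    stats$control_background <= max_healthy_background
  surv <- stats[keep, , drop = FALSE]
  surv <- surv[order(-surv$auc_single, -surv$fold_change, surv$region), ,
               drop = FALSE]
  if (nrow(surv) < top_k) {
    warning(sprintf("only %d markers pass the discovery filters (top_k = %d)",
                    nrow(surv), top_k), call. = FALSE)
  }
  surv <- utils::head(surv, top_k)
  new_marker_panel(surv$region, surv, stage = "discovery")
}

#' Tissue/plasma marker verification
#'
#' Second-stage funnel applied to an already-discovered panel, mirroring
#' assay feasibility verification: an optional user-supplied allowlist
#' first (standing in for manual curation by gene annotation and primer
#' designability), then three conjunctive rules — plasma log2 fold change
#' (cancer vs healthy) above `log2_fc_min`, plasma p-value below `p_max`
#' (raw, since only a handful of candidates reach this stage), and tissue
#' log10 fold change (tumor vs WBC) above `log10_fc_min`.
#'
#' @param panel a `marker_panel` from [select_discovery_markers()].
#' @param plasma_stats [marker_stats()] on the verification plasma cohort
#'   (cancer vs healthy).
#' @param tissue_stats [marker_stats()] on the tissue cohort
#'   (`case = "tumor"`, `control = "wbc"`).
#' @param allowlist optional character vector of region ids to intersect
#'   with before the numeric rules.
#' @param log2_fc_min,p_max,log10_fc_min rule thresholds (defaults 1, 0.05, 1).
#' @return a `marker_panel` (stage `"verified"`), ordered by plasma AUC
#'   then fold change.
#' @export
verify_markers <- function(panel, plasma_stats, tissue_stats,
                           allowlist = NULL, log2_fc_min = 1, p_max = 0.05,
                           log10_fc_min = 1) {
  stopifnot(inherits(panel, "marker_panel"))
  cand <- panel$markers
  if (!length(cand)) stop("input panel is empty", call. = FALSE)
  if (!is.null(allowlist)) cand <- intersect(cand, allowlist)
  pl <- plasma_stats[match(cand, plasma_stats$region), , drop = FALSE]
  ti <- tissue_stats[match(cand, tissue_stats$region), , drop = FALSE]
  if (anyNA(pl$region) || anyNA(ti$region)) {
    stop("candidate markers missing from verification statistics",
         call. = FALSE)
  }
  keep <- pl$log2_fc > log2_fc_min &
    pl$p_value < p_max &
    ti$log10_fc > log10_fc_min
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) {
    stop(paste0("no markers pass verification; consider relaxing ",
                "log2_fc_min/p_max/log10_fc_min"), call. = FALSE)
  }
  surv <- pl[keep, , drop = FALSE]
  surv$log10_fc_tissue <- ti$log10_fc[keep]
  surv <- surv[order(-surv$auc_single, -surv$fold_change, surv$region), ,
               drop = FALSE]
  new_marker_panel(surv$region, surv, stage = "verified",
                   allowlist = allowlist)
}
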