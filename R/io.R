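# Plain-text I/O: count matrices (TSV), sample sheets (CSV), regions
# (BED, 0-based half-open), qPCR plates (TSV), models and reports (JSON).
# All writers round-trip losslessly through their readers.

check_sample_sheet <- function(samples) {
  if (!is.data.frame(samples)) {
    stop("sample sheet must be a data.frame", call. = FALSE)
  }
  need <- c("sample", "group")
  miss <- setdiff(need, names(samples))
  if (length(miss)) {
    stop("sample sheet missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  dup <- samples$sample[duplicated(samples$sample)]
  if (length(dup)) {
    stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  samples
}

#' Write / read a methylation count matrix as TSV
#'
#' One row per sample (`sample` column first), then a pair of columns per
#' region: `<region>.meth` and `<region>.det` holding methylated and
#' detected CpG counts. Integer counts round-trip exactly.
#'
#' @param x a [meth_matrix()].
#' @param path file path.
#' @return `write_counts` returns `path` invisibly; `read_counts` returns
#'   a [meth_matrix()].
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "meth_matrix"))
  regions <- colnames(x$methylated)
  out <- data.frame(sample = rownames(x$methylated),
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (r in regions) {
    out[[paste0(r, ".meth")]] <- x$methylated[, r]
    out[[paste0(r, ".det")]] <- x$detected[, r]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (!"sample" %in% names(tab)) {
    stop("count TSV must have a 'sample' column", call. = FALSE)
  }
  cols <- setdiff(names(tab), "sample")
  meth_cols <- grep("\\.meth$", cols, value = TRUE)
  regions <- sub("\\.meth$", "", meth_cols)
  det_cols <- paste0(regions, ".det")
  if (!length(regions) || !all(det_cols %in% cols)) {
    stop("count TSV needs '<region>.meth'/'<region>.det' column pairs",
         call. = FALSE)
  }
  m <- as.matrix(tab[meth_cols])
  d <- as.matrix(tab[det_cols])
  dimnames(m) <- dimnames(d) <- list(tab$sample, regions)
  meth_matrix(m, d)
}

#' Write / read a sample sheet as CSV
#'
#' Requires `sample` and `group` columns; any further clinical covariates
#' (stage, tumor size, histology, CEA, demographics) travel unchanged.
#'
#' @param samples sample sheet data.frame.
#' @param path file path.
#' @return `write_sample_sheet` returns `path` invisibly;
#'   `read_sample_sheet` returns the validated data.frame.
#' @export
write_sample_sheet <- function(samples, path) {
  check_sample_sheet(samples)
  utils::write.csv(samples, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  check_sample_sheet(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write / read regions as BED
#'
#' Six-column BED, 0-based half-open coordinates kept native (no
#' conversion). Malformed rows are rejected with their line number; a
#' strand column is read but ignored with a warning, since region-level
#' methylation aggregates are strandless.
#'
#' @param regions data.frame with columns `chrom`, `start`, `end`, and
#'   optionally `region` (name) and `score`.
#' @param path file path.
#' @return `write_bed` returns `path` invisibly; `read_bed` returns a
#'   data.frame with `chrom`, `start`, `end`, `region`, `score`, `strand`.
#' @export
write_bed <- function(regions, path) {
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(regions))
  if (length(miss)) {
    stop("regions need column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(
    chrom = regions$chrom,
    start = as.integer(regions$start),
    end = as.integer(regions$end),
    name = regions$region %||% regions$name %||% ".",
    score = regions$score %||% 0L,
    strand = ".",
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  keep <- !grepl("^(track|browser|#)", lines)
  rows <- strsplit(lines[keep], "\t", fixed = TRUE)
  lineno <- which(keep)
  parse_row <- function(f, ln) {
    if (length(f) < 3) {
      stop(sprintf("BED line %d: fewer than 3 fields", ln), call. = FALSE)
    }
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end)) {
      stop(sprintf("BED line %d: non-integer coordinates", ln), call. = FALSE)
    }
    if (end <= start) {
      stop(sprintf("BED line %d: end (%d) must exceed start (%d)",
                   ln, end, start), call. = FALSE)
    }
    list(chrom = f[1], start = start, end = end,
         region = if (length(f) >= 4) f[4] else NA_character_,
         score = if (length(f) >= 5) suppressWarnings(as.numeric(f[5])) else NA_real_,
         strand = if (length(f) >= 6) f[6] else NA_character_)
  }
  parsed <- Map(parse_row, rows, lineno)
  out <- do.call(rbind, lapply(parsed, as.data.frame,
                               stringsAsFactors = FALSE))
  rownames(out) <- NULL
  if (any(!is.na(out$strand) & out$strand %in% c("+", "-"))) {
    warning("BED strand column ignored: methylation regions are strandless",
            call. = FALSE)
  }
  out
}

#' Write / read a qPCR plate table as TSV
#'
#' Columns `sample`, `marker`, `ct_marker`, `ct_reference`.
#'
#' @param plate plate data.frame.
#' @param path file path.
#' @return `write_qpcr` returns `path` invisibly; `read_qpcr` the
#'   validated data.frame.
#' @export
write_qpcr <- function(plate, path) {
  need <- c("sample", "marker", "ct_marker", "ct_reference")
  miss <- setdiff(need, names(plate))
  if (length(miss)) {
    stop("plate table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  utils::write.table(plate[need], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_qpcr
#' @export
read_qpcr <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "marker", "ct_marker", "ct_reference")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("plate table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tab
}

#' Serialize / restore a panel classifier as JSON
#'
#' Stores everything deployment scoring needs: markers, coefficients,
#' intercept, standardization moments, imputation medians, cutoff, mode,
#' and CV metadata. Training artifacts (out-of-fold scores, selection
#' path) are not serialized; a restored model scores new samples but does
#' not replay training summaries.
#'
#' @param model a `panel_classifier`.
#' @param path file path.
#' @return `write_model` returns `path` invisibly; `read_model` a
#'   `panel_classifier`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "panel_classifier"))
  obj <- list(
    format = "methcascade_panel_classifier",
    version = 1L,
    mode = model$mode,
    case = model$case,
    control = model$control,
    markers = model$markers,
    coefficients = unname(model$coefficients),
    intercept = model$intercept,
    center = unname(model$center),
    scale = unname(model$scale),
    impute_medians = unname(model$impute_medians),
    lambda = model$lambda,
    cutoff = model$cutoff,
    target = model$target,
    cv = list(n_repeats = model$cv$n_repeats, n_folds = model$cv$n_folds,
              stratified = model$cv$stratified, seed = model$cv$seed),
    cv_auc = model$cv_auc
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "methcascade_panel_classifier")) {
    stop("not a serialized panel_classifier: ", path, call. = FALSE)
  }
  nm <- obj$markers
  structure(list(
    mode = obj$mode,
    case = obj$case,
    control = obj$control,
    markers = nm,
    coefficients = stats::setNames(obj$coefficients, nm),
    intercept = obj$intercept,
    center = stats::setNames(obj$center, nm),
    scale = stats::setNames(obj$scale, nm),
    impute_medians = stats::setNames(obj$impute_medians, nm),
    lambda = obj$lambda,
    cutoff = obj$cutoff,
    target = obj$target,
    cv = cv_config(obj$cv$n_repeats, obj$cv$n_folds, obj$cv$stratified,
                   obj$cv$seed),
    cv_auc = obj$cv_auc,
    path = NULL,
    cv_scores = NULL,
    training_labels = NULL
  ), class = "panel_classifier")
}
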