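#' Region-level methylation count matrix
#'
#' Container for per-sample, per-region bisulfite counts: the number of
#' methylated CpG observations and the number of detected CpG observations
#' in each cell. The derived signal is the average methylation fraction
#' (AMF), methylated / detected, undefined (NA) where nothing was detected.
#'
#' @param methylated integer matrix (samples x regions) of methylated CpG
#'   counts, with sample ids as rownames and region ids as colnames.
#' @param detected integer matrix of the same shape with detected CpG counts.
#' @return an object of class `meth_matrix` with elements `methylated`,
#'   `detected`.
#' @examples
#' m <- matrix(c(30, 0, 50), 1, dimnames = list("s1", c("r1", "r2", "r3")))
#' d <- matrix(c(120, 100, 0), 1, dimnames = list("s1", c("r1", "r2", "r3")))
#' amf(meth_matrix(m, d))   # 0.25, 0, NA
#' @export
meth_matrix <- function(methylated, detected) {
  methylated <- as.matrix(methylated)
  detected <- as.matrix(detected)
  if (!identical(dim(methylated), dim(detected))) {
    stop("'methylated' and 'detected' must have identical dimensions",
         call. = FALSE)
  }
  if (is.null(rownames(methylated)) || is.null(colnames(methylated))) {
    stop("count matrices need sample rownames and region colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(methylated))) {
    stop("duplicate sample ids in count matrix", call. = FALSE)
  }
  if (any(methylated < 0, na.rm = TRUE) || any(detected < 0, na.rm = TRUE)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  bad <- which(methylated > detected, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "methylated > detected at sample '%s', region '%s'",
      rownames(methylated)[bad[1, 1]], colnames(methylated)[bad[1, 2]]),
      call. = FALSE)
  }
  structure(list(methylated = methylated, detected = detected),
            class = "meth_matrix")
}

#' Average methylation fraction
#'
#' Total methylated CpG observations divided by total detected CpG
#' observations. Returns NA where detected is zero (the ratio is undefined).
#'
#' @param x a `meth_matrix`, or a vector of methylated counts.
#' @param detected vector of detected counts (when `x` is a vector).
#' @return matrix (for `meth_matrix` input) or vector of fractions in
#'   \[0, 1\], NA where undefined.
#' @export
amf <- function(x, detected = NULL) {
  if (inherits(x, "meth_matrix")) {
    m <- x$methylated
    d <- x$detected
  } else {
    m <- x
    d <- detected
    if (is.null(d)) stop("'detected' is required for vector input", call. = FALSE)
    if (any(m > d & d > 0, na.rm = TRUE)) {
      stop("methylated count exceeds detected count", call. = FALSE)
    }
    if (any(m < 0, na.rm = TRUE) || any(d < 0, na.rm = TRUE)) {
      stop("counts must be non-negative", call. = FALSE)
    }
  }
  out <- m / d
  out[d == 0] <- NA_real_
  out
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat(sprintf("meth_matrix: %d samples x %d regions\n",
              nrow(x$methylated), ncol(x$methylated)))
  cov <- stats::median(x$detected, na.rm = TRUE)
  cat(sprintf("  median detected CpGs per cell: %s\n", format(cov)))
  invisible(x)
}

#' @export
dim.meth_matrix <- function(x) dim(x$methylated)

#' Subset a methylation matrix
#'
#' @param x a `meth_matrix`.
#' @param i sample index (ids, positions, or logical).
#' @param j region index.
#' @param ... unused.
#' @return a `meth_matrix` restricted to the selected samples/regions.
#' @export
`[.meth_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$methylated))
  if (missing(j)) j <- seq_len(ncol(x$methylated))
  meth_matrix(x$methylated[i, j, drop = FALSE],
              x$detected[i, j, drop = FALSE])
}

#' Sample and region ids of a methylation matrix
#' @param x a `meth_matrix`.
#' @return character vector of ids.
#' @export
sample_ids <- function(x) rownames(x$methylated)

#' @rdname sample_ids
#' @export
region_ids <- function(x) colnames(x$methylated)

#' Coverage filter for methylation regions
#'
#' Keeps regions whose median detected-CpG count across samples reaches
#' `min_coverage` (100X by default, the usual depth floor for region-level
#' bisulfite panels). Within retained regions, individual cells below the
#' threshold have both counts set to NA so their unreliable AMF cannot leak
#' downstream; imputation is the training step's responsibility.
#'
#' @param x a `meth_matrix`.
#' @param min_coverage minimum detected-CpG count (default 100).
#' @param mask_cells set low-coverage cells to NA within retained regions
#'   (default TRUE).
#' @return filtered `meth_matrix`; attribute `"coverage_report"` records the
#'   regions kept and dropped.
#' @export
coverage_filter <- function(x, min_coverage = 100, mask_cells = TRUE) {
  stopifnot(inherits(x, "meth_matrix"))
  check_count(min_coverage, "min_coverage")
  med <- apply(x$detected, 2, stats::median, na.rm = TRUE)
  keep <- med >= min_coverage
  if (!any(keep)) {
    stop(sprintf("no regions pass coverage (min_coverage = %d)", min_coverage),
         call. = FALSE)
  }
  out <- x[, keep]
  if (mask_cells && min_coverage > 0) {
    low <- out$detected < min_coverage
    low[is.na(low)] <- FALSE
    out$methylated[low] <- NA_integer_
    out$detected[low] <- NA_integer_
  }
  attr(out, "coverage_report") <- list(
    min_coverage = min_coverage,
    n_kept = sum(keep),
    n_dropped = sum(!keep),
    dropped = colnames(x$methylated)[!keep]
  )
  out
}
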