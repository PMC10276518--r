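#' Relative signal from qPCR cycle thresholds
#'
#' Standard relative quantification against a reference gene:
#' `2^(ct_reference - ct_marker)`. A marker reaction that never crossed
#' threshold (censored at `max_cycle`, conventionally 40) carries no
#' detectable template and is reported as 0. Records whose reference-gene
#' reaction is missing or censored fail QC and return NA.
#'
#' @param ct_marker marker Ct values (cycles); NA or `>= max_cycle` means no
#'   amplification.
#' @param ct_reference reference-gene Ct values (cycles).
#' @param max_cycle censoring limit of the instrument (default 40).
#' @return numeric vector of non-negative relative signals; NA for QC-failed
#'   records (a warning lists how many failed).
#' @examples
#' qpcr_relative_signal(25, 25)    # 1
#' qpcr_relative_signal(35, 25)    # 2^-10
#' qpcr_relative_signal(40, 25)    # 0 (censored)
#' @export
qpcr_relative_signal <- function(ct_marker, ct_reference, max_cycle = 40) {
  if (length(ct_marker) != length(ct_reference)) {
    stop("'ct_marker' and 'ct_reference' must have the same length",
         call. = FALSE)
  }
  bad_ref <- is.na(ct_reference) | ct_reference >= max_cycle |
    ct_reference <= 0
  if (any(bad_ref)) {
    warning(sprintf(
      "%d record(s) excluded: missing or censored reference-gene Ct",
      sum(bad_ref)), call. = FALSE)
  }
  censored <- !bad_ref & (is.na(ct_marker) | ct_marker >= max_cycle)
  out <- 2^(ct_reference - ct_marker)
  out[censored] <- 0
  out[bad_ref] <- NA_real_
  out
}

#' Relative-signal matrix from a qPCR plate table
#'
#' Long-format plate table (columns `sample`, `marker`, `ct_marker`,
#' `ct_reference`) to a samples x markers matrix of relative signals, the
#' qPCR counterpart of an AMF matrix.
#'
#' @param plate data.frame with columns `sample`, `marker`, `ct_marker`,
#'   `ct_reference`.
#' @param max_cycle censoring limit (default 40).
#' @return numeric matrix, samples in rows, markers in columns.
#' @export
qpcr_signal_matrix <- function(plate, max_cycle = 40) {
  need <- c("sample", "marker", "ct_marker", "ct_reference")
  miss <- setdiff(need, names(plate))
  if (length(miss)) {
    stop("plate table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  sig <- qpcr_relative_signal(plate$ct_marker, plate$ct_reference, max_cycle)
  samples <- unique(plate$sample)
  markers <- unique(plate$marker)
  out <- matrix(NA_real_, length(samples), length(markers),
                dimnames = list(samples, markers))
  out[cbind(match(plate$sample, samples), match(plate$marker, markers))] <- sig
  out
}
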