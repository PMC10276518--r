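#' Sample size for a target sensitivity or specificity
#'
#' Minimum number of diseased (for sensitivity) or non-diseased (for
#' specificity) subjects needed to estimate a proportion `P` with a
#' two-sided confidence interval of half-width `d`:
#'
#' \deqn{n = \lceil z_{1-\alpha/2}^2 \, P(1-P) / d^2 \rceil}
#'
#' The exact normal quantile is used (1.959964 at 95\% confidence, not the
#' 1.96 shorthand), and the result is rounded up because `n` is a minimum.
#'
#' @param P anticipated sensitivity or specificity, in (0, 1).
#' @param d half-width of the desired confidence interval, in (0, 1).
#' @param confidence confidence level (default 0.95).
#' @return integer minimum sample size.
#' @examples
#' required_sample_size(0.90, 0.10)        # 35
#' required_sample_size(0.90, 0.05)        # 139
#' @export
required_sample_size <- function(P, d, confidence = 0.95) {
  check_fraction(P, "P", open = TRUE)
  check_fraction(d, "d", open = TRUE)
  check_fraction(confidence, "confidence", open = TRUE)
  alpha <- 1 - confidence
  z <- stats::qnorm(1 - alpha / 2)
  n <- ceiling(z^2 * P * (1 - P) / d^2)
  as.integer(max(n, 1L))
}
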