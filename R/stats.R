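#' Percentage of reads mapped to the target chromosome
#'
#' `100 * mapped_chr / total`. In the four-line experiment this fraction
#' drops by about one third in every corrected disomy relative to the
#' trisomy, confirming the loss of one chromosome copy.
#'
#' @param mapped_chr Non-negative read count on the chromosome.
#' @param total Positive total mapped read count; `mapped_chr <= total`.
#' @return Percent (unrounded); see [format_percent()] for display.
#' @examples
#' format_percent(chr21_read_fraction(12834391, 709100730))  # "1.81"
#' @export
chr21_read_fraction <- function(mapped_chr, total) {
  stopifnot(length(mapped_chr) == length(total))
  if (any(total <= 0)) stop("total read count must be positive")
  if (any(mapped_chr < 0) || any(mapped_chr > total))
    stop("mapped_chr must lie in [0, total]")
  100 * mapped_chr / total
}

#' Chromosome-elimination efficiency
#'
#' Percentage of picked colonies that proved disomic:
#' `100 * n_disomy / n_picked`.
#'
#' @param n_disomy Non-negative count of confirmed disomy colonies.
#' @param n_picked Positive total of picked colonies; `n_disomy <= n_picked`.
#' @return Percent (unrounded); see [format_percent()].
#' @examples
#' format_percent(elimination_efficiency(12, 345))  # "3.48"
#' @export
elimination_efficiency <- function(n_disomy, n_picked) {
  stopifnot(length(n_disomy) == length(n_picked))
  if (any(n_picked <= 0)) stop("n_picked must be positive")
  if (any(n_disomy < 0) || any(n_disomy > n_picked))
    stop("n_disomy must lie in [0, n_picked]")
  100 * n_disomy / n_picked
}

#' Round half-up
#'
#' Decimal rounding where `.5` always rounds away from zero toward the
#' larger magnitude (base `round()` uses round-half-even).
#'
#' @param x Numeric.
#' @param digits Decimal places (default 2).
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format a percent to fixed decimals, half-up
#'
#' @param x Percent value(s).
#' @param digits Decimal places (default 2, the precision printed for
#'   read-fraction and efficiency figures).
#' @return Character vector.
#' @export
format_percent <- function(x, digits = 2) {
  formatC(round_half_up(x, digits), format = "f", digits = digits)
}

#' MLPA aneuploidy call
#'
#' Applies the kit decision rule for a whole-chromosome gain: trisomy is
#' indicated when at least `min_probes` of the eight relative probe ratios
#' reach `ratio_threshold` (default: at least 4 of 8 ratios >= 1.30,
#' inclusive).
#'
#' @param ratios Numeric vector of exactly 8 relative probe ratios.
#' @param ratio_threshold Ratio cut-off (default 1.30).
#' @param min_probes Minimum number of probes at or above the cut-off
#'   (default 4).
#' @return `"TRISOMY"` or `"NEGATIVE"`.
#' @examples
#' mlpa_call(c(1.35, 1.40, 1.32, 1.31, 1, 1, 1, 1))
#' @export
mlpa_call <- function(ratios, ratio_threshold = 1.30, min_probes = 4) {
  if (length(ratios) != 8)
    stop("expected exactly 8 probe ratios, got ", length(ratios))
  if (any(ratios < 0)) stop("probe ratios must be non-negative")
  if (sum(ratios >= ratio_threshold) >= min_probes) "TRISOMY" else "NEGATIVE"
}
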