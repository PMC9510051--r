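#' Binned heterozygous-SNP density per sample
#'
#' Counts, per sample, the sites whose present-base set holds two or more
#' bases, in fixed-width 1-based closed bins (`[1, bin_size]`,
#' `[bin_size + 1, 2 bin_size]`, ...). Empty bins are reported explicitly —
#' the run detector needs them.
#'
#' @param profiles A `base_profiles`, sites sorted by position.
#' @param bin_size Bin width in bp (default 10000).
#' @param chrom_length Chromosome length in bp; positions beyond it error.
#' @return A `bin_counts` object: `bin_size`, `bin_start` (1-based starts of
#'   every bin), `het` (matrix `[bin, sample]`), `samples`.
#' @export
bin_het_density <- function(profiles, bin_size = 10000, chrom_length) {
  stopifnot(inherits(profiles, "base_profiles"), bin_size >= 1,
            chrom_length >= 1)
  if (is.unsorted(profiles$pos)) stop("profiles must be sorted by position")
  if (length(profiles) && max(profiles$pos) > chrom_length)
    stop("site position ", max(profiles$pos), " beyond chrom_length ",
         chrom_length)
  n_bins <- as.integer(ceiling(chrom_length / bin_size))
  bin <- floor((profiles$pos - 1) / bin_size) + 1L
  het <- vapply(profiles$samples, function(s) {
    hs <- rowSums(profiles$present[, , s, drop = FALSE]) >= 2
    tabulate(bin[hs], nbins = n_bins)
  }, integer(n_bins))
  structure(list(bin_size = bin_size,
                 bin_start = seq(1, by = bin_size, length.out = n_bins),
                 het = matrix(het, nrow = n_bins,
                              dimnames = list(NULL, profiles$samples)),
                 samples = profiles$samples,
                 chrom = profiles$chrom[1]),
            class = "bin_counts")
}

#' @export
print.bin_counts <- function(x, ...) {
  cat("bin_counts:", length(x$bin_start), "bins of", x$bin_size, "bp\n")
  cat("  het sites per sample:",
      paste(x$samples, colSums(x$het), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Detect runs of heterozygosity loss in one sample
#'
#' Finds maximal runs of at least `min_run_bins` consecutive bins with zero
#' heterozygous sites, guarded by a flank-density requirement: on each side
#' where bins exist, the nearest `min_run_bins` bins (fewer at a chromosome
#' end) must average at least `min_flank_density` heterozygous sites per
#' bin. The guard keeps sparse-coverage gaps from masquerading as
#' homozygous segments. An empty result is a "no recombination" call for
#' that sample: a deletion line goes homozygous over a stretch only where
#' its two retained homologs are identical, the footprint a meiotic M1/M2
#' crossover leaves in the delta-P line.
#'
#' @param bins A `bin_counts` from [bin_het_density()].
#' @param sample Sample name to scan.
#' @param min_run_bins Minimum run length in bins (default 5).
#' @param min_flank_density Minimum mean het count per flanking bin
#'   (default 1).
#' @return Data frame with one row per run: `start`, `end` (bp, closed
#'   interval of whole bins), `n_bins`.
#' @export
detect_homozygous_runs <- function(bins, sample, min_run_bins = 5,
                                   min_flank_density = 1) {
  stopifnot(inherits(bins, "bin_counts"), min_run_bins >= 1,
            min_flank_density >= 0)
  if (!sample %in% bins$samples)
    stop("unknown sample '", sample, "'")
  x <- bins$het[, sample]
  r <- rle(x == 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run_bins
  res <- data.frame(start = numeric(0), end = numeric(0), n_bins = integer(0))
  for (j in which(keep)) {
    lo <- starts[j]; hi <- ends[j]
    left <- x[max(1, lo - min_run_bins):(lo - 1)]
    if (lo == 1) left <- numeric(0)
    right <- if (hi < length(x)) x[(hi + 1):min(length(x), hi + min_run_bins)]
             else numeric(0)
    side_ok <- function(v) !length(v) || mean(v) >= min_flank_density
    if (!length(left) && !length(right)) next   # whole chromosome silent
    if (side_ok(left) && side_ok(right)) {
      res <- rbind(res, data.frame(
        start = bins$bin_start[lo],
        end = bins$bin_start[hi] + bins$bin_size - 1,
        n_bins = hi - lo + 1L))
    }
  }
  res
}
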