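#' Seven validated chromosome-21 SNP profiles
#'
#' Loads the packaged presence/absence base sets at seven SNPs that span the
#' chromosome-21 centromere (rs74753297 through rs78248586), the loci whose
#' phasing was confirmed by direct Sanger sequencing. Each locus is
#' heterozygous in the trisomy and homozygous in exactly one deletion line,
#' so every one phases uniquely; phasing them with [phase_all()] yields the
#' haplotype strings `ACCTGAC` (P), `GCTCAGC` (M1) and `GTCTAGT` (M2).
#' Two loci carry their published GRCh37 coordinates; the other five
#' positions are synthetic placeholders that only preserve locus order.
#'
#' @return A `base_profiles` over samples `T21, dP, dM1, dM2`, with the
#'   rs identifiers attached as attribute `rsid`.
#' @examples
#' ht <- phase_all(seven_snp_profiles(), default_design())
#' ht$haplotypes
#' @export
seven_snp_profiles <- function() {
  path <- system.file("extdata", "chr21_seven_snp_sets.tsv",
                      package = "triphase", mustWork = TRUE)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  samples <- c("T21", "dP", "dM1", "dM2")
  sets <- lapply(seq_len(nrow(df)), function(i)
    stats::setNames(lapply(samples, function(s)
      strsplit(df[[s]][i], ",", fixed = TRUE)[[1]]), samples))
  prof <- base_profiles_from_sets(df$pos, sets, trisomy = "T21",
                                  chrom = "chr21")
  attr(prof, "rsid") <- df$rsid
  prof
}
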