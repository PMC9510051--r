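#' Write a site_counts as a four-sample VCF
#'
#' Emits VCF 4.2 with `FORMAT GT:AD:DP` per sample: `GT` is left missing
#' (`.`), `AD` carries the counts for the reference and each ALT allele in
#' order, `DP` the reported depth. Every non-reference base with a non-zero
#' count in any sample appears as an ALT allele, so the count table survives
#' a round trip through [read_multisample_vcf()] exactly. Written via
#' \pkg{vcfR}, which gzip-compresses its output — use a `.vcf.gz` path.
#'
#' @param sc A [site_counts] (single-character ref alleles only).
#' @param path Output path (will be gzip-compressed VCF text).
#' @return `path`, invisibly.
#' @export
write_sample_vcf <- function(sc, path) {
  stopifnot(inherits(sc, "site_counts"))
  n <- length(sc)
  alt_str <- vapply(sc$alt, function(a)
    if (length(a)) paste(a, collapse = ",") else ".", character(1))
  fix <- cbind(CHROM = sc$chrom, POS = as.character(sc$pos),
               ID = ".", REF = sc$ref, ALT = alt_str,
               QUAL = ".", FILTER = "PASS", INFO = ".")
  gt_cols <- vapply(sc$samples, function(s) {
    ad <- vapply(seq_len(n), function(i) {
      alleles <- c(sc$ref[i], sc$alt[[i]])
      cts <- vapply(alleles, function(b) {
        if (nchar(b) == 1 && b %in% BASES) sc$counts[i, b, s] else 0L
      }, numeric(1))
      paste(cts, collapse = ",")
    }, character(1))
    paste0(".:", ad, ":", sc$depth[, s])
  }, character(n))
  gt <- cbind(FORMAT = rep("GT:AD:DP", n),
              matrix(gt_cols, nrow = n, dimnames = list(NULL, sc$samples)))
  meta <- c(
    "##fileformat=VCFv4.2",
    "##source=triphase",
    if (!is.null(sc$chrom_length))
      sprintf("##contig=<ID=%s,length=%d>", sc$chrom[1],
              as.integer(sc$chrom_length)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths for the ref and alt alleles in the order listed">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">')
  vcf <- methods::new("vcfR", meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(vcf, file = path)
  invisible(path)
}

#' Read a four-sample VCF into a site_counts
#'
#' Expects exactly the four mapped samples with per-sample `AD` (allele
#' depth) and, preferably, `DP` fields. Per-base counts for single-character
#' A/C/G/T alleles are taken from `AD` (indel/symbolic alleles contribute no
#' base count but still classify the site); depth is `DP`, falling back to
#' the sum of `AD` where `DP` is absent. Multi-allelic records stay single
#' sites; positions are kept 1-based.
#'
#' @param path A VCF (plain or gzipped).
#' @param sample_map Optional named character vector mapping canonical sample
#'   names to the VCF's sample columns, e.g.
#'   `c(T21 = "sampleA", dP = "sampleB", ...)`. `NULL` keeps VCF names.
#' @return A [site_counts] with one record per VCF row.
#' @export
read_multisample_vcf <- function(path, sample_map = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  if (n == 0) stop("VCF contains no records: ", path)
  vcf_samples <- colnames(vcf@gt)[-1]
  if (is.null(sample_map)) {
    sample_map <- stats::setNames(vcf_samples, vcf_samples)
  }
  if (length(sample_map) != 4)
    stop("expected a mapping for exactly 4 samples, got ", length(sample_map))
  missing <- setdiff(unname(sample_map), vcf_samples)
  if (length(missing))
    stop("sample(s) not in VCF: ", paste(missing, collapse = ", "))
  samples <- names(sample_map)

  fmt <- vcf@gt[, "FORMAT"]
  if (!all(grepl("AD", fmt)))
    stop("record at ", fix[which(!grepl("AD", fmt))[1], "POS"],
         " lacks an AD field")
  ad <- vcfR::extract.gt(vcf, element = "AD")
  if (is.null(dim(ad))) ad <- matrix(ad, nrow = 1,
                                     dimnames = list(NULL, vcf_samples))
  has_dp <- all(grepl("DP", fmt))
  dp <- if (has_dp) {
    suppressWarnings(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
  } else NULL
  if (!is.null(dp) && is.null(dim(dp)))
    dp <- matrix(dp, nrow = 1, dimnames = list(NULL, vcf_samples))

  ref <- fix[, "REF"]
  alt_str <- fix[, "ALT"]
  alt <- lapply(alt_str, function(a)
    if (is.na(a) || a == ".") character(0) else strsplit(a, ",", fixed = TRUE)[[1]])
  variant_class <- vapply(seq_len(n), function(i) {
    al <- c(ref[i], alt[[i]])
    if (any(grepl("[<>*]", al)) || !all(grepl("^[ACGTNacgtn]+$", al)))
      "OTHER"
    else if (any(nchar(al) != 1)) "INDEL"
    else if (all(c(ref[i], alt[[i]]) %in% BASES)) "SNV"
    else "OTHER"
  }, character(1))

  counts <- array(0L, dim = c(n, 4L, 4L), dimnames = list(NULL, BASES, samples))
  depth <- matrix(0L, n, 4L, dimnames = list(NULL, samples))
  for (s in samples) {
    col <- sample_map[[s]]
    ad_s <- ad[, col]
    bad <- which(is.na(ad_s) | ad_s == ".")
    if (length(bad))
      stop("missing AD for sample ", col, " at ", fix[bad[1], "CHROM"], ":",
           fix[bad[1], "POS"])
    parts <- strsplit(ad_s, ",", fixed = TRUE)
    for (i in seq_len(n)) {
      alleles <- c(ref[i], alt[[i]])
      cts <- suppressWarnings(as.integer(parts[[i]]))
      if (length(cts) != length(alleles) || anyNA(cts))
        stop("malformed AD '", ad_s[i], "' for sample ", col, " at ",
             fix[i, "CHROM"], ":", fix[i, "POS"])
      keep <- nchar(alleles) == 1 & alleles %in% BASES
      if (any(keep)) {
        bi <- match(alleles[keep], BASES)
        counts[i, bi, s] <- counts[i, bi, s] + cts[keep]
      }
      depth[i, s] <- if (!is.null(dp) && !is.na(dp[i, col])) dp[i, col]
                     else sum(cts)
    }
  }
  new_site_counts(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                  ref = ref, alt = alt, variant_class = variant_class,
                  counts = counts, depth = depth, samples = samples)
}
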