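#' Per-site, per-sample base counts
#'
#' The container the filters and phasing core operate on. One record per
#' variant site, holding for each of the four samples the number of aligned
#' reads supporting each base, plus the caller-reported depth.
#'
#' @param chrom Chromosome name (length 1) or per-site vector.
#' @param pos 1-based positions.
#' @param ref Reference allele strings.
#' @param alt List of character vectors of alternate allele strings.
#' @param variant_class One of `"SNV"`, `"INDEL"`, `"OTHER"` per site.
#' @param counts Integer array `[site, base(A,C,G,T), sample]`.
#' @param depth Integer matrix `[site, sample]`; per-base counts may sum to
#'   less than depth (bases the caller did not report), never more.
#' @param samples Sample names (columns of `depth`, third margin of `counts`).
#' @param chrom_length Optional chromosome length attribute.
#' @return An object of class `site_counts`.
#' @export
new_site_counts <- function(chrom, pos, ref, alt, variant_class,
                            counts, depth, samples, chrom_length = NULL) {
  n <- length(pos)
  chrom <- rep_len(chrom, n)
  stopifnot(length(ref) == n, length(alt) == n, length(variant_class) == n,
            is.array(counts), all(dim(counts) == c(n, 4L, length(samples))),
            is.matrix(depth), all(dim(depth) == c(n, length(samples))))
  if (!all(variant_class %in% c("SNV", "INDEL", "OTHER")))
    stop("variant_class must be SNV, INDEL or OTHER")
  base_sum <- apply(counts, c(1, 3), sum)
  if (any(base_sum > depth + 1e-9))
    stop("per-base counts exceed reported depth at site index ",
         which(rowSums(base_sum > depth) > 0)[1])
  dimnames(counts) <- list(NULL, BASES, samples)
  colnames(depth) <- samples
  structure(list(chrom = chrom, pos = pos, ref = ref, alt = alt,
                 variant_class = variant_class, counts = counts,
                 depth = depth, samples = samples,
                 chrom_length = chrom_length),
            class = "site_counts")
}

#' @export
length.site_counts <- function(x) length(x$pos)

#' Subset a site_counts by site index
#' @param x A `site_counts`.
#' @param i Integer or logical site index.
#' @param ... Ignored.
#' @return The subsetted `site_counts`.
#' @export
`[.site_counts` <- function(x, i, ...) {
  new_site_counts(chrom = x$chrom[i], pos = x$pos[i], ref = x$ref[i],
                  alt = x$alt[i], variant_class = x$variant_class[i],
                  counts = x$counts[i, , , drop = FALSE],
                  depth = x$depth[i, , drop = FALSE],
                  samples = x$samples, chrom_length = x$chrom_length)
}

#' @export
print.site_counts <- function(x, ...) {
  cat("site_counts:", length(x), "sites,", length(x$samples), "samples (",
      paste(x$samples, collapse = ", "), ")\n")
  cat("  classes:", paste(names(table(x$variant_class)),
                          table(x$variant_class), collapse = ", "), "\n")
  cat("  mean depth:", round(mean(x$depth), 2), "\n")
  invisible(x)
}

#' Flatten a site_counts to a long data frame
#'
#' One row per site/sample with per-base count columns, convenient for
#' inspection and for the `filter` CLI subcommand's TSV output.
#'
#' @param x A `site_counts`.
#' @param ... Ignored.
#' @return A data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `variant_class`, `sample`, `depth`, `A`, `C`, `G`, `T`.
#' @export
as.data.frame.site_counts <- function(x, ...) {
  n <- length(x)
  do.call(rbind, lapply(x$samples, function(s) {
    data.frame(chrom = x$chrom, pos = x$pos, ref = x$ref,
               alt = vapply(x$alt, function(a)
                 if (length(a)) paste(a, collapse = ",") else ".", character(1)),
               variant_class = x$variant_class, sample = s,
               depth = x$depth[, s],
               matrix(x$counts[, , s], ncol = 4,
                      dimnames = list(NULL, BASES)),
               stringsAsFactors = FALSE)
  }))
}
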