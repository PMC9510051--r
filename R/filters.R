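#' Site-level depth and variant-class filters
#'
#' Reproduces the pre-phasing site selection: keep single-nucleotide variants
#' covered by at least `min_depth` reads in every sample; drop indels (and
#' other non-SNV records) regardless of depth. Both comparisons are
#' inclusive — a site at exactly `min_depth` in all samples is kept.
#'
#' @param sc A [site_counts].
#' @param min_depth Minimum per-sample read depth (default 10).
#' @return A list with `kept` (a [site_counts], input order preserved) and
#'   `dropped` (data frame `chrom`, `pos`, `reason` with machine-readable
#'   reasons `INDEL`, `NOT_SNV`, `LOW_DEPTH`).
#' @examples
#' ds <- simulate_dataset(sim_params(n_sites = 50, chrom_length = 1e5,
#'                                   depth_mean = 12, seed = 4))
#' f <- filter_sites(ds$counts)
#' table(f$dropped$reason)
#' @export
filter_sites <- function(sc, min_depth = 10) {
  stopifnot(inherits(sc, "site_counts"), min_depth >= 0)
  reason <- rep(NA_character_, length(sc))
  reason[sc$variant_class == "OTHER"] <- "NOT_SNV"
  reason[sc$variant_class == "INDEL"] <- "INDEL"
  low <- is.na(reason) & apply(sc$depth < min_depth, 1, any)
  reason[low] <- "LOW_DEPTH"
  drop <- !is.na(reason)
  list(kept = sc[!drop],
       dropped = data.frame(chrom = sc$chrom[drop], pos = sc$pos[drop],
                            reason = reason[drop], stringsAsFactors = FALSE))
}

#' Write the filter decision report as TSV
#'
#' @param filtered The list returned by [filter_sites()].
#' @param path Output TSV (`chrom`, `pos`, `decision`, `reason`).
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(filtered, path) {
  kept <- data.frame(chrom = filtered$kept$chrom, pos = filtered$kept$pos,
                     decision = "KEPT", reason = ".",
                     stringsAsFactors = FALSE)
  dropped <- data.frame(chrom = filtered$dropped$chrom,
                        pos = filtered$dropped$pos,
                        decision = "DROPPED", reason = filtered$dropped$reason,
                        stringsAsFactors = FALSE)
  out <- rbind(kept, dropped)
  out <- out[order(out$pos), ]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-sample base-allele-frequency thresholding
#'
#' For every site, computes the base allele frequency (BAF) of each base in
#' each sample — count over reported depth — and declares a base *present*
#' in a sample when its BAF reaches `tau_present` (inclusive, so exactly
#' 0.06 passes the default). The candidate alleles of a site are the bases
#' present in the trisomy sample; bases that never reach the threshold there
#' are treated as base-call error and excluded everywhere, even when a
#' disomy sample shows them (such sightings are tallied in the
#' `noncandidate_hits` diagnostic).
#'
#' @param sc A [site_counts], already depth-filtered so every sample has
#'   depth > 0 at every site.
#' @param tau_present Presence threshold on BAF (default 0.06).
#' @param trisomy Name of the trisomy sample (default `"T21"`).
#' @return A `base_profiles` object: positions, BAF array
#'   `[site, base, sample]`, logical candidate matrix `[site, base]`,
#'   logical presence array `[site, base, sample]`, and diagnostics.
#' @export
compute_base_sets <- function(sc, tau_present = 0.06, trisomy = "T21") {
  stopifnot(inherits(sc, "site_counts"),
            tau_present >= 0, tau_present <= 1)
  if (!trisomy %in% sc$samples)
    stop("trisomy sample '", trisomy, "' not among: ",
         paste(sc$samples, collapse = ", "))
  if (any(sc$depth == 0))
    stop("zero-depth sample at site index ",
         which(rowSums(sc$depth == 0) > 0)[1],
         "; run filter_sites() with min_depth >= 1 first")
  n <- length(sc)
  baf <- sweep(sc$counts, c(1, 3), sc$depth, "/")
  above <- baf >= tau_present
  candidates <- matrix(above[, , trisomy], n, 4,
                       dimnames = list(NULL, BASES))
  present <- above & as.vector(candidates)   # recycles over the sample margin
  dimnames(present) <- dimnames(baf)
  noncand <- rowSums(above & !as.vector(candidates), dims = 1)
  structure(list(chrom = sc$chrom, pos = sc$pos, ref = sc$ref,
                 samples = sc$samples, trisomy = trisomy,
                 tau_present = tau_present, baf = baf,
                 candidates = candidates, present = present,
                 noncandidate_hits = as.integer(noncand)),
            class = "base_profiles")
}

#' Build base profiles directly from per-sample base sets
#'
#' Constructor used for worked examples and property tests where only the
#' presence/absence pattern is known, not the underlying counts (BAF is left
#' `NA`). The candidate set is taken from the trisomy sample.
#'
#' @param pos 1-based positions (one per site).
#' @param sets A list (one element per site) of named lists mapping each
#'   sample name to a character vector of present bases.
#' @param trisomy Trisomy sample name.
#' @param chrom Chromosome label.
#' @param ref Optional reference bases (defaults to first candidate base).
#' @return A `base_profiles` object.
#' @export
base_profiles_from_sets <- function(pos, sets, trisomy = "T21",
                                    chrom = "chr21", ref = NULL) {
  n <- length(pos)
  stopifnot(length(sets) == n, n >= 1)
  samples <- names(sets[[1]])
  stopifnot(trisomy %in% samples)
  present <- array(FALSE, dim = c(n, 4L, length(samples)),
                   dimnames = list(NULL, BASES, samples))
  for (i in seq_len(n)) {
    stopifnot(setequal(names(sets[[i]]), samples))
    for (s in samples) {
      b <- sets[[i]][[s]]
      stopifnot(all(b %in% BASES))
      present[i, b, s] <- TRUE
    }
  }
  candidates <- matrix(present[, , trisomy], n, 4,
                       dimnames = list(NULL, BASES))
  present <- present & as.vector(candidates)
  if (is.null(ref))
    ref <- BASES[apply(candidates, 1, function(z) which(z)[1])]
  structure(list(chrom = rep_len(chrom, n), pos = pos, ref = ref,
                 samples = samples, trisomy = trisomy,
                 tau_present = NA_real_,
                 baf = array(NA_real_, dim = dim(present),
                             dimnames = dimnames(present)),
                 candidates = candidates, present = present,
                 noncandidate_hits = integer(n)),
            class = "base_profiles")
}

#' Extract one site's present-base sets as a named list
#'
#' @param profiles A `base_profiles`.
#' @param i Site index.
#' @return Named list mapping sample name to character vector of bases.
#' @export
present_sets <- function(profiles, i) {
  stopifnot(inherits(profiles, "base_profiles"))
  stats::setNames(
    lapply(profiles$samples, function(s) BASES[profiles$present[i, , s]]),
    profiles$samples)
}

#' @export
length.base_profiles <- function(x) length(x$pos)

#' Subset base profiles by site index
#' @param x A `base_profiles`.
#' @param i Integer or logical site index.
#' @param ... Ignored.
#' @return The subsetted `base_profiles`.
#' @export
`[.base_profiles` <- function(x, i, ...) {
  out <- x
  out$chrom <- x$chrom[i]
  out$pos <- x$pos[i]
  out$ref <- x$ref[i]
  out$baf <- x$baf[i, , , drop = FALSE]
  out$candidates <- x$candidates[i, , drop = FALSE]
  out$present <- x$present[i, , , drop = FALSE]
  out$noncandidate_hits <- x$noncandidate_hits[i]
  out
}

#' @export
print.base_profiles <- function(x, ...) {
  ncand <- rowSums(x$candidates)
  cat("base_profiles:", length(x), "sites; trisomy sample:", x$trisomy,
      "; tau =", x$tau_present, "\n")
  cat("  candidate-allele counts:",
      paste(names(table(ncand)), table(ncand), sep = "x", collapse = ", "),
      "\n")
  invisible(x)
}
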