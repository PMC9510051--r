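# Independent oracles and small generators shared across test files.
# Everything here is deliberately written as naive enumeration, separate
# from the package's own code paths.

# all functions from n_homologs slots to n_alleles symbols in which every
# symbol is used at least once, counted by explicit enumeration
brute_surjections <- function(n_alleles, n_homologs) {
  grids <- rep(list(seq_len(n_alleles)), n_homologs)
  g <- do.call(expand.grid, grids)
  sum(apply(g, 1, function(r) length(unique(r)) == n_alleles))
}

# consistent allele-to-homolog assignments by triple loop and sorted-set
# comparison; rows in lexicographic (P, M1, M2) order
brute_assignments <- function(present, design) {
  tri <- names(design)[lengths(design) == 3]
  cand <- sort(present[[tri]])
  rows <- list()
  for (p in cand) for (m1 in cand) for (m2 in cand) {
    a <- c(P = p, M1 = m1, M2 = m2)
    ok <- TRUE
    for (s in names(design)) {
      if (!identical(sort(unique(unname(a[design[[s]]]))),
                     sort(unique(present[[s]])))) { ok <- FALSE; break }
    }
    if (ok) rows[[length(rows) + 1]] <- a
  }
  if (!length(rows))
    return(data.frame(P = character(0), M1 = character(0), M2 = character(0)))
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# random per-sample present sets: candidates of size 1-3 drawn from ACGT,
# each disomy a random non-empty subset of the candidates
random_present <- function(design) {
  bases <- c("A", "C", "G", "T")
  cand <- sort(sample(bases, sample(1:3, 1)))
  pr <- list()
  for (s in names(design)) {
    pr[[s]] <- if (length(design[[s]]) == 3) cand
               else sort(sample(cand, sample(seq_along(cand), 1)))
  }
  pr
}

# hand-built bin_counts for run-detection edge cases
make_bins <- function(het, bin_size = 10000, sample = "dP") {
  structure(list(bin_size = bin_size,
                 bin_start = seq(1, by = bin_size, length.out = length(het)),
                 het = matrix(as.integer(het), ncol = 1,
                              dimnames = list(NULL, sample)),
                 samples = sample, chrom = "chr21"),
            class = "bin_counts")
}

# merge a phasing table with simulator truth by position
merge_truth <- function(ht, trio) {
  merge(ht$table,
        data.frame(pos = trio$pos, true_P = trio$P, true_M1 = trio$M1,
                   true_M2 = trio$M2, stringsAsFactors = FALSE),
        by = "pos")
}
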