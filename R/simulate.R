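#' Simulate ground-truth trio haplotypes
#'
#' Draws `n_sites` distinct positions uniformly without replacement from
#' `1:chrom_length`, assigns each a reference base and a configuration class
#' (see [config_classes()]), and fills in the alleles carried by the three
#' homologs P, M1 and M2. Alternate bases are drawn uniformly from the three
#' non-reference bases; tri-allelic sites permute reference plus two distinct
#' alternates over the homologs.
#'
#' @param params A [sim_params()] object.
#' @param seed Optional seed set before drawing; defaults to `params$seed`.
#'   Pass `NULL` to draw from the current RNG stream (used internally by
#'   [simulate_dataset()], which seeds once for the whole run).
#' @return A `trio_haplotypes` data frame with columns `pos`, `ref`, `P`,
#'   `M1`, `M2`, `class`, rows sorted by position, and attributes `chrom`
#'   and `chrom_length`.
#' @examples
#' trio <- simulate_haplotypes(sim_params(n_sites = 10, chrom_length = 1e5, seed = 7))
#' head(trio)
#' @export
simulate_haplotypes <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(seed)) set.seed(seed)
  n <- params$n_sites
  pos <- sort(sample.int(params$chrom_length, n))
  ref <- sample(BASES, n, replace = TRUE)
  cls <- sample(config_classes(), n, replace = TRUE,
                prob = params$config_weights)

  # OTHER[b, ] lists the three bases differing from BASES[b]
  other <- t(vapply(BASES, function(b) setdiff(BASES, b), character(3)))
  ref_i <- match(ref, BASES)
  a1 <- sample.int(3, n, replace = TRUE)          # first alternate
  r2 <- sample.int(2, n, replace = TRUE)          # second, distinct from first
  a2 <- r2 + (r2 >= a1)
  alt1 <- other[cbind(ref_i, a1)]
  alt2 <- other[cbind(ref_i, a2)]

  P <- ref; M1 <- ref; M2 <- ref
  P[cls == "P_private"]  <- alt1[cls == "P_private"]
  M1[cls == "M1_private"] <- alt1[cls == "M1_private"]
  M2[cls == "M2_private"] <- alt1[cls == "M2_private"]
  i <- cls == "PM1_shared"; P[i] <- alt1[i]; M1[i] <- alt1[i]
  i <- cls == "PM2_shared"; P[i] <- alt1[i]; M2[i] <- alt1[i]

  tri <- which(cls == "triallelic")
  if (length(tri)) {
    perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                   c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
    pick <- sample.int(6, length(tri), replace = TRUE)
    trip <- cbind(ref[tri], alt1[tri], alt2[tri])
    P[tri]  <- trip[cbind(seq_along(tri), perms[pick, 1])]
    M1[tri] <- trip[cbind(seq_along(tri), perms[pick, 2])]
    M2[tri] <- trip[cbind(seq_along(tri), perms[pick, 3])]
  }

  structure(
    data.frame(pos = pos, ref = ref, P = P, M1 = M1, M2 = M2, class = cls,
               stringsAsFactors = FALSE),
    chrom = params$chrom, chrom_length = params$chrom_length,
    class = c("trio_haplotypes", "data.frame"))
}

#' Overwrite M2 with M1 in alternating crossover segments
#'
#' Models the footprint of meiotic recombination between the two maternal
#' homologs: breakpoints split the chromosome into segments
#' `[1, b1), [b1, b2), ...`; in every odd-numbered segment (the first segment
#' after a breakpoint being segment 1) `M2` is overwritten by `M1`, creating
#' M1 == M2 identity there — hence homozygosity in the delta-P line. P is
#' never modified. An empty breakpoint list returns the trio unchanged.
#'
#' @param trio A `trio_haplotypes` object.
#' @param breakpoints Strictly increasing positions in `(1, chrom_length)`.
#' @return The modified `trio_haplotypes`.
#' @export
apply_recombination <- function(trio, breakpoints) {
  stopifnot(inherits(trio, "trio_haplotypes"))
  breakpoints <- as.numeric(breakpoints)
  if (!length(breakpoints)) return(trio)
  if (is.unsorted(breakpoints, strictly = TRUE))
    stop("breakpoints must be strictly increasing")
  len <- attr(trio, "chrom_length")
  if (any(breakpoints <= 1) || any(breakpoints >= len))
    stop("breakpoints must lie strictly inside (1, chrom_length)")
  seg <- findInterval(trio$pos, breakpoints)
  odd <- seg %% 2L == 1L
  trio$M2[odd] <- trio$M1[odd]
  trio
}

#' Simulate per-site read counts for the four cell-line designs
#'
#' For each site and sample, depth is Poisson with mean
#' `depth_mean * n_homologs / 2`: a sample sequenced to `depth_mean`-fold
#' genome-wide (diploid) coverage sees read depth on the target chromosome
#' proportional to its copy number, so a disomy site averages `depth_mean`
#' and a trisomy site 1.5x that, and the disomy/trisomy total-depth ratio is
#' 2/3 — the same signal the mapped-read-fraction statistic measures. Each
#' read's true base is drawn uniformly over the sample's homolog copies, so
#' heterozygous allele fractions are 1/3 or 2/3 in the trisomy and 1/2 in
#' the disomies. With probability `error_rate` a read reports a base drawn
#' uniformly from the other three. Per-base counts always sum to the
#' sample's depth.
#'
#' @param trio A `trio_haplotypes` object (truth).
#' @param design A [sample_design()].
#' @param params A [sim_params()] (supplies `depth_mean`, `error_rate`).
#' @param seed Optional seed set before drawing; `NULL` (default) draws from
#'   the current stream so [simulate_dataset()] stays on one stream.
#' @return A [site_counts] object.
#' @export
simulate_counts <- function(trio, design, params, seed = NULL) {
  stopifnot(inherits(trio, "trio_haplotypes"), inherits(design, "sample_design"),
            inherits(params, "sim_params"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(trio)
  samples <- names(design)
  counts <- array(0L, dim = c(n, 4L, 4L),
                  dimnames = list(NULL, BASES, samples))
  alleles <- as.matrix(trio[HOMOLOGS])

  for (s in samples) {
    hs <- design[[s]]
    k <- length(hs)
    depth <- stats::rpois(n, params$depth_mean * k / 2)
    # split depth uniformly over the k homolog copies
    copy <- matrix(0L, n, k)
    rem <- depth
    for (j in seq_len(k - 1)) {
      copy[, j] <- stats::rbinom(n, rem, 1 / (k - j + 1))
      rem <- rem - copy[, j]
    }
    copy[, k] <- rem
    cnt <- matrix(0L, n, 4L, dimnames = list(NULL, BASES))
    for (j in seq_len(k)) {
      bi <- match(alleles[, hs[j]], BASES)
      idx <- cbind(seq_len(n), bi)
      cnt[idx] <- cnt[idx] + copy[, j]
    }
    if (params$error_rate > 0) {
      for (b in 1:4) {
        e <- stats::rbinom(n, cnt[, b], params$error_rate)
        cnt[, b] <- cnt[, b] - e
        dest <- setdiff(1:4, b)
        d1 <- stats::rbinom(n, e, 1 / 3)
        d2 <- stats::rbinom(n, e - d1, 1 / 2)
        cnt[, dest[1]] <- cnt[, dest[1]] + d1
        cnt[, dest[2]] <- cnt[, dest[2]] + d2
        cnt[, dest[3]] <- cnt[, dest[3]] + (e - d1 - d2)
      }
    }
    counts[, , s] <- cnt
  }

  depth <- apply(counts, c(1, 3), sum)
  # ALT alleles: any non-reference base observed in any sample, plus true
  # non-reference alleles (kept even if unobserved, so truth sites survive)
  any_base <- apply(counts > 0, c(1, 2), any)
  alt <- lapply(seq_len(n), function(i) {
    tb <- union(BASES[any_base[i, ]],
                unique(alleles[i, ]))
    setdiff(intersect(BASES, tb), trio$ref[i])
  })
  new_site_counts(chrom = attr(trio, "chrom"), pos = trio$pos, ref = trio$ref,
                  alt = alt, variant_class = rep("SNV", n),
                  counts = counts, depth = depth, samples = samples,
                  chrom_length = attr(trio, "chrom_length"))
}

#' Run the whole simulator on a single RNG stream
#'
#' Seeds once from `params$seed`, then generates haplotypes, applies any
#' crossover breakpoints and simulates read counts. This is the reproducible
#' entry point the `simulate` CLI subcommand uses.
#'
#' @param params A [sim_params()].
#' @param design A [sample_design()]; defaults to the standard T21 / dP /
#'   dM1 / dM2 design over `params$sample_names`.
#' @return List with elements `trio` (post-recombination truth) and
#'   `counts` (a [site_counts]).
#' @examples
#' ds <- simulate_dataset(sim_params(n_sites = 50, chrom_length = 1e5, seed = 1))
#' ds$counts
#' @export
simulate_dataset <- function(params, design = default_design(params$sample_names)) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  trio <- simulate_haplotypes(params, seed = NULL)
  trio <- apply_recombination(trio, params$breakpoints)
  counts <- simulate_counts(trio, design, params, seed = NULL)
  list(trio = trio, counts = counts)
}

#' Write / read ground-truth haplotypes as TSV
#'
#' Columns: `chrom`, `pos` (1-based), `ref`, `allele_P`, `allele_M1`,
#' `allele_M2`, tab-separated with a header line.
#'
#' @param trio A `trio_haplotypes`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(trio, path) {
  stopifnot(inherits(trio, "trio_haplotypes"))
  out <- data.frame(chrom = attr(trio, "chrom"), pos = trio$pos,
                    ref = trio$ref, allele_P = trio$P,
                    allele_M1 = trio$M1, allele_M2 = trio$M2)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_tsv
#' @param chrom_length Chromosome length to attach (needed downstream by the
#'   binned scan); defaults to the maximum position.
#' @export
read_truth_tsv <- function(path, chrom_length = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "allele_P", "allele_M1", "allele_M2")
  if (!all(need %in% names(df)))
    stop("truth TSV must have columns: ", paste(need, collapse = ", "))
  structure(
    data.frame(pos = df$pos, ref = df$ref, P = df$allele_P,
               M1 = df$allele_M1, M2 = df$allele_M2,
               class = NA_character_, stringsAsFactors = FALSE),
    chrom = df$chrom[1],
    chrom_length = if (is.null(chrom_length)) max(df$pos) else chrom_length,
    class = c("trio_haplotypes", "data.frame"))
}
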