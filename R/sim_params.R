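#' Site configuration classes used by the simulator
#'
#' Each simulated site belongs to one configuration class describing which
#' homologs carry the alternate base:
#'
#' * `mono` — all three homologs carry the reference base.
#' * `P_private`, `M1_private`, `M2_private` — the named homolog alone
#'   carries an alternate base.
#' * `PM1_shared` ("M1 = P != M2") — P and M1 share an alternate base, M2
#'   keeps the reference; `PM2_shared` is the symmetric case.
#' * `triallelic` — reference plus two distinct alternate bases, permuted
#'   randomly over the three homologs.
#'
#' Only the unordered allele pattern matters downstream, so which allele is
#' labelled "reference" in each class is phasing-neutral.
#'
#' @return Character vector of class names.
#' @export
config_classes <- function() {
  c("mono", "P_private", "M1_private", "M2_private",
    "PM1_shared", "PM2_shared", "triallelic")
}

#' Default configuration-class weights
#'
#' The defaults make P-private heterozygous sites dominate, emulating a trio
#' in which the two maternal homologs are genetically much closer to each
#' other than either is to the paternal homolog — the structure expected when
#' M1 and M2 descend from one meiosis. Tri-allelic sites get a small weight
#' so the phasing core is exercised on three-candidate profiles.
#'
#' @return Named numeric vector over [config_classes()] summing to 1.
#' @export
default_config_weights <- function() {
  c(mono = 0.30, P_private = 0.40,
    M1_private = 0.07, M2_private = 0.07,
    PM1_shared = 0.07, PM2_shared = 0.07,
    triallelic = 0.02)
}

#' Simulation parameters
#'
#' Bundles and validates every knob of the synthetic-data generator.
#'
#' @param n_sites Positive integer; number of candidate SNP sites.
#' @param chrom_length Positive integer; chromosome length in bp (1-based
#'   coordinates). Must be at least `n_sites`.
#' @param depth_mean Positive real; expected reads per sample per site
#'   (Poisson mean). Default 30, matching ~30-fold whole-genome coverage.
#' @param error_rate Per-base substitution error probability in `[0, 1)`.
#' @param seed Integer RNG seed; required so fixtures are bit-reproducible.
#' @param config_weights Named probabilities over [config_classes()];
#'   must sum to 1 within 1e-9.
#' @param breakpoints Strictly increasing integer positions in
#'   `(1, chrom_length)` where an M1/M2 crossover is simulated
#'   (see [apply_recombination()]). Default none.
#' @param sample_names Labels for the four samples, in the order trisomy,
#'   delta-P, delta-M1, delta-M2. Defaults `T21, dP, dM1, dM2`.
#' @param chrom Chromosome name used in emitted tables/VCFs.
#'
#' @return An object of class `sim_params` (a validated list).
#' @examples
#' p <- sim_params(n_sites = 100, chrom_length = 1e6, seed = 1)
#' p$depth_mean
#' @export
sim_params <- function(n_sites, chrom_length, depth_mean = 30,
                       error_rate = 0, seed,
                       config_weights = default_config_weights(),
                       breakpoints = integer(0),
                       sample_names = c("T21", "dP", "dM1", "dM2"),
                       chrom = "chr21") {
  stopifnot(length(n_sites) == 1, n_sites >= 1, n_sites == floor(n_sites),
            length(chrom_length) == 1, chrom_length >= 1,
            length(depth_mean) == 1, depth_mean > 0,
            length(error_rate) == 1, error_rate >= 0, error_rate < 1,
            length(seed) == 1, is.finite(seed),
            length(sample_names) == 4, !anyDuplicated(sample_names),
            is.character(chrom), length(chrom) == 1)
  if (n_sites > chrom_length)
    stop("n_sites (", n_sites, ") exceeds chrom_length (", chrom_length, ")")
  cls <- config_classes()
  if (is.null(names(config_weights)) || !setequal(names(config_weights), cls))
    stop("config_weights must be named over: ", paste(cls, collapse = ", "))
  config_weights <- config_weights[cls]
  if (any(config_weights < 0) || abs(sum(config_weights) - 1) > 1e-9)
    stop("config_weights must be non-negative and sum to 1 (within 1e-9)")
  breakpoints <- as.numeric(breakpoints)
  if (length(breakpoints)) {
    if (is.unsorted(breakpoints, strictly = TRUE))
      stop("breakpoints must be strictly increasing")
    if (any(breakpoints <= 1) || any(breakpoints >= chrom_length))
      stop("breakpoints must lie strictly inside (1, chrom_length)")
  }
  structure(
    list(n_sites = as.integer(n_sites), chrom_length = chrom_length,
         depth_mean = depth_mean, error_rate = error_rate,
         seed = as.integer(seed), config_weights = config_weights,
         breakpoints = breakpoints, sample_names = sample_names,
         chrom = chrom),
    class = "sim_params")
}

#' Cell-line design: which homologs each sample carries
#'
#' The standard experiment has one trisomic sample carrying all of P, M1, M2
#' and three disomic deletion lines, each lacking exactly one homolog.
#'
#' @param sample_names Four sample labels in the order trisomy, delta-P,
#'   delta-M1, delta-M2.
#' @return A named list of class `sample_design` mapping each sample to the
#'   subset of `c("P", "M1", "M2")` it carries.
#' @examples
#' default_design()
#' @export
default_design <- function(sample_names = c("T21", "dP", "dM1", "dM2")) {
  stopifnot(length(sample_names) == 4, !anyDuplicated(sample_names))
  d <- list(c("P", "M1", "M2"), c("M1", "M2"), c("P", "M2"), c("P", "M1"))
  names(d) <- sample_names
  sample_design(d)
}

#' Construct and validate a sample design
#'
#' @param design Named list mapping sample name to the character subset of
#'   `c("P", "M1", "M2")` present in that sample. Exactly one sample must
#'   carry all three homologs and the other three must each carry two,
#'   together omitting every homolog exactly once.
#' @return The validated design, classed `sample_design`.
#' @export
sample_design <- function(design) {
  stopifnot(is.list(design), length(design) == 4,
            !is.null(names(design)), !anyDuplicated(names(design)))
  sizes <- lengths(design)
  ok_bases <- all(vapply(design, function(h) all(h %in% HOMOLOGS), logical(1)))
  if (!ok_bases || any(vapply(design, anyDuplicated, integer(1)) > 0))
    stop("design entries must be duplicate-free subsets of P, M1, M2")
  if (sum(sizes == 3) != 1 || sum(sizes == 2) != 3)
    stop("design needs one trisomic sample (3 homologs) and three disomic samples (2 homologs)")
  missing <- vapply(design[sizes == 2], function(h) setdiff(HOMOLOGS, h), character(1))
  if (!setequal(missing, HOMOLOGS))
    stop("the three disomic samples must omit each homolog exactly once")
  structure(design, class = "sample_design")
}

#' Name of the trisomic sample in a design
#' @param design A `sample_design`.
#' @return Sample name carrying all three homologs.
#' @export
trisomy_sample <- function(design) {
  names(design)[lengths(design) == 3]
}

#' Name of the sample lacking a given homolog
#' @param design A `sample_design`.
#' @param homolog One of `"P"`, `"M1"`, `"M2"`.
#' @return The deletion-line sample name.
#' @export
deletion_sample <- function(design, homolog) {
  stopifnot(homolog %in% HOMOLOGS)
  nm <- names(design)[vapply(design, function(h)
    length(h) == 2 && !(homolog %in% h), logical(1))]
  nm
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Simulation parameters:", x$n_sites, "sites on", x$chrom,
      paste0("(", format(x$chrom_length, big.mark = ","), " bp)\n"))
  cat("  depth_mean =", x$depth_mean, " error_rate =", x$error_rate,
      " seed =", x$seed, "\n")
  cat("  class weights:", paste(names(x$config_weights),
                                format(x$config_weights), collapse = ", "), "\n")
  if (length(x$breakpoints))
    cat("  crossover breakpoints:", paste(x$breakpoints, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.sample_design <- function(x, ...) {
  for (s in names(x))
    cat(sprintf("  %-6s -> {%s}\n", s, paste(x[[s]], collapse = ", ")))
  invisible(x)
}
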