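#' Exhaustively enumerate consistent allele-to-homolog assignments
#'
#' The oracle behind the subtraction logic. Every assignment of a candidate
#' base to each of P, M1 and M2 (`|candidates|^3` in total) is checked
#' against the observed presence pattern: an assignment is consistent iff,
#' for every sample, the set of bases carried by that sample's homologs
#' equals the sample's present-base set.
#'
#' @param present Named list mapping each sample to its character vector of
#'   present bases (one site); the trisomy sample's set is the candidate set.
#' @param design A [sample_design()].
#' @return Data frame with columns `P`, `M1`, `M2`, one row per consistent
#'   assignment, in lexicographic order (may have zero rows).
#' @examples
#' d <- default_design()
#' enumerate_assignments(list(T21 = c("A", "G"), dP = "G",
#'                            dM1 = c("A", "G"), dM2 = c("A", "G")), d)
#' @export
enumerate_assignments <- function(present, design) {
  stopifnot(inherits(design, "sample_design"),
            setequal(names(present), names(design)))
  cand <- sort(present[[trisomy_sample(design)]])
  if (!length(cand)) stop("candidate allele set is empty")
  grid <- expand.grid(M2 = cand, M1 = cand, P = cand,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("P", "M1", "M2"), drop = FALSE]
  ok <- vapply(seq_len(nrow(grid)), function(r) {
    a <- c(P = grid$P[r], M1 = grid$M1[r], M2 = grid$M2[r])
    all(vapply(names(design), function(s)
      setequal(unique(a[design[[s]]]), present[[s]]), logical(1)))
  }, logical(1))
  rownames(grid) <- NULL
  grid[ok, , drop = FALSE]
}

#' Phase one site by elimination subtraction
#'
#' Constructive path: a candidate base absent from exactly one deletion line
#' but present in the other two disomies is assigned to the homolog that
#' line lacks; homologs still unassigned take the base shared by every
#' sample carrying them. The result is then cross-checked against
#' [enumerate_assignments()]; the oracle always wins on disagreement, and
#' the status is set from the number of consistent assignments:
#'
#' * `PHASED` — exactly one consistent assignment over >= 2 candidates;
#' * `UNINFORMATIVE_HOMOZYGOUS` — a single candidate base, carried by all
#'   three homologs;
#' * `AMBIGUOUS` — two or more consistent assignments (homologs on which
#'   all of them agree are still reported);
#' * `CONFLICT` — no consistent assignment explains the pattern;
#' * `FILTERED` — a sample has an empty present set (no usable signal).
#'
#' @param present Named list of per-sample present-base sets (one site), as
#'   returned by [present_sets()].
#' @param design A [sample_design()].
#' @param pos Optional position carried through to the result.
#' @return A `phase_result` list: `pos`, `assignment` (named `P`, `M1`,
#'   `M2`; `NA` = unassigned), `status`, `n_consistent`, `notes`.
#' @export
phase_site <- function(present, design, pos = NA_integer_) {
  stopifnot(inherits(design, "sample_design"))
  tri <- trisomy_sample(design)
  cand <- present[[tri]]
  empty <- !vapply(present[names(design)], length, integer(1))
  unassigned <- c(P = NA_character_, M1 = NA_character_, M2 = NA_character_)
  if (any(empty)) {
    return(new_phase_result(pos, unassigned, "FILTERED", 0L,
                            paste("no present bases in:",
                                  paste(names(design)[empty], collapse = ","))))
  }

  enum <- enumerate_assignments(present, design)
  n_con <- nrow(enum)
  notes <- character(0)

  if (length(cand) == 1) {
    assignment <- c(P = cand, M1 = cand, M2 = cand)
    status <- if (n_con == 1) "UNINFORMATIVE_HOMOZYGOUS" else "CONFLICT"
    if (status == "CONFLICT") assignment <- unassigned
    return(new_phase_result(pos, assignment, status, n_con,
                            paste(notes, collapse = "; ")))
  }

  # constructive subtraction path
  constructive <- unassigned
  for (h in HOMOLOGS) {
    dh <- deletion_sample(design, h)
    others <- setdiff(names(design)[lengths(design) == 2], dh)
    specific <- setdiff(cand, present[[dh]])
    specific <- specific[specific %in% present[[others[1]]] &
                           specific %in% present[[others[2]]]]
    if (length(specific) == 1) constructive[h] <- specific
  }
  todo <- is.na(constructive)
  if (any(todo) && !all(todo)) {
    for (h in HOMOLOGS[todo]) {
      carriers <- names(design)[vapply(design, function(z) h %in% z, logical(1))]
      shared <- Reduce(intersect, present[carriers])
      if (length(shared) == 1) constructive[h] <- shared
    }
  }

  if (n_con == 1) {
    assignment <- c(P = enum$P[1], M1 = enum$M1[1], M2 = enum$M2[1])
    status <- "PHASED"
    if (!all(is.na(constructive)) &&
        !identical(constructive[!is.na(constructive)],
                   assignment[!is.na(constructive)]))
      notes <- c(notes, "constructive path disagreed with enumeration; oracle result kept")
  } else if (n_con >= 2) {
    status <- "AMBIGUOUS"
    assignment <- unassigned
    for (h in HOMOLOGS)                      # report homologs all solutions agree on
      if (length(unique(enum[[h]])) == 1) assignment[h] <- enum[[h]][1]
  } else {
    status <- "CONFLICT"
    assignment <- unassigned
  }
  new_phase_result(pos, assignment, status, n_con, paste(notes, collapse = "; "))
}

new_phase_result <- function(pos, assignment, status, n_consistent, notes = "") {
  stopifnot(status %in% PHASE_STATUSES)
  structure(list(pos = pos, assignment = assignment, status = status,
                 n_consistent = as.integer(n_consistent), notes = notes),
            class = "phase_result")
}

#' @export
print.phase_result <- function(x, ...) {
  a <- ifelse(is.na(x$assignment), ".", x$assignment)
  cat(sprintf("pos %s: %s  P=%s M1=%s M2=%s  (n_consistent=%d)%s\n",
              format(x$pos), x$status, a["P"], a["M1"], a["M2"],
              x$n_consistent,
              if (nzchar(x$notes)) paste0("  [", x$notes, "]") else ""))
  invisible(x)
}

#' Phase every site of a base-profile set
#'
#' Applies [phase_site()] to each site. Sites sharing the same
#' presence/absence pattern are phased once and the result re-used, which
#' makes chromosome-scale runs fast. Haplotype strings for P, M1 and M2 are
#' assembled from `PHASED` sites in positional order (homozygous sites are
#' reported in the table but excluded from the strings, matching the
#' convention that the phased set is the informative heterozygous sites).
#'
#' @param profiles A `base_profiles` (sites sorted by position).
#' @param design A [sample_design()].
#' @return A `haplotype_table`: `table` (per-site data frame with `chrom`,
#'   `pos`, `ref`, `status`, `base_P`, `base_M1`, `base_M2`,
#'   `n_consistent`, `notes`), `summary` (named counts per status),
#'   `haplotypes` (list of strings `P`, `M1`, `M2`), `phased_pos`.
#' @examples
#' sets <- list(list(T21 = c("A", "G"), dP = "G",
#'                   dM1 = c("A", "G"), dM2 = c("A", "G")))
#' ht <- phase_all(base_profiles_from_sets(100, sets), default_design())
#' ht$table
#' @export
phase_all <- function(profiles, design) {
  stopifnot(inherits(profiles, "base_profiles"),
            inherits(design, "sample_design"),
            setequal(profiles$samples, names(design)))
  if (is.unsorted(profiles$pos))
    stop("profiles must be sorted by position")
  n <- length(profiles)
  out <- data.frame(chrom = profiles$chrom, pos = profiles$pos,
                    ref = profiles$ref, status = rep(NA_character_, n),
                    base_P = rep(NA_character_, n),
                    base_M1 = rep(NA_character_, n),
                    base_M2 = rep(NA_character_, n),
                    n_consistent = rep(NA_integer_, n),
                    notes = rep("", n), stringsAsFactors = FALSE)
  if (n > 0) {
    # encode each sample's 4-base presence pattern as a nibble; sites with an
    # identical key across samples phase identically
    key <- rep("", n)
    for (s in profiles$samples) {
      code <- as.integer(profiles$present[, 1, s]) +
        2L * profiles$present[, 2, s] + 4L * profiles$present[, 3, s] +
        8L * profiles$present[, 4, s]
      key <- paste(key, code, sep = ":")
    }
    uk <- unique(key)
    first <- match(uk, key)
    res <- lapply(first, function(i)
      phase_site(present_sets(profiles, i), design))
    idx <- match(key, uk)
    out$status <- vapply(res, `[[`, character(1), "status")[idx]
    out$base_P <- vapply(res, function(r) r$assignment[["P"]], character(1))[idx]
    out$base_M1 <- vapply(res, function(r) r$assignment[["M1"]], character(1))[idx]
    out$base_M2 <- vapply(res, function(r) r$assignment[["M2"]], character(1))[idx]
    out$n_consistent <- vapply(res, `[[`, integer(1), "n_consistent")[idx]
    out$notes <- vapply(res, `[[`, character(1), "notes")[idx]
  }
  summary <- stats::setNames(integer(length(PHASE_STATUSES)), PHASE_STATUSES)
  tab <- table(factor(out$status, levels = PHASE_STATUSES))
  summary[names(tab)] <- as.integer(tab)
  ph <- out$status == "PHASED"
  structure(list(
    table = out,
    summary = summary,
    haplotypes = list(P = paste(out$base_P[ph], collapse = ""),
                      M1 = paste(out$base_M1[ph], collapse = ""),
                      M2 = paste(out$base_M2[ph], collapse = "")),
    phased_pos = out$pos[ph],
    design = design), class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("haplotype_table:", nrow(x$table), "sites\n")
  for (s in names(x$summary))
    if (x$summary[s] > 0) cat(sprintf("  %-26s %d\n", s, x$summary[s]))
  np <- length(x$phased_pos)
  if (np > 0 && np <= 60)
    cat("  P :", x$haplotypes$P, "\n  M1:", x$haplotypes$M1,
        "\n  M2:", x$haplotypes$M2, "\n")
  else if (np > 0)
    cat("  phased haplotype strings of length", np, "\n")
  invisible(x)
}

#' Write per-site phasing results as TSV
#'
#' Columns `chrom`, `pos`, `ref`, `status`, `base_P`, `base_M1`, `base_M2`,
#' `n_consistent`; unassigned bases are written as `.`.
#'
#' @param ht A `haplotype_table`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_haplotype_tsv <- function(ht, path) {
  stopifnot(inherits(ht, "haplotype_table"))
  out <- ht$table[c("chrom", "pos", "ref", "status",
                    "base_P", "base_M1", "base_M2", "n_consistent")]
  for (cc in c("base_P", "base_M1", "base_M2"))
    out[[cc]][is.na(out[[cc]])] <- "."
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write phased sites as a triploid phased VCF
#'
#' Emits one record per `PHASED` site with a single trisomy-sample column
#' whose genotype is the phased triploid `GT` in homolog order `P|M1|M2`
#' (e.g. `0|1|1`); the header documents the convention. Gzip-compressed by
#' \pkg{vcfR}.
#'
#' @param ht A `haplotype_table`.
#' @param path Output path (`.vcf.gz`).
#' @param sample Column name for the trisomy genotype (default `"T21"`).
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(ht, path, sample = "T21") {
  stopifnot(inherits(ht, "haplotype_table"))
  tb <- ht$table[ht$table$status == "PHASED", , drop = FALSE]
  if (!nrow(tb)) stop("no PHASED sites to write")
  alleles <- lapply(seq_len(nrow(tb)), function(i) {
    a <- c(tb$base_P[i], tb$base_M1[i], tb$base_M2[i])
    c(tb$ref[i], sort(setdiff(unique(a), tb$ref[i])))
  })
  gt <- vapply(seq_len(nrow(tb)), function(i) {
    a <- c(tb$base_P[i], tb$base_M1[i], tb$base_M2[i])
    paste(match(a, alleles[[i]]) - 1L, collapse = "|")
  }, character(1))
  fix <- cbind(CHROM = tb$chrom, POS = as.character(tb$pos), ID = ".",
               REF = tb$ref,
               ALT = vapply(alleles, function(a)
                 if (length(a) > 1) paste(a[-1], collapse = ",") else ".",
                 character(1)),
               QUAL = ".", FILTER = "PASS", INFO = ".")
  gtm <- cbind(FORMAT = rep("GT", nrow(tb)),
               matrix(gt, ncol = 1, dimnames = list(NULL, sample)))
  meta <- c("##fileformat=VCFv4.2",
            "##source=triphase",
            "##phasing=full; triploid GT ordered P|M1|M2 (paternal, maternal-1, maternal-2)",
            '##FORMAT=<ID=GT,Number=1,Type=String,Description="Phased triploid genotype, homolog order P|M1|M2">')
  vcf <- methods::new("vcfR", meta = meta, fix = fix, gt = gtm)
  vcfR::write.vcf(vcf, file = path)
  invisible(path)
}

#' Size of the phase-ambiguity space
#'
#' At one heterozygous site, the number of ways to place `n_alleles` distinct
#' observed alleles on `n_homologs` labelled homologs so that every allele
#' appears at least once is the surjection count
#' \deqn{S = \sum_{i=0}^{a} (-1)^i \binom{a}{i} (a - i)^h,}
#' by inclusion–exclusion. Independent sites multiply, so the ambiguity
#' space for `n_sites` such sites is `S^n_sites`: 6 per biallelic site on
#' three homologs, 216 for three sites, 279,936 for seven.
#'
#' @param n_sites Positive integer number of heterozygous sites.
#' @param n_alleles Distinct alleles per site (default 2).
#' @param n_homologs Labelled homologs (default 3).
#' @return The number of joint assignments (0 when
#'   `n_alleles > n_homologs`).
#' @examples
#' theoretical_combinations(3)   # 216
#' theoretical_combinations(7)   # 279936
#' @export
theoretical_combinations <- function(n_sites, n_alleles = 2, n_homologs = 3) {
  stopifnot(length(n_sites) == 1, n_sites >= 1, n_sites == floor(n_sites),
            n_alleles >= 1, n_homologs >= 1)
  a <- n_alleles
  i <- 0:a
  per_site <- sum((-1)^i * choose(a, i) * (a - i)^n_homologs)
  if (per_site <= 0) return(0)
  per_site^n_sites
}
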