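design <- default_design()

test_that("enumerate_assignments resolves the two published worked examples", {
  # rs74753297: A/G heterozygous everywhere except the delta-P line
  one <- enumerate_assignments(list(T21 = c("A", "G"), dP = "G",
                                    dM1 = c("A", "G"), dM2 = c("A", "G")),
                               design)
  expect_equal(one, data.frame(P = "A", M1 = "G", M2 = "G"),
               ignore_attr = TRUE)
  # rs78248586: C/T heterozygous except the delta-M2 line
  two <- enumerate_assignments(list(T21 = c("C", "T"), dP = c("C", "T"),
                                    dM1 = c("C", "T"), dM2 = "C"),
                               design)
  expect_equal(two, data.frame(P = "C", M1 = "C", M2 = "T"),
               ignore_attr = TRUE)
  # two bases cannot keep all three two-homolog subsets heterozygous
  none <- enumerate_assignments(list(T21 = c("A", "G"), dP = c("A", "G"),
                                     dM1 = c("A", "G"), dM2 = c("A", "G")),
                                design)
  expect_equal(nrow(none), 0)
})

test_that("enumerate_assignments agrees with a naive brute-force enumerator", {
  set.seed(42)
  for (i in 1:300) {
    pr <- random_present(design)
    expect_equal(enumerate_assignments(pr, design), brute_assignments(pr, design),
                 ignore_attr = TRUE)
  }
})

test_that("phase_site classifies the canonical patterns", {
  r <- phase_site(list(T21 = c("A", "G"), dP = "G", dM1 = c("A", "G"),
                       dM2 = c("A", "G")), design, pos = 9830857)
  expect_equal(r$status, "PHASED")
  expect_equal(r$assignment, c(P = "A", M1 = "G", M2 = "G"))
  expect_equal(r$n_consistent, 1L)

  hom <- phase_site(list(T21 = "T", dP = "T", dM1 = "T", dM2 = "T"), design)
  expect_equal(hom$status, "UNINFORMATIVE_HOMOZYGOUS")
  expect_equal(unname(hom$assignment), rep("T", 3))

  con <- phase_site(list(T21 = c("A", "G"), dP = c("A", "G"),
                         dM1 = c("A", "G"), dM2 = c("A", "G")), design)
  expect_equal(con$status, "CONFLICT")
  expect_equal(con$n_consistent, 0L)
  expect_true(all(is.na(con$assignment)))

  filt <- phase_site(list(T21 = c("A", "G"), dP = character(0),
                          dM1 = "A", dM2 = "G"), design)
  expect_equal(filt$status, "FILTERED")
})

test_that("a tri-allelic site phases uniquely when each disomy shows two bases", {
  r <- phase_site(list(T21 = c("A", "C", "G"), dP = c("A", "C"),
                       dM1 = c("A", "G"), dM2 = c("C", "G")), design)
  expect_equal(r$status, "PHASED")
  expect_equal(r$assignment, c(P = "G", M1 = "C", M2 = "A"))
})

test_that("the standard three-deletion design never leaves an ambiguous site", {
  # exhaustive: every candidate set of 2 or 3 bases, every combination of
  # non-empty disomy subsets; the three pairwise constraints always pin the
  # assignment down to at most one solution
  subsets <- function(x) {
    unlist(lapply(seq_along(x), function(k)
      combn(x, k, simplify = FALSE)), recursive = FALSE)
  }
  for (cand in list(c("A", "G"), c("C", "T"), c("A", "C", "G"))) {
    ss <- subsets(cand)
    for (s1 in ss) for (s2 in ss) for (s3 in ss) {
      pr <- list(T21 = cand, dP = s1, dM1 = s2, dM2 = s3)
      expect_lte(nrow(enumerate_assignments(pr, design)), 1)
    }
  }
})

test_that("phasing is equivariant under consistent base relabelling", {
  set.seed(7)
  perm_bases <- function(x, map) unname(map[x])
  for (i in 1:100) {
    pr <- random_present(design)
    map <- setNames(sample(c("A", "C", "G", "T")), c("A", "C", "G", "T"))
    pr2 <- lapply(pr, perm_bases, map = map)
    r1 <- phase_site(pr, design)
    r2 <- phase_site(pr2, design)
    expect_equal(r2$status, r1$status)
    expect_equal(r2$n_consistent, r1$n_consistent)
    if (r1$status == "PHASED")
      expect_equal(r2$assignment, map[r1$assignment], ignore_attr = TRUE)
  }
})

test_that("phase_all reconstructs the seven validated SNP haplotype strings", {
  prof <- seven_snp_profiles()
  ht <- phase_all(prof, design)
  expect_equal(unname(ht$summary["PHASED"]), 7L)
  expect_equal(ht$haplotypes, list(P = "ACCTGAC", M1 = "GCTCAGC",
                                   M2 = "GTCTAGT"))
  expect_equal(ht$table$pos, prof$pos)
})

test_that("phase_all handles empty input and rejects unsorted positions", {
  prof <- seven_snp_profiles()
  empty <- phase_all(prof[integer(0)], design)
  expect_equal(nrow(empty$table), 0)
  expect_true(all(empty$summary == 0))
  expect_equal(empty$haplotypes$P, "")

  shuffled <- prof[c(3, 1, 2, 4, 5, 6, 7)]
  expect_error(phase_all(shuffled, design), "sorted")
})

test_that("phase_all on an error-free simulation recovers the full truth", {
  p <- sim_params(n_sites = 3000, chrom_length = 1e6, seed = 13,
                  error_rate = 0)
  ds <- simulate_dataset(p)
  prof <- compute_base_sets(filter_sites(ds$counts)$kept)
  ht <- phase_all(prof, design)
  m <- merge_truth(ht, ds$trio)
  het <- !(m$true_P == m$true_M1 & m$true_M1 == m$true_M2)
  expect_true(all(m$status[het] == "PHASED"))
  expect_true(all(m$status[!het] == "UNINFORMATIVE_HOMOZYGOUS"))
  ph <- m$status == "PHASED"
  expect_true(all(m$base_P[ph] == m$true_P[ph] &
                    m$base_M1[ph] == m$true_M1[ph] &
                    m$base_M2[ph] == m$true_M2[ph]))
  expect_equal(sum(ht$summary), length(prof))
})

test_that("sequencing error degrades statuses but never flips a phased assignment", {
  p0 <- sim_params(n_sites = 3000, chrom_length = 1e6, seed = 17,
                   error_rate = 0)
  p1 <- sim_params(n_sites = 3000, chrom_length = 1e6, seed = 17,
                   error_rate = 0.01)
  clean <- simulate_dataset(p0)
  noisy <- simulate_dataset(p1)
  ht0 <- phase_all(compute_base_sets(filter_sites(clean$counts)$kept), design)
  ht1 <- phase_all(compute_base_sets(filter_sites(noisy$counts)$kept), design)
  m <- merge(ht1$table, ht0$table, by = "pos", suffixes = c("_noisy", "_clean"))
  both <- m$status_noisy == "PHASED" & m$status_clean == "PHASED"
  expect_true(all(m$base_P_noisy[both] == m$base_P_clean[both] &
                    m$base_M1_noisy[both] == m$base_M1_clean[both] &
                    m$base_M2_noisy[both] == m$base_M2_clean[both]))
})

test_that("theoretical_combinations matches brute-force surjection counting", {
  # per-site count for two alleles on three homologs, by explicit enumeration
  expect_equal(theoretical_combinations(1), brute_surjections(2, 3))
  expect_equal(theoretical_combinations(1), 6)
  for (n in 1:10)
    expect_equal(theoretical_combinations(n), 6^n)
  expect_equal(theoretical_combinations(2, n_alleles = 3),
               brute_surjections(3, 3)^2)
  expect_equal(theoretical_combinations(5, n_alleles = 4, n_homologs = 3), 0)
  expect_error(theoretical_combinations(0))
})

test_that("haplotype TSV and phased VCF writers emit consistent records", {
  ht <- phase_all(seven_snp_profiles(), design)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_haplotype_tsv(ht, tsv)
  df <- read.delim(tsv)
  expect_equal(nrow(df), 7)
  expect_equal(df$base_P, strsplit("ACCTGAC", "")[[1]])

  vcf <- withr::local_tempfile(fileext = ".vcf.gz")
  write_phased_vcf(ht, vcf)
  lines <- readLines(gzfile(vcf))
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), 7)
  gt <- vapply(strsplit(body, "\t"), `[`, character(1), 10)
  expect_true(all(grepl("^[0-9]\\|[0-9]\\|[0-9]$", gt)))
  # first record: P=A M1=G M2=G with ref A -> 0|1|1
  expect_equal(gt[1], "0|1|1")
})
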