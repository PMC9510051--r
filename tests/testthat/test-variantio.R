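write_test_vcf <- function(lines) {
  path <- withr::local_tempfile(fileext = ".vcf", .local_envir = parent.frame())
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "T21", "dP", "dM1", "dM2", sep = "\t"))
  writeLines(c(header, lines), path)
  path
}

rec <- function(pos, ref, alt, ...) {
  paste("chr21", pos, ".", ref, alt, ".", "PASS", ".", "GT:AD:DP", ...,
        sep = "\t")
}

test_that("read_multisample_vcf maps AD/DP fields and variant classes", {
  path <- write_test_vcf(c(
    rec(100, "A", "G", "./.:10,10:20", "0/0:20,0:20", "./.:10,10:20",
        "./.:9,11:20"),
    rec(200, "A", "AT", "./.:30,5:35", "./.:30,5:35", "./.:30,5:35",
        "./.:30,5:35"),
    rec(300, "C", "G,T", "./.:10,4,6:20", "./.:10,0,10:20",
        "./.:10,4,6:20", "./.:14,6,0:20")))
  sc <- read_multisample_vcf(path)
  expect_s3_class(sc, "site_counts")
  expect_equal(length(sc), 3)
  expect_equal(sc$pos, c(100L, 200L, 300L))
  expect_equal(sc$variant_class, c("SNV", "INDEL", "SNV"))
  expect_equal(sc$counts[1, "A", "T21"], 10L)
  expect_equal(sc$counts[1, "G", "dM2"], 11L)
  expect_equal(unname(sc$depth[1, ]), rep(20L, 4))
  # multi-allelic record stays one site with three counted bases
  expect_equal(sc$counts[3, c("C", "G", "T"), "T21"], c(C = 10L, G = 4L, T = 6L))
  # indel alleles contribute no base counts but the site keeps its depth
  expect_equal(sum(sc$counts[2, , "T21"]), 30L)
  expect_equal(unname(sc$depth[2, "T21"]), 35L)
})

test_that("read_multisample_vcf falls back to summed AD without DP and rejects bad input", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "T21", "dP", "dM1", "dM2", sep = "\t"),
    paste("chr21", 50, ".", "A", "G", ".", "PASS", ".", "AD",
          "12,8", "20,0", "11,9", "10,10", sep = "\t")), path)
  sc <- read_multisample_vcf(path)
  expect_equal(unname(sc$depth[1, ]), rep(20L, 4))

  bad <- write_test_vcf(rec(100, "A", "G", "./.:.:20", "./.:20,0:20",
                            "./.:10,10:20", "./.:9,11:20"))
  expect_error(read_multisample_vcf(bad), "missing AD")
  good <- write_test_vcf(rec(100, "A", "G", "./.:10,10:20", "./.:20,0:20",
                             "./.:10,10:20", "./.:9,11:20"))
  expect_error(read_multisample_vcf(good, sample_map = c(T21 = "nope",
                                                         dP = "dP",
                                                         dM1 = "dM1",
                                                         dM2 = "dM2")),
               "not in VCF")
})

test_that("a simulated dataset round-trips through VCF exactly", {
  p <- sim_params(n_sites = 150, chrom_length = 5e4, seed = 21,
                  error_rate = 0.01)
  ds <- simulate_dataset(p)
  path <- withr::local_tempfile(fileext = ".vcf.gz")
  write_sample_vcf(ds$counts, path)
  back <- read_multisample_vcf(path)
  expect_identical(back$pos, ds$counts$pos)
  expect_identical(back$ref, ds$counts$ref)
  expect_equal(back$counts, ds$counts$counts, ignore_attr = FALSE)
  expect_true(all(back$depth == ds$counts$depth))
  expect_identical(back$variant_class, ds$counts$variant_class)
})

test_that("filter_sites applies inclusive depth and indel rules and partitions the input", {
  path <- write_test_vcf(c(
    rec(100, "A", "G", "./.:20,10:30", "./.:5,4:9", "./.:20,10:30",
        "./.:20,10:30"),                                   # dP depth 9 -> drop
    rec(150, "A", "G", "./.:5,5:10", "./.:10,0:10", "./.:5,5:10",
        "./.:5,5:10"),                                     # boundary 10 -> keep
    rec(200, "A", "AT", "./.:60,40:100", "./.:60,40:100", "./.:60,40:100",
        "./.:60,40:100"),                                  # indel -> drop
    rec(250, "C", "T", "./.:15,15:30", "./.:30,0:30", "./.:15,15:30",
        "./.:15,15:30")))
  sc <- read_multisample_vcf(path)
  f <- filter_sites(sc, min_depth = 10)
  expect_equal(f$kept$pos, c(150L, 250L))
  expect_equal(f$dropped$pos, c(100L, 200L))
  expect_equal(f$dropped$reason, c("LOW_DEPTH", "INDEL"))
  expect_equal(length(f$kept) + nrow(f$dropped), length(sc))

  # raising min_depth never increases the kept set
  kept_sizes <- vapply(c(0, 5, 10, 20, 40),
                       function(d) length(filter_sites(sc, d)$kept), integer(1))
  expect_true(all(diff(kept_sizes) <= 0))

  report <- withr::local_tempfile(fileext = ".tsv")
  write_filter_report(f, report)
  rep_df <- read.delim(report)
  expect_equal(nrow(rep_df), length(sc))
  expect_equal(sum(rep_df$decision == "KEPT"), 2)
})

test_that("compute_base_sets reproduces the published presence pattern and threshold behaviour", {
  path <- write_test_vcf(c(
    rec(9830857, "G", "A", "./.:20,10:30", "./.:30,0:30", "./.:15,15:30",
        "./.:14,16:30")))
  prof <- compute_base_sets(filter_sites(read_multisample_vcf(path))$kept)
  expect_equal(colnames(prof$candidates)[prof$candidates[1, ]], c("A", "G"))
  expect_equal(present_sets(prof, 1),
               list(T21 = c("A", "G"), dP = "G", dM1 = c("A", "G"),
                    dM2 = c("A", "G")))

  # 1/30 = 0.033 < 0.06 is error; 2/30 = 0.067 >= 0.06 is a candidate
  low <- write_test_vcf(c(
    rec(10, "A", "G", "./.:29,1:30", "./.:30,0:30", "./.:30,0:30",
        "./.:30,0:30"),
    rec(20, "A", "G", "./.:28,2:30", "./.:30,0:30", "./.:30,0:30",
        "./.:30,0:30")))
  prof <- compute_base_sets(read_multisample_vcf(low))
  expect_equal(present_sets(prof, 1)$T21, "A")
  expect_equal(present_sets(prof, 2)$T21, c("A", "G"))

  # raising tau never enlarges a present set
  sizes <- vapply(c(0.02, 0.06, 0.2, 0.5), function(tau) {
    pr <- compute_base_sets(read_multisample_vcf(low), tau_present = tau)
    sum(pr$present)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("compute_base_sets refuses unfiltered zero-depth sites", {
  path <- write_test_vcf(rec(5, "A", "G", "./.:10,10:20", "./.:0,0:0",
                             "./.:10,10:20", "./.:10,10:20"))
  sc <- read_multisample_vcf(path)
  expect_error(compute_base_sets(sc), "zero-depth")
})
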