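Package: triphase
Title: Haplotype Phasing of Trisomic Chromosomes by Elimination Subtraction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Phases the three homologs of a trisomic chromosome (paternal P and
    the two maternal copies M1 and M2 of chromosome 21) by comparing multi-sample
    whole-genome sequencing base counts between the trisomic line and three
    corrected disomy lines, each of which lacks exactly one homolog. A base
    present in the trisomy but absent from exactly one single-deletion line is
    assigned to the homolog that line lacks; an exhaustive enumeration oracle
    classifies every other base-set pattern. Includes depth and base-allele-
    frequency site filters, a read-count simulator that emulates the four
    cell-line designs, binned heterozygous-SNP density with homozygous-run
    detection for recombination screening, and small helpers for read-fraction,
    elimination-efficiency and MLPA aneuploidy-call statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
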