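Package: btiscan
Title: Pool-Seq Genome Scans, Neutrality Tests and Bioassay Analysis for
    Bti-Resistance Genetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis toolkit for dissecting the genetics of resistance to
    the bio-insecticide Bacillus thuringiensis subsp. israelensis (Bti) in
    mosquitoes. Implements pooled-sequencing SNP filtering, read-count based
    pairwise Fst with Fisher exact tests and Storey q-values, empirical
    Fst-tail outlier detection, sequence diversity summaries with Tajima's D
    and Fu and Li's D* and F* neutrality tests, a backward-in-time
    Wright-Fisher coalescent simulator with per-generation size changes and
    introgression for demography-corrected significance, log-probit
    dose-response analysis (Abbott correction, Fieller fiducial limits,
    resistance ratios), PCA-corrected association mapping with min-p
    permutation adjustment, and pooled-versus-individual genotyping
    concordance reports. Ships simulators that generate every input the
    pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    jsonlite
Config/testthat/edition: 3
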