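#!/usr/bin/env Rscript
# Pooled-versus-individual validation: apply the array QC filters to the
# genotype panel, then test the concordance between allele frequencies
# estimated from pooled read counts and from individual genotypes for the
# SNPs the two data sets share. Pooled counts for the shared SNPs are drawn
# from the panel's population-1 frequencies, mimicking an array designed from
# the pooled discovery set.

suppressPackageStartupMessages(library(btiscan))
set.seed(103)

gm <- read_genotype_table("results/data/panel_genotypes.tsv",
                          "results/data/panel_qc.tsv")
keep <- qc_filter(gm$qc)
message(sprintf("QC filter: %d of %d SNPs kept (GC50 > 0.35, GenTrain > 0.50, CR > 0.50)",
                sum(keep), length(keep)))
gm_qc <- genotype_matrix(gm$geno[, gm$qc$snp[keep], drop = FALSE],
                         pop = gm$pop, phenotype = gm$phenotype,
                         qc = gm$qc[keep, ])

# pooled read counts for the kept SNPs: deep pool sequencing of population 1
p1 <- gm_qc$geno[gm_qc$pop == "pop1", , drop = FALSE]
freq1 <- colSums(p1, na.rm = TRUE) / (2 * colSums(!is.na(p1)))
coverage <- 600L
pooled <- data.frame(snp = colnames(gm_qc$geno), minor = "G", major = "A",
                     count = rbinom(ncol(gm_qc$geno), coverage, freq1),
                     coverage = coverage, stringsAsFactors = FALSE)

gm_pop1 <- genotype_matrix(p1, pop = rep("pop1", nrow(p1)), qc = gm_qc$qc)
rep <- concordance_report(pooled, gm_pop1, max_missing = 0.10)
print(rep)
write.table(rep$per_snp, "results/concordance_per_snp.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

summ <- validation_summary(
  n_arrayed = length(keep),
  n_genotyped = sum(keep),
  n_monomorphic = sum(apply(gm_qc$geno, 2, function(g)
    var(g, na.rm = TRUE) == 0)),
  n_transferred = sum(keep),
  n_poly_panel = sum(apply(gm_qc$geno, 2, function(g)
    sum(g > 0, na.rm = TRUE) >= 2)))
str(summ)
write.table(as.data.frame(summ), "results/validation_summary.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
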