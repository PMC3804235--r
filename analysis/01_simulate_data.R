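#!/usr/bin/env Rscript
# Generate every input the downstream analyses consume: a two-strain pooled
# sequencing experiment, candidate-gene haplotype alignments for a susceptible
# and a selected strain, a six-population genotype panel with population-level
# resistance phenotypes, and dose-mortality bioassays for those populations.
# All files land under results/data/.

suppressPackageStartupMessages(library(btiscan))
set.seed(20130831)
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

## Pooled experiment: 1520 SNPs, ~1% under selection in the resistant line
pool <- simulate_pooled_experiment(pool_sim_spec(seed = 101))
write_sync(pool$sync, "results/data/pools.sync")
write.table(pool$truth, "results/data/pools_truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("pooled experiment: %d SNPs, %d under selection",
                nrow(pool$truth), sum(pool$truth$selected)))

## Candidate-gene alignments: neutral haplotypes for the susceptible strain
## (constant size) and the selected strain (bottleneck + introgression
## history); 22 haplotypes each, theta chosen at the scale seen for these loci
for (gene in c("geneA", "geneB", "geneC")) {
  theta <- c(geneA = 4, geneB = 1.5, geneC = 6)[[gene]]
  sus <- simulate_neutral_sample(constant_scenario(ne = 6000, sample_size = 22),
                                 theta = theta,
                                 seed = 200 + match(gene, c("geneA", "geneB", "geneC")))
  res <- simulate_neutral_sample(litox_scenario(sample_size = 22),
                                 theta = theta,
                                 seed = 300 + match(gene, c("geneA", "geneB", "geneC")))
  write_fasta_alignment(sus, sprintf("results/data/%s_susceptible.fa", gene))
  write_fasta_alignment(res, sprintf("results/data/%s_resistant.fa", gene))
}
message("candidate-gene alignments written for 3 loci x 2 strains")

## Genotype panel: six populations x 30 individuals, 324 SNPs, 3 causal loci
panel <- simulate_genotype_panel(panel_sim_spec(missing_rate = 0.03,
                                                seed = 401))
write_genotype_table(panel$gm, "results/data/panel_genotypes.tsv",
                     qc_path = "results/data/panel_qc.tsv")
writeLines(panel$truth$causal, "results/data/panel_causal_snps.txt")
message(sprintf("genotype panel: %d individuals x %d SNPs, causal: %s",
                nrow(panel$gm$geno), ncol(panel$gm$geno),
                paste(panel$truth$causal, collapse = ", ")))

## Bioassays: a susceptible reference plus six populations whose true LC50
## tracks the panel's population phenotype scale
lc50_true <- c(reference = 1.00, pop1 = 1.40, pop2 = 1.88, pop3 = 1.88,
               pop4 = 2.27, pop5 = 1.03, pop6 = 0.85)
assays <- do.call(rbind, lapply(names(lc50_true), function(p) {
  simulate_bioassay(lc50 = lc50_true[[p]], slope = 3.5,
                    doses = 10^seq(-0.6, 0.9, length.out = 6),
                    n_per_dose = 25, replicates = 4, control_mortality = 0.02,
                    population = p, seed = 500 + match(p, names(lc50_true)))
}))
write.csv(assays, "results/data/bioassays.csv", row.names = FALSE)
write.csv(data.frame(population = names(lc50_true), lc50_true = lc50_true),
          "results/data/bioassays_truth.csv", row.names = FALSE)
message(sprintf("bioassays: %d rows over %d populations",
                nrow(assays), length(lc50_true)))
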