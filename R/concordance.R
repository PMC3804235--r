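# Validation of pooled allele-frequency estimates against individual
# genotyping: array QC filters, Pearson concordance, per-SNP Fisher tests
# with Bonferroni correction, and the integer-count validation summary.

#' Array QC filter for genotyped SNPs
#'
#' Keeps SNPs with `GC50 > 0.35`, `GenTrain > 0.50` and call rate
#' `CR > 0.50` (all strict inequalities).
#'
#' @param qc data.frame with columns `snp`, `GC50`, `GenTrain`, `CR` in
#'   `[0, 1]`.
#' @return logical vector (named by SNP) of SNPs kept.
#' @export
qc_filter <- function(qc) {
  need <- c("snp", "GC50", "GenTrain", "CR")
  stopifnot(all(need %in% names(qc)))
  sc <- as.matrix(qc[, c("GC50", "GenTrain", "CR")])
  if (any(sc < 0 | sc > 1)) stop("QC scores must lie in [0, 1]")
  keep <- qc$GC50 > 0.35 & qc$GenTrain > 0.50 & qc$CR > 0.50
  names(keep) <- qc$snp
  keep
}

#' Allele frequency from individual genotypes
#'
#' Counted-allele frequency: sum of dosages over twice the number of
#' non-missing individuals.
#'
#' @param gm a `genotype_matrix`.
#' @param snp SNP index/name, or missing for all SNPs.
#' @return frequency (vector over SNPs when `snp` is missing).
#' @export
individual_allele_freq <- function(gm, snp) {
  stopifnot(inherits(gm, "genotype_matrix"))
  G <- if (missing(snp)) gm$geno else gm$geno[, snp, drop = FALSE]
  nn <- colSums(!is.na(G))
  if (any(nn == 0L)) stop("SNP with all genotypes missing")
  out <- colSums(G, na.rm = TRUE) / (2 * nn)
  if (!missing(snp) && length(out) == 1L) out <- unname(out)
  out
}

#' Validation summary percentages from integer counts
#'
#' Recomputes the arithmetic summary of a pooled-SNP validation experiment:
#' array genotyping success, laboratory validation (SNPs polymorphic in at
#' least one laboratory strain among those genotyped), transferability to a
#' second panel, polymorphism in that panel, and overall validation (SNPs
#' polymorphic in the laboratory or recovered as polymorphic in the panel).
#' Percentages are reported to one decimal.
#'
#' @param n_arrayed SNPs placed on the array.
#' @param n_genotyped SNPs successfully genotyped.
#' @param n_monomorphic genotyped SNPs monomorphic in both laboratory
#'   strains.
#' @param n_transferred SNPs successfully genotyped in the second panel.
#' @param n_poly_panel transferred SNPs polymorphic in the second panel.
#' @param n_mono_recovered laboratory-monomorphic SNPs polymorphic in the
#'   panel.
#' @return named list of counts and percentages.
#' @export
validation_summary <- function(n_arrayed, n_genotyped, n_monomorphic,
                               n_transferred = NA, n_poly_panel = NA,
                               n_mono_recovered = 0) {
  pct <- function(x, d) round(100 * x / d, 1)
  list(n_arrayed = n_arrayed,
       n_genotyped = n_genotyped,
       n_monomorphic = n_monomorphic,
       pct_genotyped = pct(n_genotyped, n_arrayed),
       pct_validated_lab = pct(n_genotyped - n_monomorphic, n_genotyped),
       pct_transferred = pct(n_transferred, n_arrayed),
       pct_polymorphic_panel = pct(n_poly_panel, n_transferred),
       pct_validated_overall = pct(n_genotyped -
                                     (n_monomorphic - n_mono_recovered),
                                   n_genotyped))
}

#' Concordance of pooled and individual allele frequencies
#'
#' Restricts to matched SNPs with a missing-data fraction below `max_missing`
#' in the individual data, re-orients individual dosages to the pooled minor
#' allele when the counted allele is recorded in the QC table, and reports the
#' Pearson correlation between the two frequency vectors plus, per SNP, a
#' two-sided Fisher exact test of pooled read counts against individual
#' allele counts (2N), Bonferroni-adjusted by the number of SNPs tested.
#'
#' @param pooled data.frame with `snp`, `minor`, `major`, `count` (minor
#'   reads), `coverage` columns (e.g. derived from [scan_pools()] output).
#' @param gm a `genotype_matrix`; if its QC table has an `allele` column, it
#'   names the allele counted by each SNP's dosage.
#' @param max_missing missing-fraction ceiling (default 0.10).
#' @return list of class `concordance_report`: `r` (with test), per-SNP
#'   table, and counts.
#' @export
concordance_report <- function(pooled, gm, max_missing = 0.10) {
  stopifnot(inherits(gm, "genotype_matrix"),
            all(c("snp", "count", "coverage") %in% names(pooled)))
  common <- intersect(pooled$snp, colnames(gm$geno))
  if (length(common) == 0L) stop("no overlapping SNPs between data sets")
  pooled <- pooled[match(common, pooled$snp), , drop = FALSE]
  G <- gm$geno[, common, drop = FALSE]
  miss <- colMeans(is.na(G))
  keep <- miss < max_missing
  if (!any(keep)) stop("no SNPs below the missing-data ceiling")
  pooled <- pooled[keep, , drop = FALSE]
  G <- G[, keep, drop = FALSE]
  # harmonise orientation: dosage of the pooled minor allele
  if (!is.null(gm$qc) && "allele" %in% names(gm$qc) && "minor" %in% names(pooled)) {
    counted <- gm$qc$allele[match(colnames(G), gm$qc$snp)]
    flip <- which(!is.na(counted) & counted != pooled$minor)
    G[, flip] <- 2L - G[, flip]
  }
  nn <- colSums(!is.na(G))
  freq_ind <- colSums(G, na.rm = TRUE) / (2 * nn)
  freq_pool <- pooled$count / pooled$coverage
  m <- length(freq_ind)
  ct <- if (m >= 3) stats::cor.test(freq_pool, freq_ind)
        else list(estimate = NA_real_, p.value = NA_real_)
  fisher_p <- vapply(seq_len(m), function(j) {
    dos <- sum(G[, j], na.rm = TRUE)
    tab <- matrix(c(pooled$count[j], pooled$coverage[j] - pooled$count[j],
                    dos, 2 * nn[j] - dos), nrow = 2L)
    stats::fisher.test(tab)$p.value
  }, numeric(1))
  per_snp <- data.frame(snp = colnames(G), freq_pooled = freq_pool,
                        freq_individual = unname(freq_ind),
                        missing = unname(miss[keep]),
                        fisher_p = fisher_p,
                        fisher_p_bonf = pmin(1, m * fisher_p),
                        stringsAsFactors = FALSE)
  structure(list(r = unname(ct$estimate), r_p = ct$p.value,
                 n_tested = m, per_snp = per_snp,
                 n_discordant = sum(per_snp$fisher_p_bonf < 0.05)),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("concordance over %d SNPs: Pearson r = %.3f (P = %.3g); %d SNP(s) discordant after Bonferroni\n",
              x$n_tested, x$r, x$r_p, x$n_discordant))
  invisible(x)
}
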