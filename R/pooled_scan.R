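# Pooled genome scan: SNP calling filters on read counts, heterozygosity-based
# pairwise Fst with finite-coverage correction, per-SNP Fisher exact tests,
# Storey q-values and the empirical Fst-tail outlier rule.

#' Minor-allele frequency from pooled read counts
#'
#' @param minor_count reads carrying the minor allele.
#' @param coverage total reads at the site.
#' @return `minor_count / coverage`.
#' @export
pool_allele_freq <- function(minor_count, coverage) {
  if (any(coverage <= 0)) stop("coverage must be positive")
  if (any(minor_count < 0) || any(minor_count > coverage))
    stop("minor_count must lie in [0, coverage]")
  minor_count / coverage
}

#' Call biallelic SNPs from pooled counts
#'
#' Applies the pooled SNP-calling filters: a site is retained when it is
#' biallelic (ignoring `N` and deletion slots), total read coverage is at
#' least `min_coverage` in *each* pool, the minor allele is supported by at
#' least `min_supporting_reads` reads summed over both pools, and the overall
#' minor-allele frequency (both pools combined) is at least `min_maf`. Sites
#' where more than two alleles carry reads are dropped.
#'
#' @param sync a `sync` object with exactly two pools.
#' @param cfg a [run_config()].
#' @return data.frame with one row per retained SNP: `chrom`, `pos`, `ref`,
#'   `major`, `minor`, per-pool minor counts/coverages (`count1`, `cov1`,
#'   `count2`, `cov2`) and frequencies (`freq1`, `freq2`); `fst`, `fisher_p`,
#'   `qvalue`, `outlier` initialised to `NA`.
#' @export
filter_sites <- function(sync, cfg = run_config()) {
  stopifnot(inherits(sync, "sync"))
  n_pools <- dim(sync$counts)[2]
  if (n_pools == 0L) stop("sync object has zero pools")
  if (n_pools != 2L) stop("the scan requires exactly two pools, got ", n_pools)
  acgt <- sync$counts[, , 1:4, drop = FALSE]  # N and del excluded
  n <- dim(acgt)[1]
  pool1 <- matrix(acgt[, 1, ], nrow = n)
  pool2 <- matrix(acgt[, 2, ], nrow = n)
  tot <- pool1 + pool2                        # site x 4 pooled counts
  n_alleles <- rowSums(tot > 0L)
  ord <- t(apply(tot, 1L, order, decreasing = TRUE))
  maj_idx <- ord[, 1]
  min_idx <- ord[, 2]
  i_maj <- cbind(seq_len(n), maj_idx)
  i_min <- cbind(seq_len(n), min_idx)
  cov1 <- pool1[i_maj] + pool1[i_min]
  cov2 <- pool2[i_maj] + pool2[i_min]
  count1 <- pool1[i_min]
  count2 <- pool2[i_min]
  minor_total <- tot[i_min]
  overall_maf <- ifelse(cov1 + cov2 > 0, minor_total / (cov1 + cov2), 0)
  keep <- n_alleles == 2L &
    cov1 >= cfg$min_coverage & cov2 >= cfg$min_coverage &
    minor_total >= cfg$min_supporting_reads &
    overall_maf >= cfg$min_maf
  alleles <- c("A", "T", "C", "G")
  out <- data.frame(chrom = sync$sites$chrom[keep],
                    pos = sync$sites$pos[keep],
                    ref = sync$sites$ref[keep],
                    major = alleles[maj_idx[keep]],
                    minor = alleles[min_idx[keep]],
                    count1 = count1[keep], cov1 = cov1[keep],
                    count2 = count2[keep], cov2 = cov2[keep],
                    stringsAsFactors = FALSE)
  out$freq1 <- ifelse(out$cov1 > 0, out$count1 / out$cov1, NA_real_)
  out$freq2 <- ifelse(out$cov2 > 0, out$count2 / out$cov2, NA_real_)
  nr <- nrow(out)
  out$fst <- rep(NA_real_, nr)
  out$fisher_p <- rep(NA_real_, nr)
  out$qvalue <- rep(NA_real_, nr)
  out$outlier <- rep(NA, nr)
  out
}

#' Pairwise Fst from pooled read counts
#'
#' Classical heterozygosity-based estimator with a finite-coverage correction,
#' computed per SNP from the two pools' minor-allele read counts:
#' `pi_pool = 2 p (1-p) c/(c-1)` with `c` the pool's coverage,
#' `pi_S` the mean of the two pool values, and
#' `pi_T = 2 pbar (1-pbar) C/(C-1)` on the pooled counts (`C` the summed
#' coverage). `Fst = (pi_T - pi_S)/pi_T`, clamped to `[0, 1]`, and 0 when
#' `pi_T = 0`. An uncorrected variant (no `c/(c-1)` factors) is available for
#' sensitivity checks.
#'
#' @param count1,cov1 minor-allele reads and coverage in pool 1 (vectorised).
#' @param count2,cov2 same for pool 2.
#' @param corrected apply the finite-coverage correction (default `TRUE`).
#' @return numeric vector of Fst values in `[0, 1]`.
#' @export
pairwise_fst <- function(count1, cov1, count2, cov2, corrected = TRUE) {
  if (any(cov1 < 2) || any(cov2 < 2))
    stop("coverage must be >= 2 in each pool to estimate Fst")
  if (any(count1 < 0) || any(count2 < 0) ||
      any(count1 > cov1) || any(count2 > cov2))
    stop("minor counts must lie in [0, coverage]")
  p1 <- count1 / cov1
  p2 <- count2 / cov2
  cc <- function(c) if (corrected) c / (c - 1) else rep(1, length(c))
  pi1 <- 2 * p1 * (1 - p1) * cc(cov1)
  pi2 <- 2 * p2 * (1 - p2) * cc(cov2)
  pi_s <- (pi1 + pi2) / 2
  C <- cov1 + cov2
  pbar <- (count1 + count2) / C
  pi_t <- 2 * pbar * (1 - pbar) * cc(C)
  fst <- ifelse(pi_t > 0, (pi_t - pi_s) / pi_t, 0)
  pmin(pmax(fst, 0), 1)
}

#' Two-sided Fisher exact test on a site's read counts
#'
#' Tests the 2x2 table (minor/major allele x pool 1/pool 2) of read counts;
#' the two-sided p-value sums hypergeometric probabilities no larger than that
#' of the observed table.
#'
#' @param count1,cov1,count2,cov2 per-pool minor counts and coverages
#'   (vectorised).
#' @return numeric vector of p-values in `(0, 1]`.
#' @export
fisher_exact_site <- function(count1, cov1, count2, cov2) {
  if (any(c(count1, count2) < 0) || any(count1 > cov1) || any(count2 > cov2))
    stop("counts must be non-negative and no larger than coverage")
  p <- mapply(function(a, c1, b, c2) {
    m <- matrix(c(a, c1 - a, b, c2 - b), nrow = 2L)
    stats::fisher.test(m)$p.value
  }, count1, cov1, count2, cov2)
  pmin(p, 1)  # exact-test summation can exceed 1 by a rounding hair
}

#' Storey q-values with a single-lambda pi0 estimate
#'
#' Implements the q-value transform `q_i = pi0 * min_{t >= p_i} m t / #{p <= t}`
#' with the null proportion estimated at a single lambda:
#' `pi0 = #{p > lambda} / ((1 - lambda) m)`, capped at 1. With `pi0 = 1`
#' (`pi0_method = "one"`) the result equals Benjamini-Hochberg adjusted
#' p-values.
#'
#' @param p p-values in `[0, 1]`.
#' @param lambda tuning point for the pi0 estimate (default 0.5).
#' @param pi0_method `"single"` (default, single-lambda estimate) or `"one"`
#'   (force `pi0 = 1`, the BH reduction).
#' @return q-values in input order.
#' @export
storey_qvalues <- function(p, lambda = 0.5, pi0_method = c("single", "one")) {
  if (any(p < 0 | p > 1, na.rm = TRUE) || anyNA(p))
    stop("p-values must lie in [0, 1]")
  pi0_method <- match.arg(pi0_method)
  m <- length(p)
  pi0 <- if (pi0_method == "one") 1 else
    min(1, sum(p > lambda) / ((1 - lambda) * m))
  if (pi0 <= 0) pi0 <- 1 / m  # degenerate: every p below lambda
  o <- order(p, decreasing = TRUE)
  q <- pi0 * pmin(1, cummin(m * p[o] / rank(p, ties.method = "max")[o]))
  q[o] <- q
  pmin(q, 1)
}

#' Flag empirical Fst-tail outliers
#'
#' A SNP is an outlier when its Fst is at or above the empirical
#' `1 - fst_tail_fraction` quantile of all retained SNP Fst values (linear
#' interpolation; ties at the threshold included) *and* its q-value is below
#' `q_max`. The quantile threshold used is attached as attribute
#' `fst_threshold`.
#'
#' @param snps SNP data.frame with `fst` and `qvalue` populated.
#' @param cfg a [run_config()].
#' @return `snps` with `outlier` set; attribute `fst_threshold` holds the
#'   empirical tail threshold.
#' @export
detect_outliers <- function(snps, cfg = run_config()) {
  if (nrow(snps) == 0L) stop("no SNPs to classify")
  if (anyNA(snps$fst) || anyNA(snps$qvalue))
    stop("fst and qvalue must be populated before outlier detection")
  thr <- stats::quantile(snps$fst, probs = 1 - cfg$fst_tail_fraction,
                         names = FALSE, type = 7)
  in_tail <- snps$fst >= thr
  # Degenerate distribution: if every SNP ties at the threshold the "tail"
  # is the whole distribution, which is no tail at all.
  if (all(in_tail)) in_tail <- snps$fst > thr
  snps$outlier <- in_tail & snps$qvalue < cfg$q_max
  attr(snps, "fst_threshold") <- thr
  snps
}

#' Run the full pooled genome scan
#'
#' Chains [filter_sites()], [pairwise_fst()], [fisher_exact_site()],
#' [storey_qvalues()] and [detect_outliers()].
#'
#' @param sync a two-pool `sync` object.
#' @param cfg a [run_config()].
#' @param corrected passed to [pairwise_fst()].
#' @return the annotated SNP data.frame (see [filter_sites()]), with attribute
#'   `fst_threshold`.
#' @export
scan_pools <- function(sync, cfg = run_config(), corrected = TRUE) {
  snps <- filter_sites(sync, cfg)
  if (nrow(snps) == 0L) stop("no SNPs passed the filters")
  snps$fst <- pairwise_fst(snps$count1, snps$cov1, snps$count2, snps$cov2,
                           corrected = corrected)
  snps$fisher_p <- fisher_exact_site(snps$count1, snps$cov1,
                                     snps$count2, snps$cov2)
  snps$qvalue <- storey_qvalues(snps$fisher_p)
  detect_outliers(snps, cfg)
}
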