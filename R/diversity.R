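# Sequence diversity summaries and neutrality tests for candidate-gene
# haplotype alignments. Sites containing N or a gap in any haplotype are
# list-wise deleted before any statistic is computed; per-site quantities are
# scaled by the number of valid sites.

valid_columns <- function(aln) {
  stopifnot(inherits(aln, "hap_alignment"))
  if (aln$L == 0L) return(logical(0))
  apply(aln$seq, 2L, function(col) all(col %in% c("A", "C", "G", "T")))
}

# Per-site allele tallies on the valid columns only.
site_tables <- function(aln) {
  ok <- valid_columns(aln)
  m <- aln$seq[, ok, drop = FALSE]
  list(m = m, tables = lapply(seq_len(ncol(m)), function(j) table(m[, j])))
}

harmonic <- function(k) if (k < 1L) 0 else sum(1 / seq_len(k))
harmonic2 <- function(k) if (k < 1L) 0 else sum(1 / seq_len(k)^2)

pairwise_diff_total <- function(m) {
  n <- nrow(m)
  if (n < 2L || ncol(m) == 0L) return(0)
  tot <- 0
  for (j in seq_len(ncol(m))) {
    cnt <- table(m[, j])
    tot <- tot + (choose(n, 2) - sum(choose(cnt, 2)))
  }
  tot
}

#' Diversity summaries for a haplotype alignment
#'
#' Computes the classical within-strain summaries: segregating sites `S`,
#' total mutations `eta` (a site with k states contributes k-1), singleton
#' mutations `eta_s` (states carried by exactly one haplotype), mean pairwise
#' differences `K_within`, per-site nucleotide diversity `pi`, haplotype
#' diversity `Hd = n/(n-1) (1 - sum f_h^2)`, and Watterson's
#' `theta_w = S / a_n` (per locus, `a_n = sum_{i<n} 1/i`). When a second
#' alignment is supplied, `K_between` is the mean number of differences over
#' all cross-strain pairs, computed on sites valid in both alignments.
#'
#' @param aln a `hap_alignment` with `n >= 2`.
#' @param other optional second `hap_alignment` of the same locus (same
#'   alignment length).
#' @return list of class `diversity_stats`.
#' @export
diversity_stats <- function(aln, other = NULL) {
  if (aln$n < 2L) stop("at least 2 haplotypes required")
  st <- site_tables(aln)
  m <- st$m
  L_valid <- ncol(m)
  n <- aln$n
  S <- 0L; eta <- 0L; eta_s <- 0L
  for (tab in st$tables) {
    k <- length(tab)
    if (k > 1L) {
      S <- S + 1L
      eta <- eta + (k - 1L)
      eta_s <- eta_s + min(sum(tab == 1L), k - 1L)
    }
  }
  K_within <- pairwise_diff_total(m) / choose(n, 2)
  pi <- if (L_valid > 0L) K_within / L_valid else 0
  haps <- apply(m, 1L, paste, collapse = "")
  fh <- table(haps) / n
  Hd <- n / (n - 1) * (1 - sum(fh^2))
  theta_w <- S / harmonic(n - 1L)
  K_between <- NA_real_
  if (!is.null(other)) {
    if (other$L != aln$L)
      stop("between-strain comparison needs alignments of equal length")
    ok <- valid_columns(aln) & valid_columns(other)
    m1 <- aln$seq[, ok, drop = FALSE]
    m2 <- other$seq[, ok, drop = FALSE]
    diffs <- 0
    for (i in seq_len(nrow(m1)))
      for (j in seq_len(nrow(m2)))
        diffs <- diffs + sum(m1[i, ] != m2[j, ])
    K_between <- diffs / (nrow(m1) * nrow(m2))
  }
  structure(list(n = n, L_valid = L_valid, S = S, eta = eta, eta_s = eta_s,
                 K_within = K_within, pi = pi, Hd = Hd, theta_w = theta_w,
                 K_between = K_between),
            class = "diversity_stats")
}

#' @export
print.diversity_stats <- function(x, ...) {
  cat(sprintf("n=%d  L=%d  S=%d  eta=%d  eta_s=%d  K=%.4f  pi=%.5f  Hd=%.4f  thetaW=%.4f\n",
              x$n, x$L_valid, x$S, x$eta, x$eta_s, x$K_within, x$pi, x$Hd,
              x$theta_w))
  invisible(x)
}

# Tajima (1989) variance constants.
tajima_constants <- function(n) {
  a1 <- harmonic(n - 1L)
  a2 <- harmonic2(n - 1L)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

# Fu & Li (1993) starred-test variance constants, in the corrected form used
# by the standard reference implementations (Simonsen et al. 1995 erratum).
fu_li_star_constants <- function(n) {
  an <- harmonic(n - 1L)
  bn <- harmonic2(n - 1L)
  an1 <- an + 1 / n
  cn <- 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (1.5 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vD <- ((n / (n - 1))^2 * bn + an^2 * dn -
           2 * (n * an * (an + 1)) / (n - 1)^2) / (an^2 + bn)
  uD <- (n / (n - 1)) * (an - n / (n - 1)) - vD
  vF <- (dn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) -
           (2 / (n - 1)) * (4 * bn - 6 + 8 / n)) / (an^2 + bn)
  uF <- (n / (n - 1) + (n + 1) / (3 * (n - 1)) - 4 / (n * (n - 1)) +
           2 * (n + 1) / (n - 1)^2 * (an1 - 2 * n / (n + 1))) / an - vF
  list(an = an, bn = bn, uD = uD, vD = vD, uF = uF, vF = vF)
}

stats_or_compute <- function(aln, stats) {
  if (is.null(stats)) diversity_stats(aln) else stats
}

#' Tajima's D
#'
#' `D = (K - S/a1) / sqrt(e1 S + e2 S (S-1))` contrasting mean pairwise
#' differences with the Watterson estimate; negative values indicate an
#' excess of rare variants, positive values an excess of intermediate-
#' frequency variants.
#'
#' @param aln a `hap_alignment` with `n >= 4` and at least one segregating
#'   site.
#' @param stats optional precomputed [diversity_stats()].
#' @return the statistic (scalar).
#' @export
tajimas_d <- function(aln, stats = NULL) {
  s <- stats_or_compute(aln, stats)
  if (s$n < 4L) stop("Tajima's D requires n >= 4")
  if (s$S == 0L) stop("Tajima's D undefined when S = 0")
  k <- tajima_constants(s$n)
  (s$K_within - s$S / k$a1) / sqrt(k$e1 * s$S + k$e2 * s$S * (s$S - 1))
}

#' Fu and Li's D* (no outgroup)
#'
#' Numerator `(n/(n-1)) eta - a_n eta_s`; variance from the published
#' starred-test constants. Negative when singletons are in excess.
#'
#' @inheritParams tajimas_d
#' @return the statistic (scalar).
#' @export
fu_li_d_star <- function(aln, stats = NULL) {
  s <- stats_or_compute(aln, stats)
  if (s$n < 4L) stop("Fu & Li's D* requires n >= 4")
  if (s$S == 0L) stop("Fu & Li's D* undefined when S = 0")
  k <- fu_li_star_constants(s$n)
  num <- (s$n / (s$n - 1)) * s$eta - k$an * s$eta_s
  num / sqrt(k$uD * s$eta + k$vD * s$eta^2)
}

#' Fu and Li's F* (no outgroup)
#'
#' Numerator `K - ((n-1)/n) eta_s`, contrasting pairwise diversity with
#' singletons.
#'
#' @inheritParams tajimas_d
#' @return the statistic (scalar).
#' @export
fu_li_f_star <- function(aln, stats = NULL) {
  s <- stats_or_compute(aln, stats)
  if (s$n < 4L) stop("Fu & Li's F* requires n >= 4")
  if (s$S == 0L) stop("Fu & Li's F* undefined when S = 0")
  k <- fu_li_star_constants(s$n)
  num <- s$K_within - ((s$n - 1) / s$n) * s$eta_s
  num / sqrt(k$uF * s$eta + k$vF * s$eta^2)
}

#' All three neutrality tests on one alignment
#'
#' @param aln a `hap_alignment`.
#' @return data.frame with rows `D`, `Dstar`, `Fstar` and column `value`.
#' @export
neutrality_tests <- function(aln) {
  s <- diversity_stats(aln)
  data.frame(statistic = c("D", "Dstar", "Fstar"),
             value = c(tajimas_d(aln, s), fu_li_d_star(aln, s),
                       fu_li_f_star(aln, s)),
             stringsAsFactors = FALSE)
}
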