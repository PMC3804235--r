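# Independent oracles and small fixture builders used across the suite.

# Exhaustive two-sided Fisher exact p for a 2x2 table: enumerate every table
# with the observed margins and sum the hypergeometric probabilities that do
# not exceed the observed table's (with the customary 1 + 1e-7 slack against
# floating-point ties).
fisher_enum_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)
  if (lo > hi) return(1)
  support <- lo:hi
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Brute-force mean pairwise Hamming distance over the valid (fully A/C/G/T)
# columns of an alignment.
brute_k_within <- function(aln) {
  ok <- apply(aln$seq, 2L, function(col) all(col %in% c("A", "C", "G", "T")))
  m <- aln$seq[, ok, drop = FALSE]
  n <- nrow(m)
  tot <- 0
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      tot <- tot + sum(m[i, ] != m[j, ])
  tot / choose(n, 2)
}

# A random sync object (two pools) for round-trip checks.
random_sync <- function(n, seed) {
  set.seed(seed)
  counts <- array(rpois(n * 2 * 6, lambda = 8), dim = c(n, 2, 6))
  storage.mode(counts) <- "integer"
  sites <- data.frame(chrom = paste0("sc", sample(1:5, n, replace = TRUE)),
                      pos = sort(sample.int(1e6, n)),
                      ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
                      stringsAsFactors = FALSE)
  btiscan:::new_sync(sites, counts)
}

# A small alignment with a prescribed set of site patterns (one string per
# haplotype).
aln_from_strings <- function(x, label = "") {
  names(x) <- paste0("h", seq_along(x))
  hap_alignment(x, label = label)
}

# Minimal probit_fit stand-in with prescribed coefficients and vcov, for
# exercising Fieller edge cases.
fake_probit_fit <- function(alpha, beta, vcov, mult = qnorm(0.975)) {
  dimnames(vcov) <- list(c("alpha", "beta"), c("alpha", "beta"))
  structure(list(alpha = alpha, beta = beta, vcov = vcov, h = 1, df = 3,
                 heterogeneity = FALSE, mult = mult, n_doses = 5,
                 converged = TRUE),
            class = "probit_fit")
}
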