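sync_from_counts <- function(...) {
  # each argument: c(pool1 A,T,C,G,N,del, pool2 A,T,C,G,N,del)
  rows <- list(...)
  counts <- array(0L, dim = c(length(rows), 2, 6))
  for (i in seq_along(rows)) counts[i, , ] <- matrix(rows[[i]], 2, 6, byrow = TRUE)
  sites <- data.frame(chrom = "sc1", pos = seq_along(rows) * 10L, ref = "A",
                      stringsAsFactors = FALSE)
  btiscan:::new_sync(sites, counts)
}

test_that("pooled allele frequencies are exact ratios with guarded input", {
  expect_equal(pool_allele_freq(0, 10), 0)
  expect_equal(pool_allele_freq(10, 10), 1)
  expect_equal(pool_allele_freq(3, 12), 0.25)
  expect_error(pool_allele_freq(1, 0), "positive")
  expect_error(pool_allele_freq(5, 4), "minor_count")
})

test_that("SNP calling filters enforce coverage, support and frequency rules", {
  s <- sync_from_counts(
    c(5, 0, 0, 4, 0, 0,   30, 0, 0, 30, 0, 0),   # pool1 coverage 9 -> out
    c(99, 0, 0, 1, 0, 0,  100, 0, 0, 0, 0, 0),   # minor 1 read, 0.5% -> out
    c(90, 0, 0, 2, 0, 0,  104, 0, 0, 4, 0, 0),   # 6/200 = 3% -> kept
    c(196, 0, 0, 2, 0, 0, 200, 0, 0, 0, 0, 0),   # 2/398 = 0.5% -> out
    c(50, 0, 0, 50, 0, 0, 50, 0, 0, 50, 0, 0),   # balanced -> kept
    c(48, 1, 0, 50, 0, 0, 50, 1, 0, 50, 0, 0),   # triallelic -> out
    c(50, 0, 0, 50, 9, 9, 50, 0, 0, 50, 9, 9))   # N/del ignored -> kept
  snps <- filter_sites(s)
  expect_equal(snps$pos, c(30L, 50L, 70L))
  expect_equal(snps$minor[1], "G")
  expect_equal(snps$count1[1], 2L)
  expect_equal(snps$cov2[1], 108L)
})

test_that("minor allele on a single read is excluded, on two reads kept", {
  one <- sync_from_counts(c(100, 0, 0, 1, 0, 0, 100, 0, 0, 0, 0, 0))
  expect_equal(nrow(filter_sites(one, run_config(min_maf = 0.001))), 0L)
  two <- sync_from_counts(c(100, 0, 0, 1, 0, 0, 100, 0, 0, 1, 0, 0))
  expect_equal(nrow(filter_sites(two, run_config(min_maf = 0.001))), 1L)
})

test_that("pairwise Fst matches the heterozygosity oracle and its bounds", {
  # fixed difference: the scan's strongest possible signal
  expect_equal(pairwise_fst(0, 100, 120, 120), 1)
  # identical frequencies
  expect_equal(pairwise_fst(20, 100, 20, 100), 0)
  # 8A/2G vs 2A/8G at coverage 10: hand-computed from the pi formulas
  p1 <- 0.2; p2 <- 0.8
  pi1 <- 2 * p1 * (1 - p1) * 10 / 9
  pi2 <- 2 * p2 * (1 - p2) * 10 / 9
  piT <- 2 * 0.5 * 0.5 * 20 / 19
  expect_equal(pairwise_fst(2, 10, 8, 10), (piT - (pi1 + pi2) / 2) / piT)
  expect_error(pairwise_fst(0, 1, 5, 10), ">= 2")
})

test_that("Fst is symmetric, bounded and zero only without differentiation", {
  set.seed(21)
  cov1 <- sample(10:200, 200, replace = TRUE)
  cov2 <- sample(10:200, 200, replace = TRUE)
  c1 <- rbinom(200, cov1, runif(200))
  c2 <- rbinom(200, cov2, runif(200))
  f12 <- pairwise_fst(c1, cov1, c2, cov2)
  f21 <- pairwise_fst(c2, cov2, c1, cov1)
  expect_equal(f12, f21)
  expect_true(all(f12 >= 0 & f12 <= 1))
  expect_equal(pairwise_fst(0, 50, 60, 60), 1)
  expect_equal(pairwise_fst(30, 60, 25, 50), 0)  # both 0.5
})

test_that("Fisher exact p equals full fixed-margin enumeration", {
  expect_equal(fisher_exact_site(10, 10, 0, 10), 2 / choose(20, 10))
  expect_equal(fisher_exact_site(5, 10, 5, 10), 1)
  set.seed(4)
  for (i in 1:50) {
    a <- sample(0:12, 1); b <- sample(0:12, 1)
    c <- sample(0:12, 1); d <- sample(0:12, 1)
    expect_equal(fisher_exact_site(a, a + b, c, c + d),
                 fisher_enum_p(a, b, c, d), tolerance = 1e-10)
  }
})

test_that("q-values reduce to BH at pi0 = 1 and preserve p order", {
  expect_equal(storey_qvalues(rep(1, 10)), rep(1, 10))
  set.seed(8)
  p <- runif(500)^1.5
  expect_equal(storey_qvalues(p, pi0_method = "one"), p.adjust(p, "BH"))
  q <- storey_qvalues(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_true(all(q <= p.adjust(p, "BH") + 1e-12))  # pi0 <= 1 shrinks BH
  expect_error(storey_qvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("outlier rule composes the Fst tail with the q-value filter", {
  fst <- c(rep(0.1, 988), rep(0.9, 12))
  q <- rep(0.5, 1000)
  q[989:997] <- 0.001   # 9 of the 12 tail SNPs pass the q filter
  q[998:1000] <- 0.01
  snps <- data.frame(fst = fst, qvalue = q)
  out <- detect_outliers(snps, run_config())
  expect_equal(sum(out$outlier), 9L)
  expect_equal(attr(out, "fst_threshold"), 0.9)

  flat <- data.frame(fst = rep(0.3, 50), qvalue = rep(1e-6, 50))
  expect_equal(sum(detect_outliers(flat)$outlier), 0L)
  expect_error(detect_outliers(snps[0, ]), "no SNPs")
})

test_that("under pure drift the scan flags at most 1% of SNPs", {
  sim <- simulate_pooled_experiment(
    pool_sim_spec(n_snps = 1000, selected_fraction = 0, seed = 19))
  res <- scan_pools(sim$sync)
  expect_lte(mean(res$outlier), 0.01)
})
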