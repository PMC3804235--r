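two_pop_panel <- function(n_per = 10, m = 20, seed = 70) {
  set.seed(seed)
  # fixed differences between the two populations at every SNP
  G <- rbind(matrix(0L, n_per, m), matrix(2L, n_per, m))
  # a little within-population noise on a few SNPs keeps the matrix full rank
  G[1, 1:3] <- 1L
  colnames(G) <- paste0("s", seq_len(m))
  genotype_matrix(G, pop = rep(c("a", "b"), each = n_per),
                  phenotype = rnorm(2 * n_per))
}

test_that("PCA separates structured populations and matches dense eigen", {
  gm <- two_pop_panel()
  sc <- pca_covariates(gm, k = 2)
  grp <- rep(c("a", "b"), each = 10)
  expect_gt(abs(mean(sc[grp == "a", 1]) - mean(sc[grp == "b", 1])), 1)
  expect_lt(stats::var(sc[grp == "b", 1]), 1e-20)

  # oracle: eigen-decomposition of the explicitly formed correlation matrix
  X <- scale(gm$geno)
  ev <- eigen(stats::cor(gm$geno))
  proj <- X %*% ev$vectors[, 1]
  expect_equal(abs(drop(cor(sc[, 1], proj))), 1, tolerance = 1e-10)
})

test_that("PCA sign convention is deterministic and k is capped", {
  gm <- two_pop_panel()
  s1 <- pca_covariates(gm, k = 3)
  s2 <- pca_covariates(gm, k = 3)
  expect_identical(s1, s2)
  small <- genotype_matrix(gm$geno[1:4, ], pop = gm$pop[1:4],
                           phenotype = gm$phenotype[1:4])
  expect_lte(ncol(pca_covariates(small, k = 10)), 3L)
})

test_that("a marker fully explaining the phenotype gives R2 = 1, p ~ 0", {
  set.seed(71)
  g <- sample(0:2, 40, replace = TRUE)
  gm <- genotype_matrix(matrix(g, ncol = 1, dimnames = list(NULL, "m1")),
                        pop = rep("a", 40), phenotype = 2.5 * g - 1)
  res <- marker_model(gm, covariates = NULL, snp = "m1")
  expect_equal(res[["r2"]], 1, tolerance = 1e-12)
  expect_lt(res[["p"]], 1e-12)
  expect_equal(res[["effect"]], 2.5, tolerance = 1e-10)
})

test_that("allele relabelling flips the effect sign but not p or R2", {
  set.seed(72)
  g <- sample(0:2, 60, replace = TRUE)
  y <- 0.5 * g + rnorm(60)
  gm1 <- genotype_matrix(matrix(g, ncol = 1, dimnames = list(NULL, "m")),
                         pop = rep("a", 60), phenotype = y)
  gm2 <- genotype_matrix(matrix(2L - g, ncol = 1, dimnames = list(NULL, "m")),
                         pop = rep("a", 60), phenotype = y)
  r1 <- marker_model(gm1, NULL, "m")
  r2 <- marker_model(gm2, NULL, "m")
  expect_equal(r1[["p"]], r2[["p"]])
  expect_equal(r1[["r2"]], r2[["r2"]])
  expect_equal(r1[["effect"]], -r2[["effect"]])
})

test_that("null-marker p-values are uniform", {
  set.seed(73)
  ps <- replicate(300, {
    g <- rbinom(50, 2, 0.4)
    y <- rnorm(50)
    gm <- genotype_matrix(matrix(g, ncol = 1, dimnames = list(NULL, "m")),
                          pop = rep("a", 50), phenotype = y)
    marker_model(gm, NULL, "m")[["p"]]
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("a marker collinear with covariates degrades gracefully", {
  set.seed(74)
  g <- rep(c(0L, 2L), each = 10)
  cov <- matrix(g / 2, ncol = 1)
  gm <- genotype_matrix(matrix(g, ncol = 1, dimnames = list(NULL, "m")),
                        pop = rep("a", 20), phenotype = rnorm(20))
  expect_warning(res <- marker_model(gm, cov, "m"), "collinear")
  expect_equal(res[["p"]], 1)
  expect_equal(res[["r2"]], 0)
})

test_that("permutation adjustment hits its boundary and preserves order", {
  # one marker determines the phenotype (up to hair-thin noise), the rest are
  # unstructured: its raw p undercuts every permutation minimum
  set.seed(75)
  n <- 60
  G <- cbind(causal = rbinom(n, 2, 0.5),
             matrix(rbinom(n * 29, 2, 0.5), n, 29,
                    dimnames = list(NULL, paste0("s", 1:29))))
  y <- G[, "causal"] + rnorm(n, 0, 1e-4)
  gm <- genotype_matrix(G, pop = rep("a", n), phenotype = y)
  res <- permutation_adjust(gm, covariates = NULL, B = 200, seed = 77)
  expect_equal(res$p_adj[res$marker == "causal"], 1 / 201)
  expect_true("causal" %in% res$marker[res$significant])
  # adjusted p is monotone in raw p and bounded below by 1/(B+1)
  o <- order(res$p_raw)
  expect_true(all(diff(res$p_adj[o]) >= 0))
  expect_true(all(res$p_adj >= 1 / 201))
  expect_error(permutation_adjust(gm, B = 50), ">= 100")
})

test_that("permutation adjustment is reproducible given the seed", {
  spec <- panel_sim_spec(n_populations = 3, n_per_pop = 10, n_snps = 15,
                         seed = 80)
  sim <- simulate_genotype_panel(spec)
  r1 <- permutation_adjust(sim$gm, B = 150, seed = 5)
  r2 <- permutation_adjust(sim$gm, B = 150, seed = 5)
  expect_identical(r1, r2)
})

test_that("the missing-data path agrees with the complete-data path", {
  set.seed(81)
  n <- 40
  G <- matrix(rbinom(n * 12, 2, 0.5), n, 12,
              dimnames = list(NULL, paste0("s", 1:12)))
  y <- G[, 5] + rnorm(n, 0, 0.5)
  gm <- genotype_matrix(G, pop = rep("a", n), phenotype = y)
  cov <- pca_covariates(gm, 3)  # shared covariates so the two paths compare
  res_c <- permutation_adjust(gm, covariates = cov, B = 150, seed = 9)
  gm_na <- gm
  gm_na$geno[1, 3] <- NA_integer_  # forces the general per-marker path
  res_n <- permutation_adjust(gm_na, covariates = cov, B = 150, seed = 9)
  common <- setdiff(res_c$marker, "s3")
  expect_equal(res_c$p_raw[match(common, res_c$marker)],
               res_n$p_raw[match(common, res_n$marker)], tolerance = 1e-10)
  expect_true("s5" %in% res_n$marker[res_n$significant])
})
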