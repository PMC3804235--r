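test_that("scenario construction validates sizes and fractions", {
  expect_error(demographic_scenario(ne = c(100, 1), introgression = 0), ">= 2")
  expect_error(demographic_scenario(ne = 100, introgression = c(0, 0.5)),
               "equal length")
  expect_error(demographic_scenario(ne = 100, introgression = 1.5), "\\[0, 1\\]")
  sc <- litox_scenario()
  expect_equal(sc$n_generations, 18L)
  # forward generations 11-12 (the crash) sit at backward indices 8 and 7
  expect_equal(which(sc$introgression == 0.20), c(7L, 8L))
  expect_equal(sc$ne[7:8], c(600, 600))
  expect_equal(sc$ne[1], 6000)
})

test_that("simulation is reproducible bit-for-bit given the seed", {
  sc <- litox_scenario(sample_size = 12)
  a1 <- simulate_neutral_sample(sc, theta = 4, seed = 99)
  a2 <- simulate_neutral_sample(sc, theta = 4, seed = 99)
  expect_identical(a1$seq, a2$seq)
  a3 <- simulate_neutral_sample(sc, theta = 4, seed = 100)
  expect_false(identical(a3$seq, a1$seq))
})

test_that("sampling more haplotypes than gene copies is refused", {
  sc <- demographic_scenario(ne = 5, introgression = 0, source_ne = 1000,
                             sample_size = 20)
  expect_error(simulate_neutral_sample(sc, theta = 1, seed = 1), "2\\*Ne")
})

test_that("constant-size mean segregating sites matches the closed form", {
  # E[S] = theta for n = 2
  sc <- constant_scenario(ne = 500, sample_size = 2)
  mu <- 1 / (4 * 500)
  set.seed(17)
  S <- replicate(2000, length(btiscan:::drop_mutations(
    btiscan:::sim_genealogy(sc), mu)$counts))
  sem <- sd(S) / sqrt(length(S))
  expect_lt(abs(mean(S) - 1), 3 * sem)
})

test_that("total introgression hands the sample to the source population", {
  # focal strain bottlenecked to near-nothing, but immediate migration out:
  # diversity must match the source's constant-size expectation, not the
  # bottleneck's
  sc_mig <- demographic_scenario(ne = rep(10, 30), introgression = 1,
                                 source_ne = 2000, sample_size = 8)
  sc_ref <- constant_scenario(ne = 2000, sample_size = 8)
  mu <- 5 / (4 * 2000)
  set.seed(23)
  S_mig <- replicate(800, length(btiscan:::drop_mutations(
    btiscan:::sim_genealogy(sc_mig), mu)$counts))
  S_ref <- replicate(800, length(btiscan:::drop_mutations(
    btiscan:::sim_genealogy(sc_ref), mu)$counts))
  expect_equal(mean(S_mig), mean(S_ref), tolerance = 0.1)
  # and the same history without migration collapses diversity
  sc_trap <- demographic_scenario(ne = rep(10, 30), introgression = 0,
                                  source_ne = 2000, sample_size = 8)
  S_trap <- replicate(400, length(btiscan:::drop_mutations(
    btiscan:::sim_genealogy(sc_trap), mu)$counts))
  expect_lt(mean(S_trap), 0.5 * mean(S_ref))
})

test_that("recent expansion pushes D negative, recent bottleneck positive", {
  mu <- 8 / (4 * 1000)
  grow <- demographic_scenario(ne = rep(50000, 60), introgression = 0,
                               source_ne = 1000, sample_size = 15)
  shrink <- demographic_scenario(ne = rep(60, 60), introgression = 0,
                                 source_ne = 1000, sample_size = 15)
  stat_mean <- function(sc, seed) {
    set.seed(seed)
    vals <- replicate(400, {
      cnt <- btiscan:::drop_mutations(btiscan:::sim_genealogy(sc), mu)$counts
      if (length(cnt) == 0) NA_real_
      else btiscan:::neutrality_from_counts(cnt, 15)[["D"]]
    })
    mean(vals, na.rm = TRUE)
  }
  expect_lt(stat_mean(grow, 5), stat_mean(shrink, 6))
  expect_lt(stat_mean(grow, 5), 0)
  expect_gt(stat_mean(shrink, 6), 0)
})

test_that("the empirical corrected p-value uses the plus-one estimator", {
  sc <- constant_scenario(ne = 1000, sample_size = 10)
  res <- corrected_pvalue(20, "D", sc, theta = 5, n_replicates = 200,
                          seed = 3, keep_sims = TRUE)
  expect_equal(res$p, 1 / (res$n_valid + 1))
  expect_true(all(res$sims < 20))
  med <- median(res$sims)
  res_med <- corrected_pvalue(med, "D", sc, theta = 5, n_replicates = 200,
                              seed = 3)
  expect_equal(res_med$p, 0.5, tolerance = 0.1)
  expect_error(corrected_pvalue(1, "D", sc, theta = 5, n_replicates = 50),
               ">= 100")
})

test_that("monomorphic replicates are excluded and counted", {
  sc <- constant_scenario(ne = 200, sample_size = 4)
  res <- corrected_pvalue(0.5, "D", sc, theta = 0.3, n_replicates = 300,
                          seed = 10)
  expect_gt(res$n_monomorphic, 0)
  expect_equal(res$n_valid + res$n_monomorphic, 300)
  expect_error(corrected_pvalue(0.5, "D", sc, theta = 1e-9,
                                n_replicates = 100, seed = 1),
               "monomorphic")
})
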