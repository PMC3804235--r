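noise_free_assay <- function(alpha = 0, beta = 2, n = 1000,
                             doses = 10^seq(-1, 1, 0.5)) {
  p <- pnorm(alpha + beta * log10(doses))
  data.frame(concentration = doses, n_exposed = n, n_dead = p * n,
             replicate = 1L)
}

test_that("Abbott's correction is the stated rescaling with clamping", {
  expect_equal(abbott_correct(0.7, 0), 0.7)
  expect_equal(abbott_correct(0.55, 0.10), 0.5)
  expect_warning(out <- abbott_correct(0.05, 0.10), "clamped")
  expect_equal(out, 0)
  expect_error(abbott_correct(0.5, 1), "< 1")
  # identity at zero control, monotone in observed mortality
  obs <- seq(0, 1, 0.05)
  expect_equal(abbott_correct(obs, 0), obs)
  expect_true(all(diff(suppressWarnings(abbott_correct(obs, 0.2))) >= 0))
})

test_that("noise-free generated curves are recovered to four decimals", {
  fit <- fit_probit(noise_free_assay())
  expect_equal(fit$alpha, 0, tolerance = 1e-4)
  expect_equal(fit$beta, 2, tolerance = 1e-4)
  lc50 <- lethal_concentration(fit, 0.5)
  expect_equal(lc50[["lc"]], 1, tolerance = 1e-4)
  lc95 <- lethal_concentration(fit, 0.95)
  expect_equal(lc95[["lc"]], 10^(qnorm(0.95) / 2), tolerance = 1e-4)
  # huge n: fiducial limits collapse onto the point estimate
  tight <- fit_probit(noise_free_assay(n = 1e7))
  lc <- lethal_concentration(tight, 0.5)
  expect_lt(lc[["upper"]] - lc[["lower"]], 0.01)
  expect_true(lc[["lower"]] <= lc[["lc"]] && lc[["lc"]] <= lc[["upper"]])
})

test_that("degenerate designs are refused", {
  flat <- data.frame(concentration = c(0.01, 100), n_exposed = 20,
                     n_dead = c(0, 20), replicate = 1L)
  expect_error(fit_probit(flat), "all-or-nothing")
  expect_error(fit_probit(data.frame(concentration = 1, n_exposed = 10,
                                     n_dead = 5, replicate = 1L)),
               "2 distinct")
})

test_that("an imprecise slope fails Fieller's validity condition", {
  f <- fake_probit_fit(0, 2, matrix(c(0.1, 0, 0, 10), 2))  # g >> 1
  expect_error(lethal_concentration(f, 0.5), "g >= 1")
})

test_that("control mortality rows are used by Abbott before fitting", {
  set.seed(40)
  tbl <- simulate_bioassay(lc50 = 2, slope = 2.5, control_mortality = 0.15,
                           n_per_dose = 200, seed = 41)
  expect_true(any(tbl$concentration == 0))
  fit <- suppressWarnings(fit_probit(tbl))
  lc <- lethal_concentration(fit, 0.5)
  expect_equal(unname(lc[["lc"]]), 2, tolerance = 0.25)
  # ignoring the control biases the LC50 downwards
  fit0 <- suppressWarnings(fit_probit(tbl[tbl$concentration > 0, ]))
  expect_lt(lethal_concentration(fit0, 0.5)[["lc"]], lc[["lc"]])
})

test_that("resistance ratios follow the extreme-bound CI and the dual rule", {
  fit <- fit_probit(noise_free_assay(n = 500))
  rr_self <- resistance_ratio(fit, fit, 0.5)
  expect_equal(rr_self$rr, 1)
  expect_false(rr_self$significant)

  # arithmetic of the stated rule on prescribed LC intervals
  pop <- fake_probit_fit(-log10(2) * 2.2, 2.2,
                         matrix(c(1e-4, 0, 0, 1e-4), 2))
  ref <- fake_probit_fit(0, 2.2, matrix(c(1e-4, 0, 0, 1e-4), 2))
  rr <- resistance_ratio(pop, ref, 0.5)
  expect_equal(rr$rr, 2, tolerance = 1e-6)
  expect_equal(rr$ci[["lower"]],
               rr$lc_pop[["lower"]] / rr$lc_ref[["upper"]])
  expect_equal(rr$ci[["upper"]],
               rr$lc_pop[["upper"]] / rr$lc_ref[["lower"]])
  expect_true(rr$significant)
  # plain rule is narrower on both sides
  rr_plain <- resistance_ratio(pop, ref, 0.5, ci_rule = "plain")
  expect_gt(rr_plain$ci[["lower"]], rr$ci[["lower"]])
  expect_lt(rr_plain$ci[["upper"]], rr$ci[["upper"]])
})

test_that("overlapping fiducial intervals veto significance even when CI > 1", {
  # wide reference interval overlapping the population's, ratio CI above 1
  pop <- fake_probit_fit(-log10(1.6) * 2, 2, matrix(c(4e-4, 0, 0, 4e-4), 2))
  ref <- fake_probit_fit(0, 2, matrix(c(0.04, 0, 0, 1e-6), 2))
  rr <- resistance_ratio(pop, ref, 0.5, ci_rule = "plain")
  overlap <- rr$lc_pop[["lower"]] <= rr$lc_ref[["upper"]] &&
    rr$lc_ref[["lower"]] <= rr$lc_pop[["upper"]]
  expect_true(overlap)
  expect_gt(rr$ci[["lower"]], 1)
  expect_false(rr$significant)
})

test_that("LC estimates rescale with dose units and RRs do not", {
  set.seed(50)
  tbl <- simulate_bioassay(lc50 = 1.5, slope = 2, seed = 51)
  ref <- simulate_bioassay(lc50 = 1.0, slope = 2, seed = 52)
  f1 <- fit_probit(tbl); r1 <- fit_probit(ref)
  tbl10 <- tbl; tbl10$concentration <- tbl10$concentration * 10
  ref10 <- ref; ref10$concentration <- ref10$concentration * 10
  f2 <- fit_probit(tbl10); r2 <- fit_probit(ref10)
  expect_equal(lethal_concentration(f2, 0.5), 10 * lethal_concentration(f1, 0.5))
  expect_equal(resistance_ratio(f2, r2, 0.5)$rr,
               resistance_ratio(f1, r1, 0.5)$rr)
})

test_that("strong lack of fit triggers the heterogeneity adjustment", {
  # systematic dose-level departures from any probit line inflate the
  # Pearson chi-square over its degrees of freedom
  doses <- 10^seq(-1, 1, length.out = 7)
  p <- pnorm(1.2 * log10(doses)) + rep(c(0.12, -0.12), length.out = 7)
  p <- pmin(0.99, pmax(0.01, p))
  rows <- data.frame(concentration = doses, n_exposed = 800,
                     n_dead = round(800 * p), replicate = 1L)
  fit <- fit_probit(rows)
  expect_gt(fit$h, 1)
  expect_true(fit$heterogeneity)
  expect_equal(fit$mult, qt(0.975, fit$df))
  # a clean curve at the same design is not flagged
  clean <- noise_free_assay(doses = doses)
  expect_false(fit_probit(clean)$heterogeneity)
})
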