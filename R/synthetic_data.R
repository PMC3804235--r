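# Generators for every input the pipeline consumes, with the statistical
# structure the analyses assume: a two-strain pooled experiment (drift +
# selection at a minority of loci, binomial read sampling at overdispersed
# coverage), a structured multi-population genotype panel (Balding-Nichols
# island model with population-level phenotypes), and binomial bioassay
# mortality from a log-probit curve with optional control mortality.

#' Specification of a two-pool drift/selection experiment
#'
#' Defaults mirror the laboratory selection design: 1520 SNPs, an effective
#' size of 6000, 18 generations of divergence, about 1% of loci under
#' selection with coefficient 0.5, and negative-binomially overdispersed read
#' coverage with mean 1000 per pool.
#'
#' @param n_snps number of SNPs.
#' @param ne effective population size during divergence.
#' @param generations generations of independent drift for each descendant
#'   population.
#' @param selected_fraction fraction of loci under directional selection in
#'   population 2 (the selected strain).
#' @param s selection coefficient at selected loci (genic selection).
#' @param coverage_mean,coverage_size negative-binomial read coverage per
#'   pool (mean and dispersion `size`).
#' @param freq_range ancestral minor-allele frequencies are drawn uniformly
#'   from this range.
#' @param seed integer seed.
#' @return list of class `pool_sim_spec`.
#' @export
pool_sim_spec <- function(n_snps = 1520L, ne = 6000, generations = 18L,
                          selected_fraction = 0.01, s = 0.5,
                          coverage_mean = 1000, coverage_size = 3,
                          freq_range = c(0.05, 0.5), seed = 1L) {
  stopifnot(n_snps >= 1, ne >= 2, generations >= 0,
            selected_fraction >= 0, selected_fraction <= 1, s >= 0,
            coverage_mean > 0, coverage_size > 0,
            all(freq_range > 0), all(freq_range < 1))
  structure(as.list(environment()), class = "pool_sim_spec")
}

wf_drift <- function(p, ne, generations, s = 0) {
  for (g in seq_len(generations)) {
    if (s > 0) p <- p * (1 + s) / (1 + s * p)  # deterministic selection update
    p <- stats::rbinom(length(p), 2 * ne, p) / (2 * ne)
  }
  p
}

#' Simulate a pooled two-strain sequencing experiment
#'
#' Each SNP draws an ancestral frequency; two descendant populations drift
#' independently for the specified generations by binomial Wright-Fisher
#' sampling, with selected loci receiving a deterministic selection update in
#' population 2 before each sampling step. Read counts are then drawn
#' binomially at a negative-binomial coverage per pool.
#'
#' @param spec a [pool_sim_spec()].
#' @return list with `sync` (a two-pool `sync` object; the focal allele
#'   occupies the `G` slot, the other the `A` slot) and `truth` (data.frame
#'   of ancestral/final frequencies and the selected flag).
#' @export
simulate_pooled_experiment <- function(spec) {
  stopifnot(inherits(spec, "pool_sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_snps
  p0 <- stats::runif(n, spec$freq_range[1], spec$freq_range[2])
  selected <- stats::runif(n) < spec$selected_fraction
  p1 <- wf_drift(p0, spec$ne, spec$generations)           # susceptible line
  p2 <- numeric(n)                                         # selected line
  p2[!selected] <- wf_drift(p0[!selected], spec$ne, spec$generations)
  if (any(selected))
    p2[selected] <- wf_drift(p0[selected], spec$ne, spec$generations,
                             s = spec$s)
  cov1 <- pmax(2L, stats::rnbinom(n, mu = spec$coverage_mean,
                                  size = spec$coverage_size))
  cov2 <- pmax(2L, stats::rnbinom(n, mu = spec$coverage_mean,
                                  size = spec$coverage_size))
  alt1 <- stats::rbinom(n, cov1, p1)
  alt2 <- stats::rbinom(n, cov2, p2)
  counts <- array(0L, dim = c(n, 2L, 6L))
  counts[, 1, 1] <- cov1 - alt1   # A slot: non-focal allele
  counts[, 1, 4] <- alt1          # G slot: focal allele
  counts[, 2, 1] <- cov2 - alt2
  counts[, 2, 4] <- alt2
  sites <- data.frame(chrom = sprintf("sc%04d", seq_len(n)),
                      pos = rep(100L, n), ref = "A",
                      stringsAsFactors = FALSE)
  truth <- data.frame(chrom = sites$chrom, pos = sites$pos,
                      p_ancestral = p0, p_pool1 = p1, p_pool2 = p2,
                      selected = selected, stringsAsFactors = FALSE)
  list(sync = new_sync(sites, counts), truth = truth)
}

#' Specification of a structured genotype panel
#'
#' Defaults mirror the island-sampling design of the field study: six
#' populations of 30 individuals, island-model differentiation `Fst = 0.1`,
#' population-level phenotypes with a handful of causal SNPs whose
#' differentiation is inflated relative to neutral markers (local selection
#' pushes resistance alleles apart between treated and untreated
#' populations).
#'
#' @param n_populations number of populations.
#' @param n_per_pop individuals per population.
#' @param n_snps number of SNPs.
#' @param fst island-model differentiation of neutral SNPs, in (0, 1).
#' @param causal_fst differentiation of causal SNPs (selection-inflated).
#' @param n_causal number of causal SNPs.
#' @param effect phenotype change per unit causal allele frequency.
#' @param pop_noise_sd SD of population-level phenotype noise.
#' @param ind_noise_sd SD of individual-level phenotype noise (0 reproduces a
#'   purely population-level phenotype such as an LC95 shared by all
#'   members).
#' @param baseline phenotype baseline.
#' @param freq_range ancestral frequency range.
#' @param missing_rate genotype missingness rate.
#' @param seed integer seed.
#' @return list of class `panel_sim_spec`.
#' @export
panel_sim_spec <- function(n_populations = 6L, n_per_pop = 30L,
                           n_snps = 324L, fst = 0.1, causal_fst = 0.3,
                           n_causal = 3L, effect = 2, pop_noise_sd = 1,
                           ind_noise_sd = 0, baseline = 10,
                           freq_range = c(0.1, 0.9), missing_rate = 0,
                           seed = 1L) {
  stopifnot(n_populations >= 2, n_per_pop >= 1, n_snps >= 1,
            fst > 0, fst < 1, causal_fst > 0, causal_fst < 1,
            n_causal >= 0, n_causal <= n_snps,
            missing_rate >= 0, missing_rate < 1)
  structure(as.list(environment()), class = "panel_sim_spec")
}

balding_nichols <- function(p, fst, n_pop) {
  a <- p * (1 - fst) / fst
  b <- (1 - p) * (1 - fst) / fst
  matrix(stats::rbeta(length(p) * n_pop, rep(a, n_pop), rep(b, n_pop)),
         nrow = length(p), ncol = n_pop)
}

#' Simulate a structured genotype panel with phenotypes
#'
#' Per SNP an ancestral frequency is drawn; population frequencies follow the
#' Balding-Nichols island model `Beta(p(1-F)/F, (1-p)(1-F)/F)` (with the
#' inflated `causal_fst` at causal SNPs); genotypes are `Binomial(2, p_pop)`.
#' The population phenotype is
#' `baseline + sum effects * causal allele frequency + Normal(0, pop_noise_sd)`
#' assigned to every member, plus optional individual noise. QC scores are
#' drawn so a fraction of SNPs fails each array threshold.
#'
#' @param spec a [panel_sim_spec()].
#' @return list with `gm` (a `genotype_matrix` with phenotype and QC) and
#'   `truth` (causal SNP names, population frequencies and phenotype
#'   components).
#' @export
simulate_genotype_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_sim_spec"))
  set.seed(spec$seed)
  n_pop <- spec$n_populations
  n_ind <- n_pop * spec$n_per_pop
  m <- spec$n_snps
  snp_names <- sprintf("snp%04d", seq_len(m))
  causal <- sort(sample.int(m, spec$n_causal))
  p0 <- stats::runif(m, spec$freq_range[1], spec$freq_range[2])
  pf <- balding_nichols(p0, spec$fst, n_pop)
  if (spec$n_causal > 0L)
    pf[causal, ] <- balding_nichols(p0[causal], spec$causal_fst, n_pop)
  pop <- rep(paste0("pop", seq_len(n_pop)), each = spec$n_per_pop)
  G <- matrix(NA_integer_, nrow = n_ind, ncol = m,
              dimnames = list(paste0("ind", seq_len(n_ind)), snp_names))
  for (k in seq_len(n_pop)) {
    rows <- which(pop == paste0("pop", k))
    G[rows, ] <- matrix(stats::rbinom(m * length(rows), 2L,
                                      rep(pf[, k], each = length(rows))),
                        nrow = length(rows))
  }
  if (spec$missing_rate > 0) {
    drop <- stats::runif(length(G)) < spec$missing_rate
    G[drop] <- NA_integer_
  }
  pheno_pop <- spec$baseline +
    if (spec$n_causal > 0L)
      colSums(matrix(spec$effect * pf[causal, , drop = FALSE],
                     nrow = spec$n_causal)) else 0
  pheno_pop <- pheno_pop + stats::rnorm(n_pop, 0, spec$pop_noise_sd)
  phenotype <- pheno_pop[match(pop, paste0("pop", seq_len(n_pop)))] +
    stats::rnorm(n_ind, 0, spec$ind_noise_sd)
  qc <- data.frame(snp = snp_names,
                   GC50 = pmin(1, pmax(0, stats::rbeta(m, 8, 2))),
                   GenTrain = pmin(1, pmax(0, stats::rbeta(m, 8, 2))),
                   CR = 1 - colMeans(is.na(G)),
                   allele = "G",
                   stringsAsFactors = FALSE)
  gm <- genotype_matrix(G, pop = pop, phenotype = phenotype, qc = qc)
  truth <- list(causal = snp_names[causal], pop_freq = pf,
                pheno_pop = pheno_pop, p_ancestral = p0)
  list(gm = gm, truth = truth)
}

#' Simulate a dose-mortality bioassay from a log-probit curve
#'
#' Deaths per replicate follow
#' `Binomial(n, c + (1 - c) * pnorm(slope * (log10(dose) - log10(lc50))))`
#' with control mortality `c`. When `c > 0` a control row (concentration 0)
#' is included per replicate. Defaults mirror the bioassay protocol: five
#' concentrations, four replicates, 25 larvae each.
#'
#' @param lc50 true LC50 (dose units, > 0).
#' @param slope probit slope per log10 dose (> 0).
#' @param doses positive dose vector (default five doses spanning the
#'   activity range).
#' @param n_per_dose larvae per replicate and dose.
#' @param replicates number of replicates.
#' @param control_mortality natural mortality proportion.
#' @param population label attached to the rows.
#' @param seed optional integer seed.
#' @return a bioassay data.frame (`population`, `concentration`, `n_exposed`,
#'   `n_dead`, `replicate`).
#' @export
simulate_bioassay <- function(lc50, slope, doses = lc50 * 10^seq(-1, 1, 0.5),
                              n_per_dose = 25L, replicates = 4L,
                              control_mortality = 0, population = "simulated",
                              seed = NULL) {
  if (lc50 <= 0 || slope <= 0) stop("lc50 and slope must be positive")
  if (any(doses <= 0)) stop("doses must be positive")
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(replicate = seq_len(replicates), concentration = doses)
  p <- control_mortality + (1 - control_mortality) *
    stats::pnorm(slope * (log10(grid$concentration) - log10(lc50)))
  out <- data.frame(population = population,
                    concentration = grid$concentration,
                    n_exposed = n_per_dose,
                    n_dead = stats::rbinom(nrow(grid), n_per_dose, p),
                    replicate = grid$replicate,
                    stringsAsFactors = FALSE)
  if (control_mortality > 0) {
    ctrl <- data.frame(population = population, concentration = 0,
                       n_exposed = n_per_dose,
                       n_dead = stats::rbinom(replicates, n_per_dose,
                                              control_mortality),
                       replicate = seq_len(replicates),
                       stringsAsFactors = FALSE)
    out <- rbind(ctrl, out)
  }
  out
}
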