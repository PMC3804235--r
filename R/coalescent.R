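# Backward-in-time neutral coalescent with a per-generation demographic
# window (discrete Wright-Fisher parent picking, introgression as lineage
# migration into a constant-size source population) followed by a standard
# continuous-time coalescent in the pre-history phase. Used to recalibrate
# neutrality-test significance under the resistant strain's selection history:
# a bottlenecked, repeatedly introgressed strain is not at neutral
# equilibrium, so the analytic significance bands of D, D* and F* do not
# apply and an empirical null is simulated instead.

#' Describe a demographic scenario for the coalescent null
#'
#' Generation 1 is the most recent. Each generation has an effective size for
#' the focal (selected) strain and an introgression fraction: the probability
#' that a lineage's parent that generation belongs to the external source
#' population (the susceptible stock the strain was founded from and
#' replenished with). Before the window the strain merges into the source,
#' which evolves at constant size.
#'
#' @param ne vector of per-generation effective sizes (generation 1 first).
#' @param introgression vector of per-generation introgression fractions in
#'   `[0, 1]`; recycled to `length(ne)` if scalar.
#' @param source_ne effective size of the source population.
#' @param sample_size haplotypes sampled at present.
#' @return object of class `demographic_scenario`.
#' @export
demographic_scenario <- function(ne, introgression = 0, source_ne = 6000,
                                 sample_size = 22) {
  if (length(introgression) == 1L) introgression <- rep(introgression, length(ne))
  if (length(introgression) != length(ne))
    stop("ne and introgression must have equal length")
  if (any(introgression < 0 | introgression > 1))
    stop("introgression fractions must lie in [0, 1]")
  if (length(ne) > 0L && any(ne < 2)) stop("all Ne must be >= 2")
  if (source_ne < 2) stop("source_ne must be >= 2")
  structure(list(n_generations = length(ne), ne = as.numeric(ne),
                 introgression = as.numeric(introgression),
                 source_ne = as.numeric(source_ne),
                 sample_size = as.integer(sample_size)),
            class = "demographic_scenario")
}

#' The resistant-strain selection history used for corrected significance
#'
#' Eighteen generations of selection at a census of about 6000 larvae with
#' 2.5% introgression from the susceptible stock each generation; after
#' generation 10 the strain crashed, selection was suspended for two
#' generations and introgression raised to 20%. The bottleneck size is not
#' published, so it is a parameter here (default one tenth of the base size).
#'
#' @param sample_size haplotypes sampled (the sequencing yielded 20-24 per
#'   gene).
#' @param ne_base effective size in ordinary generations.
#' @param ne_bottleneck effective size in the two crash generations.
#' @param bottleneck_gens forward-time generation indices of the crash
#'   (default 11 and 12 of 18).
#' @param intro_base,intro_bottleneck introgression fractions outside and
#'   inside the crash.
#' @param n_generations length of the selection window.
#' @param source_ne effective size of the susceptible source stock.
#' @return a [demographic_scenario()].
#' @export
litox_scenario <- function(sample_size = 22, ne_base = 6000,
                           ne_bottleneck = 600, bottleneck_gens = c(11, 12),
                           intro_base = 0.025, intro_bottleneck = 0.20,
                           n_generations = 18, source_ne = 6000) {
  ne_fwd <- rep(ne_base, n_generations)
  m_fwd <- rep(intro_base, n_generations)
  ne_fwd[bottleneck_gens] <- ne_bottleneck
  m_fwd[bottleneck_gens] <- intro_bottleneck
  # backward indexing: generation 1 = most recent = forward generation n
  demographic_scenario(ne = rev(ne_fwd), introgression = rev(m_fwd),
                       source_ne = source_ne, sample_size = sample_size)
}

#' Constant-size neutral scenario
#'
#' @param ne constant effective size.
#' @param sample_size haplotypes sampled.
#' @return a [demographic_scenario()] with an empty recent window (pure
#'   continuous-time coalescent at size `ne`).
#' @export
constant_scenario <- function(ne = 6000, sample_size = 22) {
  demographic_scenario(ne = numeric(0), introgression = numeric(0),
                       source_ne = ne, sample_size = sample_size)
}

# Simulate one genealogy. Returns parent pointers and node times (in
# generations); tips are nodes 1..n at time 0.
sim_genealogy <- function(scenario) {
  n <- scenario$sample_size
  max_nodes <- 2L * n  # at most n - 1 internal nodes are ever created
  parent <- integer(max_nodes)
  time <- numeric(max_nodes)
  active <- seq_len(n)
  in_source <- rep(FALSE, n)
  next_node <- n + 1L
  # discrete Wright-Fisher window
  for (g in seq_len(scenario$n_generations)) {
    if (length(active) == 1L) break
    if (sum(!in_source) > 2 * scenario$ne[g])
      stop("sample size exceeds 2*Ne at generation ", g)
    mig <- !in_source & stats::runif(length(active)) < scenario$introgression[g]
    in_source[mig] <- TRUE
    drop <- logical(length(active))
    new_nodes <- integer(0)
    new_src <- logical(0)
    for (src in c(FALSE, TRUE)) {
      idx <- which(in_source == src)  # positions within `active`
      if (length(idx) < 2L) next
      npar <- if (src) 2 * scenario$source_ne else 2 * scenario$ne[g]
      pars <- sample.int(npar, length(idx), replace = TRUE)
      for (grp in split(idx, pars)) {
        if (length(grp) < 2L) next
        node <- next_node; next_node <- next_node + 1L
        time[node] <- g
        parent[active[grp]] <- node
        drop[grp] <- TRUE
        new_nodes <- c(new_nodes, node)
        new_src <- c(new_src, src)
      }
    }
    active <- c(active[!drop], new_nodes)
    in_source <- c(in_source[!drop], new_src)
  }
  # continuous phase in the source/ancestral population
  t <- scenario$n_generations
  k <- length(active)
  while (k > 1L) {
    t <- t + stats::rexp(1L, rate = k * (k - 1) / 2 / (2 * scenario$source_ne))
    pair <- sample.int(k, 2L)
    node <- next_node; next_node <- next_node + 1L
    time[node] <- t
    parent[active[pair]] <- node
    active <- c(active[-pair], node)
    k <- k - 1L
  }
  list(parent = parent[seq_len(next_node - 1L)],
       time = time[seq_len(next_node - 1L)], n = n,
       root = active[1L])
}

# Number of sampled tips below each node (handles polytomies).
tip_counts <- function(tree) {
  cnt <- numeric(length(tree$parent))
  cnt[seq_len(tree$n)] <- 1
  ord <- order(tree$time)
  for (i in ord) {
    p <- tree$parent[i]
    if (p > 0L) cnt[p] <- cnt[p] + cnt[i]
  }
  cnt
}

# Poisson mutations on branches under infinite sites; returns the derived
# allele count of each mutation (and optionally the tips carrying it).
drop_mutations <- function(tree, mu, want_matrix = FALSE) {
  nb <- length(tree$parent)
  has_parent <- tree$parent > 0L
  len <- numeric(nb)
  len[has_parent] <- tree$time[tree$parent[has_parent]] -
    tree$time[has_parent]
  nmut <- stats::rpois(nb, mu * len)
  cnt <- tip_counts(tree)
  carriers <- NULL
  if (want_matrix) {
    below <- vector("list", nb)
    for (i in seq_len(tree$n)) below[[i]] <- i
    for (i in order(tree$time)) {
      p <- tree$parent[i]
      if (p > 0L) below[[p]] <- c(below[[p]], below[[i]])
    }
    edges <- rep(seq_len(nb), nmut)
    carriers <- lapply(edges, function(e) below[[e]])
  }
  list(counts = rep(cnt, nmut), carriers = carriers)
}

# D, D*, F* straight from derived-allele counts of segregating sites.
neutrality_from_counts <- function(counts, n) {
  S <- length(counts)
  K <- sum(counts * (n - counts)) / choose(n, 2)
  eta <- S
  eta_s <- sum(counts == 1 | counts == n - 1)
  tk <- tajima_constants(n)
  fk <- fu_li_star_constants(n)
  D <- (K - S / tk$a1) / sqrt(tk$e1 * S + tk$e2 * S * (S - 1))
  Dstar <- ((n / (n - 1)) * eta - fk$an * eta_s) /
    sqrt(fk$uD * eta + fk$vD * eta^2)
  Fstar <- (K - ((n - 1) / n) * eta_s) / sqrt(fk$uF * eta + fk$vF * eta^2)
  c(D = D, Dstar = Dstar, Fstar = Fstar, S = S, K = K, eta_s = eta_s)
}

#' Simulate one neutral haplotype sample under a demographic scenario
#'
#' Lineages are traced backwards: exact discrete Wright-Fisher parent picking
#' (with multi-mergers) through the recent per-generation window, lineage
#' migration into the source population with each generation's introgression
#' fraction, and a standard exponential-time coalescent in the constant-size
#' source beyond the window. Mutations fall on branches as a Poisson process
#' with rate `mu` per generation under infinite sites.
#'
#' @param scenario a [demographic_scenario()].
#' @param theta per-locus scaled mutation rate `4 * source_ne * mu`; exactly
#'   one of `theta`, `mu` must be given.
#' @param mu per-locus per-generation mutation rate.
#' @param seed optional integer seed.
#' @return a binary `hap_alignment` (`A` = ancestral, `G` = derived) with one
#'   column per segregating site; zero columns when the sample is
#'   monomorphic.
#' @export
simulate_neutral_sample <- function(scenario, theta = NULL, mu = NULL,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(mu) == is.null(theta))
    stop("give exactly one of theta, mu")
  if (is.null(mu)) mu <- theta / (4 * scenario$source_ne)
  tree <- sim_genealogy(scenario)
  mut <- drop_mutations(tree, mu, want_matrix = TRUE)
  n <- scenario$sample_size
  S <- length(mut$counts)
  m <- matrix("A", nrow = n, ncol = S)
  for (j in seq_len(S)) m[mut$carriers[[j]], j] <- "G"
  rownames(m) <- paste0("hap", seq_len(n))
  hap_alignment(m, label = "coalescent")
}

#' Empirical demography-corrected p-value for a neutrality statistic
#'
#' Simulates `n_replicates` neutral samples under the scenario, computes the
#' chosen statistic on each (monomorphic replicates are skipped and counted),
#' and reports the one-tailed empirical p in the direction of the observed
#' sign with the plus-one estimator
#' `(#{as-or-more extreme} + 1) / (n_valid + 1)`.
#'
#' @param observed the observed statistic value.
#' @param statistic `"D"`, `"Dstar"` or `"Fstar"`.
#' @param scenario a [demographic_scenario()].
#' @param theta per-locus scaled mutation rate for the simulations.
#' @param n_replicates number of neutral replicates (>= 100).
#' @param seed optional integer seed.
#' @param two_tailed double the one-tailed p (capped at 1) instead.
#' @param keep_sims retain the simulated statistic values.
#' @return list with `p`, `n_valid`, `n_monomorphic`, significance `bands`
#'   (logical at 0.05, 0.02, 0.01) and optionally `sims`.
#' @export
corrected_pvalue <- function(observed, statistic = c("D", "Dstar", "Fstar"),
                             scenario, theta, n_replicates = 1000L,
                             seed = NULL, two_tailed = FALSE,
                             keep_sims = FALSE) {
  statistic <- match.arg(statistic)
  if (n_replicates < 100L) stop("n_replicates must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  mu <- theta / (4 * scenario$source_ne)
  n <- scenario$sample_size
  sims <- numeric(n_replicates)
  valid <- logical(n_replicates)
  for (r in seq_len(n_replicates)) {
    tree <- sim_genealogy(scenario)
    counts <- drop_mutations(tree, mu)$counts
    if (length(counts) == 0L) next
    sims[r] <- neutrality_from_counts(counts, n)[[statistic]]
    valid[r] <- TRUE
  }
  n_valid <- sum(valid)
  if (n_valid == 0L)
    stop("all replicates were monomorphic; increase theta")
  vals <- sims[valid]
  extreme <- if (observed >= 0) sum(vals >= observed) else sum(vals <= observed)
  p <- (extreme + 1) / (n_valid + 1)
  if (two_tailed) p <- min(1, 2 * p)
  out <- list(p = p, n_valid = n_valid,
              n_monomorphic = n_replicates - n_valid,
              bands = c(`0.05` = p < 0.05, `0.02` = p < 0.02,
                        `0.01` = p < 0.01),
              statistic = statistic, observed = observed)
  if (keep_sims) out$sims <- vals
  out
}
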