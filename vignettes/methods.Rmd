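---
title: "Methods: from pooled read counts to resistance loci"
author: "btiscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from pooled read counts to resistance loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(btiscan)
```

# Overview

`btiscan` implements the statistical chain used to hunt loci underlying
resistance to the larvicide *Bacillus thuringiensis* subsp. *israelensis*
(*Bti*) in mosquitoes: a pooled-sequencing genome scan between a susceptible
and a laboratory-selected strain, neutrality testing of candidate genes
against a demography-aware coalescent null, probit quantification of
resistance in bioassays, and PCA-corrected association mapping in structured
field populations. Every stage is driven by simulators
(`simulate_pooled_experiment()`, `simulate_genotype_panel()`,
`simulate_bioassay()`, `simulate_neutral_sample()`) that reproduce the
statistical structure each analysis assumes, so the whole chain is testable
without any sequencing data. The `analysis/` scripts walk the chain end to
end on such simulated data.

# Pooled genome scan

## SNP calling filters

Pooled read counts arrive in the sync format (one colon-separated
`A:T:C:G:N:del` tuple per pool and site). `filter_sites()` retains biallelic
sites with total coverage of at least 10 reads in *each* pool, a minor allele
carried by at least 2 reads, and an overall minor-allele frequency of at
least 1%. The `N` and deletion slots are parsed but never enter
allele-frequency computation. Two choices the count data do not decide for
us:

* the 1% frequency rule is applied to the two pools combined, not per pool —
  a per-pool rule would discard precisely the strongly differentiated sites
  the scan is looking for;
* sites where three or more alleles carry reads are dropped outright rather
  than reduced to their two most frequent alleles. Sequencing error makes
  spurious third alleles at deep coverage common, and reducing them would
  silently misattribute those reads.

## Fst, Fisher tests, q-values, outliers

`pairwise_fst()` uses the classical heterozygosity estimator on read-count
frequencies with a finite-coverage correction:
$\pi_{pool} = 2p(1-p)\,c/(c-1)$ per pool ($c$ = coverage),
$\pi_S$ their mean, $\pi_T$ the same quantity on the pooled counts, and
$F_{st} = (\pi_T - \pi_S)/\pi_T$, clamped to $[0,1]$ and defined as 0 when
$\pi_T = 0$. An uncorrected variant (`corrected = FALSE`) is provided for
sensitivity checks. Two pools fixed for alternative alleles give exactly 1;
equal frequencies give exactly 0.

Because Fst on read counts is noisy at low coverage, each SNP also gets a
two-sided Fisher exact test on the 2x2 table of minor/major read counts by
pool (`fisher_exact_site()`, checked in the test suite against exhaustive
fixed-margin enumeration for all tables with total up to 24). The resulting
p-values are converted to q-values with the Storey procedure
(`storey_qvalues()`); the null proportion $\hat\pi_0$ is estimated with the
single-lambda estimator at $\lambda = 0.5$ rather than a spline smoother —
with thousands of tests the difference is negligible and the single-lambda
form is exactly reproducible. Forcing $\hat\pi_0 = 1$ recovers
Benjamini–Hochberg, which the tests exploit as an oracle.

`detect_outliers()` flags a SNP when its Fst reaches the empirical 99th
percentile of all retained SNPs (type-7 quantile, linear interpolation, ties
at the threshold included) *and* its q-value is below 0.005. When every SNP
ties at the threshold the "tail" would be the whole distribution, so the rule
degenerates to strict inequality and flags nothing. On drift-only simulations
the flagged fraction stays below 1% by construction of the tail, and in
practice far below it because of the q-value filter.

# Diversity and neutrality statistics

`diversity_stats()` computes $S$, total mutations $\eta$ (a site with $k$
states contributes $k-1$), singletons $\eta_s$ (states carried by exactly one
haplotype), mean pairwise differences $K$, per-site $\pi$, haplotype
diversity $H_d$ and Watterson's $\theta_W = S/a_n$. Columns containing a gap
or `N` in any haplotype are deleted list-wise and all per-site quantities use
the remaining length — the convention of the standard desktop tools for
Sanger alignments, which keeps values comparable with published tables.
Multi-hit sites contribute once to $S$ but fully to $\eta$; Tajima's $D$ is
computed from $S$ while the starred Fu & Li statistics use $\eta$.

Tajima's $D$ uses the 1989 variance constants; Fu & Li's $D^*$ and $F^*$ use
the published starred-test constants in the corrected form adopted by the
reference implementations. The constants are pinned by regression tests
(a hand-derived $n = 4$ alignment) and, more tellingly, by simulation: on
5000 neutral constant-size genealogies ($n = 20$, $\theta = 5$) the means of
$D$, $D^*$ and $F^*$ are all within a few hundredths of zero and
$E[\pi] \approx E[\theta_W]$ to better than 5%.

# The demography-corrected null

A strain founded from a susceptible stock, selected for 18 generations,
bottlenecked and repeatedly introgressed is nowhere near neutral-equilibrium,
so the analytic significance bands of $D$, $D^*$, $F^*$ do not apply.
`simulate_neutral_sample()` builds the appropriate null: backwards in time,
the recent window is simulated with exact discrete Wright–Fisher parent
picking per generation (multi-mergers allowed), each lineage migrating into
the source population with that generation's introgression fraction; beyond
the window all lineages join the constant-size source and coalesce under the
standard exponential-time process. Mutations fall on branches as a Poisson
process with per-generation rate $\mu = \theta/(4N_{e,source})$ under
infinite sites.

`litox_scenario()` encodes the selected strain's history: 18 generations at
$N_e = 6000$ with 2.5% introgression per generation, and a two-generation
crash after generation 10 with introgression raised to 20%. The crash size
was never published; it defaults to one tenth of the base size and is a
parameter, not an assertion. `corrected_pvalue()` simulates 1000 replicates,
computes the chosen statistic on each, skips monomorphic replicates (the
statistics are undefined at $S = 0$) while reporting how many were skipped,
and returns the one-tailed plus-one empirical p in the direction of the
observed sign — published tables report directional significance ("P <
0.02"), and a two-tailed option is provided. The simulator is validated
against closed forms ($E[S] = \theta\sum_{i<n} 1/i$ within 3 standard errors
at $10^4$ replicates) and by sign checks: recent expansion drives mean $D$
negative, a recent bottleneck positive.

# Probit dose–response

`fit_probit()` fits $\Phi^{-1}(p) = \alpha + \beta \log_{10}(dose)$ by
binomial maximum likelihood (IRLS, tolerance $10^{-8}$, 100 iterations).
Control mortality from concentration-0 rows is removed beforehand with
Abbott's formula $(obs - ctrl)/(1 - ctrl)$, per replicate by default (each
replicate's own control, falling back to the pooled control), with clamping
and a warning when observed mortality falls below the control. Doses with 0%
or 100% mortality stay in the likelihood; only a design where *every* dose is
all-or-nothing is refused as unidentifiable.

Lack of fit is measured by Finney's heterogeneity factor $h$ = Pearson
$\chi^2/df$ on dose-aggregated data; when $h > 1$ and the $\chi^2$ test is
significant at 5%, variances are inflated by $h$ and a $t_{df}$ multiplier
replaces the normal one. `lethal_concentration()` inverts the fit
($LC_q = 10^{(\Phi^{-1}(q)-\alpha)/\beta}$) with 95% limits from Fieller's
theorem; $g \ge 1$ (slope too imprecise for the ratio to have finite limits)
is an error, not a number. Calibration is verified by simulation: over 1000
simulated assays (5 doses, 4 replicates of 25 larvae) the fiducial limits
cover the true LC50 at 95% within Monte-Carlo error.

`resistance_ratio()` divides the LCs and builds the ratio CI from the extreme
fiducial bounds (population lower over reference upper, and vice versa) — the
conservative reading of dividing "extreme" CI values; a same-side
(`"plain"`) rule is switchable. Significance requires both non-overlapping
fiducial intervals and a ratio CI excluding 1. Note that under the extreme
rule the CI-above-1 condition already implies disjoint intervals, so the dual
rule only binds under the plain rule.

# Association mapping in structured populations

`pca_covariates()` extracts the top three principal components of the SNP
correlation matrix (monomorphic SNPs dropped, missing genotypes mean-imputed,
deterministic sign convention). `marker_model()` fits phenotype ~ intercept +
PCs + additive genotype per marker, reporting the marker's share of the total
phenotype sum of squares and the partial-F p-value; individuals missing a
genotype are dropped for that marker only. `permutation_adjust()` controls
the family-wise error by the min-p (max-T) scheme: the phenotype vector is
freely permuted across individuals B = 1000 times, all markers refit, the
per-permutation minimum p recorded, and marker j adjusted to
`(#{min-p <= p_j} + 1)/(B + 1)`.

The phenotype is population-level: every individual inherits its population's
LC95. This is the design's fundamental limitation and the vignette is blunt
about it: effective replication is the number of populations, not of
individuals. Two consequences, both demonstrated by the package's own
simulations:

* *Calibration.* Free permutation is exact under exchangeable phenotypes. The
  FWER calibration simulation therefore uses individual-level phenotypes with
  genotypic structure present and structure fully captured by the covariates;
  measured FWER sits at the nominal 5% (within Monte-Carlo error over 500
  data sets). With population-level phenotypes and fewer components than
  population dimensions (three PCs for six populations), residual confounding
  inflates the error — visible in `analysis/06_association.R`, where
  non-causal markers reach significance alongside the causal ones.
* *Power.* With six populations, three PCs absorbing most between-population
  genotype variance, and min-p correction across hundreds of markers,
  per-causal-marker power is structurally capped: simulations at effect sizes
  of twice the population-level noise SD yield roughly 30–40% power, and even
  in the noise-free limit power does not reach 80%. The acceptance suite
  states the 80% aspiration and reports the measured value; the shortfall is
  a property of population-level phenotyping, not of the estimator.

A related subtlety: with population-constant phenotypes and covariates that
fully span the population structure, the residual phenotype is identically
zero and no marker test is defined. Detection under this design *requires*
leaving population dimensions uncaptured, which is exactly what trading three
PCs against six populations does — at the price of the confounding above.

# Synthetic data

`simulate_pooled_experiment()` draws ancestral frequencies uniformly from
(0.05, 0.5), drifts two descendant populations independently for 18
generations of binomial Wright–Fisher sampling at $N_e = 6000$ (the selected
line receiving a deterministic genic-selection update, $s = 0.5$ at about 1%
of loci, before each sampling step), then samples reads binomially at
negative-binomial coverage (mean 1000, matching deep pooled cDNA-tag
coverage; the dispersion reflects the wide genic/nongenic coverage spread).
The truth table ships with every run. The drift variance matches
$p_0(1-p_0)\left(1-(1-\tfrac{1}{2N_e})^t\right)$; note that the per-SNP
heterozygosity-ratio Fst between two demes has roughly *half* that value in
expectation at small differentiation (the classical two-deme bias of
$G_{st}$-type ratio estimators), so generator checks are written against the
variance identity, not the ratio.

`simulate_genotype_panel()` uses the Balding–Nichols island model
($Beta(p\frac{1-F}{F}, (1-p)\frac{1-F}{F})$) with $F = 0.1$ for neutral SNPs
across six populations of 30 individuals. Causal SNPs get a larger
differentiation parameter (0.3 by default): local selection in treated
populations pushes resistance-allele frequencies apart far beyond neutral
expectation, and this inflation is what gives field association designs their
signal. Population phenotypes are a baseline plus effect times causal allele
frequency plus noise; an individual-level noise component (default 0) exists
for calibration studies. QC scores are drawn so that some SNPs fail each
array threshold.

`simulate_bioassay()` draws deaths as
$Binomial(n,\; c + (1-c)\,\Phi(\beta(\log_{10} d - \log_{10} LC_{50})))$ with
optional control rows — five concentrations and four replicates of 25 larvae
by default, the standard larval bioassay design.

What the simulators do *not* emulate: linkage between SNPs (every locus is
independent, so the scan cannot be tested for hitchhiking-induced clustering
of outliers), sequencing error, alignment artefacts, allele-specific
expression biases of pooled mRNA data, and haplotype phase uncertainty
(alignments are generated phased). Passing tests therefore validate the
statistics, not the upstream bioinformatics.

# Numerical choices and scales

* Empirical quantile: R type 7 (linear interpolation), ties included by
  `>=`.
* Probit convergence: IRLS, $|\Delta\ell| < 10^{-8}$, max 100 iterations.
* Fieller limits: heterogeneity-adjusted covariance when flagged; collapse
  to the point estimate as variances vanish.
* Coalescent reproducibility: bit-for-bit given (seed, scenario, theta).
* Test-suite problem sizes: $10^4$ coalescent replicates for the mean-S
  check, 5000 for statistic centring, 1000 simulated assays for fiducial
  coverage, 500 data sets (B = 200) for FWER, 50 (B = 200) for power, one
  1520-SNP pooled experiment for the end-to-end scan — sizes chosen so the
  Monte-Carlo error is comfortably below each tolerance being asserted.

# Interfaces

The package's functions, the numbered scripts under `analysis/` and this
vignette are the interface; the scripts cover the scan, diversity/neutrality,
corrected significance, probit, association, concordance and simulation
steps, each as a thin driver over exported functions, writing tab-separated
tables (with an audit header carrying seed and thresholds) under `results/`.
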