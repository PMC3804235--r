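# Structured association mapping: PCA covariates from the SNP correlation
# matrix, a per-marker least-squares fixed-effects model (phenotype ~
# intercept + PCs + additive genotype) with a partial F test, and family-wise
# multiple-testing adjustment by min-p permutation of the phenotype.

impute_standardise <- function(geno) {
  G <- geno
  mono <- apply(G, 2L, function(g) {
    v <- stats::var(g, na.rm = TRUE)
    is.na(v) || v == 0
  })
  G <- G[, !mono, drop = FALSE]
  if (ncol(G) == 0L) stop("all SNPs are monomorphic")
  for (j in seq_len(ncol(G))) {
    mu <- mean(G[, j], na.rm = TRUE)
    G[is.na(G[, j]), j] <- mu
  }
  scale(G)
}

#' Principal-component covariates from genetic markers
#'
#' Scores of the top `k` eigenvectors of the SNP correlation matrix
#' (monomorphic SNPs excluded; missing genotypes mean-imputed per SNP). Signs
#' follow a deterministic convention: each component's largest-magnitude
#' loading is positive.
#'
#' @param gm a `genotype_matrix`.
#' @param k number of components (default 3; capped at individuals - 1).
#' @return numeric matrix individuals x k of PC scores.
#' @export
pca_covariates <- function(gm, k = 3L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n <- nrow(gm$geno)
  if (n < 2L) stop("need at least 2 individuals")
  k <- min(k, n - 1L)  # at most n - 1 informative components
  Z <- impute_standardise(gm$geno)
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  k <- min(k, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  flip <- vapply(seq_len(k), function(j) {
    l <- rot[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  scores <- pc$x[, seq_len(k), drop = FALSE] %*% diag(flip, k)
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- rownames(gm$geno)
  scores
}

# Partial F test of one marker given covariates; returns R2 (share of the
# phenotype total sum of squares explained by the marker on top of the
# covariates), the p-value and the marker effect estimate.
marker_fit <- function(y, Z, g) {
  keep <- !is.na(g) & !is.na(y)
  y <- y[keep]; g <- g[keep]; Z <- Z[keep, , drop = FALSE]
  n <- length(y)
  tss <- sum((y - mean(y))^2)
  qz <- qr(Z)
  rss_red <- sum(qr.resid(qz, y)^2)
  Xf <- cbind(Z, g)
  qf <- qr(Xf)
  if (qf$rank < ncol(Xf)) {
    warning("marker collinear with covariates")
    return(c(r2 = 0, p = 1, effect = NA_real_))
  }
  rss_full <- sum(qr.resid(qf, y)^2)
  df2 <- n - ncol(Xf)
  if (df2 <= 0) return(c(r2 = 0, p = 1, effect = NA_real_))
  Fstat <- (rss_red - rss_full) / (rss_full / df2)
  p <- if (!is.finite(Fstat)) {
    if (rss_red > rss_full) 0 else 1  # exact fit (or no variation at all)
  } else {
    stats::pf(Fstat, 1, df2, lower.tail = FALSE)
  }
  eff <- unname(qr.coef(qf, y)[ncol(Xf)])
  c(r2 = if (tss > 0) (rss_red - rss_full) / tss else 0, p = p, effect = eff)
}

#' Single-marker fixed-effects association model
#'
#' Least-squares fit of `phenotype ~ intercept + covariates + genotype`
#' (additive 0/1/2 coding); the marker's contribution is measured as
#' `R^2 = (RSS_reduced - RSS_full) / TSS` and tested with the partial F test.
#' Individuals missing the genotype are dropped for that marker.
#'
#' @param gm a `genotype_matrix` with phenotypes.
#' @param covariates matrix of covariates (e.g. [pca_covariates()]); an
#'   intercept is added internally.
#' @param snp SNP index or name.
#' @return named numeric `c(r2, p, effect)`.
#' @export
marker_model <- function(gm, covariates = NULL, snp) {
  stopifnot(inherits(gm, "genotype_matrix"), !is.null(gm$phenotype))
  g <- gm$geno[, snp]
  v <- stats::var(g, na.rm = TRUE)
  if (is.na(v) || v == 0)
    stop("marker is monomorphic among non-missing individuals")
  Z <- cbind(`(Intercept)` = rep(1, nrow(gm$geno)), covariates)
  marker_fit(gm$phenotype, Z, g)
}

#' Permutation-adjusted association scan
#'
#' Fits every polymorphic marker, then permutes the phenotype vector across
#' individuals `B` times (covariates stay attached to individuals), refits
#' all markers per permutation and records the minimum raw p. The adjusted
#' p-value of marker `j` is `(#{b : min-p_b <= p_j} + 1) / (B + 1)` (the
#' max-T/min-p family-wise correction); markers with adjusted p at or below
#' `alpha` are flagged.
#'
#' @param gm a `genotype_matrix` with phenotypes.
#' @param covariates covariate matrix (default: 3 PCs via
#'   [pca_covariates()]).
#' @param B number of permutations (>= 100; the study design used 1000).
#' @param alpha family-wise significance level.
#' @param seed optional integer seed for the permutations.
#' @return data.frame (one row per marker): `marker`, `r2`, `p_raw`, `p_adj`,
#'   `significant`, `effect`.
#' @export
permutation_adjust <- function(gm, covariates = NULL, B = 1000L,
                               alpha = 0.05, seed = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"), !is.null(gm$phenotype))
  if (B < 100L) stop("B must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(covariates)) covariates <- pca_covariates(gm, 3L)
  y <- gm$phenotype
  Z <- cbind(rep(1, nrow(gm$geno)), covariates)
  G <- gm$geno
  poly <- apply(G, 2L, function(g) {
    v <- stats::var(g, na.rm = TRUE)
    !is.na(v) && v > 0
  })
  G <- G[, poly, drop = FALSE]
  if (ncol(G) == 0L) stop("no polymorphic markers")
  m <- ncol(G)
  complete <- !anyNA(G) && !anyNA(y)
  if (complete) {
    n <- nrow(G)
    qz <- qr(Z)
    p_cov <- qz$rank
    df2 <- n - p_cov - 1L
    Gr <- qr.resid(qz, G)
    gnorm <- sqrt(colSums(Gr^2))
    sing <- gnorm < 1e-10
    yr <- qr.resid(qz, y)
    rss_red <- sum(yr^2)
    tss <- sum((y - mean(y))^2)
    r_to_p <- function(r) {
      r2 <- pmin(r^2, 1)
      stats::pf(r2 / (1 - r2) * df2, 1, df2, lower.tail = FALSE)
    }
    rho <- as.vector(crossprod(Gr, yr)) / (gnorm * sqrt(rss_red))
    rho[sing] <- 0
    p_raw <- r_to_p(rho)
    p_raw[sing] <- 1
    r2 <- rho^2 * rss_red / tss
    effect <- as.vector(crossprod(Gr, yr)) / gnorm^2
    effect[sing] <- NA_real_
    minp <- numeric(B)
    for (b in seq_len(B)) {
      yp <- sample(y)
      ypr <- qr.resid(qz, yp)
      rb <- as.vector(crossprod(Gr, ypr)) / (gnorm * sqrt(sum(ypr^2)))
      rb[sing] <- 0
      minp[b] <- r_to_p(max(abs(rb)))
    }
  } else {
    fits <- vapply(seq_len(m), function(j)
      marker_fit(y, Z, G[, j]), numeric(3))
    r2 <- fits["r2", ]; p_raw <- fits["p", ]; effect <- fits["effect", ]
    minp <- numeric(B)
    for (b in seq_len(B)) {
      yp <- sample(y)
      pb <- vapply(seq_len(m), function(j)
        suppressWarnings(marker_fit(yp, Z, G[, j])["p"]), numeric(1))
      minp[b] <- min(pb)
    }
  }
  p_adj <- (vapply(p_raw, function(p) sum(minp <= p), numeric(1)) + 1) / (B + 1)
  data.frame(marker = colnames(G), r2 = r2, p_raw = p_raw, p_adj = p_adj,
             significant = p_adj <= alpha, effect = effect,
             stringsAsFactors = FALSE, row.names = NULL)
}
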