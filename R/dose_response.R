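# Log-probit bioassay analysis after Finney: Abbott control-mortality
# correction, maximum-likelihood probit regression on log10(dose),
# heterogeneity-adjusted variances, Fieller fiducial limits for lethal
# concentrations, and resistance ratios with the dual significance rule
# (non-overlapping fiducial intervals AND ratio CI excluding 1).

#' Abbott's correction for control mortality
#'
#' `(observed - control) / (1 - control)`, clamped to `[0, 1]`. A warning is
#' emitted when observed mortality falls below the control (the corrected
#' value is clamped to 0).
#'
#' @param observed observed mortality proportion(s) in `[0, 1]`.
#' @param control control (natural) mortality proportion(s) in `[0, 1)`.
#' @return corrected mortality proportion(s).
#' @export
abbott_correct <- function(observed, control) {
  if (any(control >= 1)) stop("control mortality must be < 1")
  if (any(observed < 0 | observed > 1) || any(control < 0))
    stop("mortality proportions must lie in [0, 1]")
  if (any(observed < control))
    warning("observed mortality below control mortality; clamped to 0")
  pmin(1, pmax(0, (observed - control) / (1 - control)))
}

check_bioassay <- function(tbl) {
  need <- c("concentration", "n_exposed", "n_dead")
  if (!all(need %in% names(tbl)))
    stop("bioassay table needs columns: ", paste(need, collapse = ", "))
  if (any(tbl$concentration < 0)) stop("concentrations must be >= 0")
  if (any(tbl$n_dead < 0 | tbl$n_dead > tbl$n_exposed))
    stop("n_dead must lie in [0, n_exposed]")
  if (!"replicate" %in% names(tbl)) tbl$replicate <- 1L
  tbl
}

#' Fit a log-probit dose-response model
#'
#' Maximum-likelihood binomial fit of `probit(p) = alpha + beta * log10(dose)`
#' by iteratively reweighted least squares (convergence 1e-8, at most 100
#' iterations). Control rows (`concentration == 0`) supply the natural
#' mortality removed by Abbott's correction, applied per replicate by default.
#' The heterogeneity factor `h` (Pearson chi-square over degrees of freedom,
#' on dose-aggregated data) is computed; when `h > 1` and its chi-square test
#' is significant at 5%, variances are inflated by `h` and a t multiplier
#' replaces the normal multiplier in all fiducial limits (Finney's
#' heterogeneity adjustment). Doses with 0% or 100% mortality stay in the
#' likelihood.
#'
#' @param tbl data.frame with `concentration`, `n_exposed`, `n_dead` and
#'   optionally `replicate` and control rows at concentration 0.
#' @param abbott `"replicate"` (default: each replicate corrected by its own
#'   control row, falling back to the pooled control), `"pooled"`, or
#'   `"none"`.
#' @return object of class `probit_fit` with elements `alpha`, `beta`,
#'   `vcov`, `h`, `df`, `heterogeneity` (flag), `mult` (normal or t
#'   multiplier), `converged`.
#' @export
fit_probit <- function(tbl, abbott = c("replicate", "pooled", "none")) {
  abbott <- match.arg(abbott)
  tbl <- check_bioassay(tbl)
  ctrl <- tbl[tbl$concentration == 0, , drop = FALSE]
  dose <- tbl[tbl$concentration > 0, , drop = FALSE]
  if (length(unique(dose$concentration)) < 2L)
    stop("need at least 2 distinct positive concentrations")
  p_obs <- dose$n_dead / dose$n_exposed
  if (abbott != "none" && nrow(ctrl) > 0L) {
    pooled_c <- sum(ctrl$n_dead) / sum(ctrl$n_exposed)
    cvec <- rep(pooled_c, nrow(dose))
    if (abbott == "replicate") {
      per_rep <- tapply(ctrl$n_dead, ctrl$replicate, sum) /
        tapply(ctrl$n_exposed, ctrl$replicate, sum)
      hit <- match(as.character(dose$replicate), names(per_rep))
      cvec[!is.na(hit)] <- per_rep[hit[!is.na(hit)]]
    }
    p_obs <- abbott_correct(p_obs, cvec)
  }
  agg_p <- tapply(p_obs * dose$n_exposed, dose$concentration, sum) /
    tapply(dose$n_exposed, dose$concentration, sum)
  if (all(agg_p %in% c(0, 1)))
    stop("slope unidentifiable: all-or-nothing mortality at every dose")
  x <- log10(dose$concentration)
  dead_eff <- p_obs * dose$n_exposed
  fit <- suppressWarnings(
    stats::glm(cbind(dead_eff, dose$n_exposed - dead_eff) ~ x,
               family = stats::binomial(link = "probit"),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  alpha <- unname(stats::coef(fit)[1])
  beta <- unname(stats::coef(fit)[2])
  V <- stats::vcov(fit)
  dimnames(V) <- list(c("alpha", "beta"), c("alpha", "beta"))
  # heterogeneity on dose-aggregated expected vs observed deaths
  doses_u <- sort(unique(dose$concentration))
  n_u <- tapply(dose$n_exposed, dose$concentration, sum)[as.character(doses_u)]
  d_u <- tapply(dead_eff, dose$concentration, sum)[as.character(doses_u)]
  p_hat <- stats::pnorm(alpha + beta * log10(doses_u))
  ok <- p_hat > 1e-12 & p_hat < 1 - 1e-12
  X2 <- sum((d_u[ok] - n_u[ok] * p_hat[ok])^2 /
              (n_u[ok] * p_hat[ok] * (1 - p_hat[ok])))
  df <- length(doses_u) - 2L
  h <- if (df > 0L) X2 / df else 1
  het <- df > 0L && h > 1 &&
    stats::pchisq(X2, df, lower.tail = FALSE) < 0.05
  if (het) V <- V * h
  mult <- if (het) stats::qt(0.975, df) else stats::qnorm(0.975)
  structure(list(alpha = alpha, beta = beta, vcov = V, h = h, df = df,
                 heterogeneity = het, mult = mult,
                 n_doses = length(doses_u), converged = fit$converged),
            class = "probit_fit")
}

#' @export
print.probit_fit <- function(x, ...) {
  cat(sprintf("probit fit: probit(p) = %.4f + %.4f log10(dose)  [h = %.2f%s]\n",
              x$alpha, x$beta, x$h,
              if (x$heterogeneity) ", heterogeneity-adjusted" else ""))
  invisible(x)
}

#' Lethal concentration with Fieller fiducial limits
#'
#' `LC_q = 10^((qnorm(q) - alpha)/beta)`; 95% limits from Fieller's theorem on
#' the ratio using the fit's (heterogeneity-adjusted) variance-covariance
#' matrix.
#'
#' @param fit a [fit_probit()] result.
#' @param quantile mortality quantile, typically 0.5 or 0.95.
#' @return named numeric `c(lc, lower, upper)` on the dose scale.
#' @export
lethal_concentration <- function(fit, quantile = 0.5) {
  stopifnot(inherits(fit, "probit_fit"))
  if (fit$beta <= 0) stop("invalid fit: slope must be positive")
  z <- stats::qnorm(quantile)
  m <- (z - fit$alpha) / fit$beta
  v11 <- fit$vcov["alpha", "alpha"]
  v12 <- fit$vcov["alpha", "beta"]
  v22 <- fit$vcov["beta", "beta"]
  t <- fit$mult
  g <- t^2 * v22 / fit$beta^2
  if (g >= 1) stop("fiducial limits undefined (slope too imprecise, g >= 1)")
  centre <- m + (g / (1 - g)) * (m + v12 / v22)
  disc <- v11 + 2 * m * v12 + m^2 * v22 - g * (v11 - v12^2 / v22)
  half <- (t / (fit$beta * (1 - g))) * sqrt(max(disc, 0))
  out <- 10^c(m, centre - half, centre + half)
  names(out) <- c("lc", "lower", "upper")
  out
}

#' Resistance ratio with the dual significance rule
#'
#' `RR = LC_pop / LC_ref`; its 95% CI divides the extreme fiducial bounds
#' (population lower over reference upper, population upper over reference
#' lower: the widest ratio). The ratio is flagged significant only when the
#' two fiducial intervals do not overlap *and* the RR CI lower bound exceeds
#' 1.
#'
#' @param pop_fit,ref_fit [fit_probit()] results for the test population and
#'   the susceptible reference.
#' @param quantile mortality quantile (0.5 for RR50, 0.95 for RR95).
#' @param ci_rule `"extreme"` (default, widest cross-ratio of bounds) or
#'   `"plain"` (same-side ratio of bounds).
#' @return list of class `resistance_ratio`: `rr`, `ci`, `significant`,
#'   plus the two LC triples.
#' @export
resistance_ratio <- function(pop_fit, ref_fit, quantile = 0.5,
                             ci_rule = c("extreme", "plain")) {
  ci_rule <- match.arg(ci_rule)
  lc_pop <- lethal_concentration(pop_fit, quantile)
  lc_ref <- lethal_concentration(ref_fit, quantile)
  if (lc_ref[["lc"]] <= 0) stop("reference LC must be positive")
  rr <- lc_pop[["lc"]] / lc_ref[["lc"]]
  ci <- if (ci_rule == "extreme")
    c(lower = lc_pop[["lower"]] / lc_ref[["upper"]],
      upper = lc_pop[["upper"]] / lc_ref[["lower"]])
  else
    c(lower = lc_pop[["lower"]] / lc_ref[["lower"]],
      upper = lc_pop[["upper"]] / lc_ref[["upper"]])
  overlap <- lc_pop[["lower"]] <= lc_ref[["upper"]] &&
    lc_ref[["lower"]] <= lc_pop[["upper"]]
  structure(list(rr = rr, ci = ci, significant = !overlap && ci[["lower"]] > 1,
                 quantile = quantile, lc_pop = lc_pop, lc_ref = lc_ref),
            class = "resistance_ratio")
}

#' @export
print.resistance_ratio <- function(x, ...) {
  cat(sprintf("RR%d = %.3f  (95%% CI %.3f-%.3f)%s\n",
              round(100 * x$quantile), x$rr, x$ci[["lower"]], x$ci[["upper"]],
              if (x$significant) "  *significant*" else ""))
  invisible(x)
}
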