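#' Two-sided selection threshold on the z scale
#'
#' @param alpha_level two-sided significance level.
#' @return `c = qnorm(1 - alpha/2)`, the |Z| cutoff the estimate survived.
#' @export
selection_threshold <- function(alpha_level) {
  stopifnot(alpha_level > 0, alpha_level <= 1)
  stats::qnorm(1 - alpha_level / 2)
}

#' Density of a z-statistic conditional on significance
#'
#' The naive z-statistic is modelled as `Z ~ N(mu, 1)`; only values with
#' `|Z| > c` are observed. The conditional density is the normal density
#' truncated to the two tails,
#' `p_mu(z) = phi(z - mu) / [Phi(mu - c) + Phi(-mu - c)]`.
#'
#' @param z observed z value(s); must satisfy `|z| > c` (support).
#' @param mu true standardized effect.
#' @param c selection threshold (>= 0). `c = 0` recovers the unconditional
#'   normal density.
#' @return density value(s).
#' @export
conditional_density <- function(z, mu, c) {
  stopifnot(c >= 0, is.finite(mu))
  if (c > 0 && any(abs(z) <= c))
    stop("out of support: |z| <= c under selection")
  stats::dnorm(z - mu) / (stats::pnorm(mu - c) + stats::pnorm(-mu - c))
}

# Conditional CDF P(Z <= z | |Z| > c) under Z ~ N(mu, 1); piecewise in z.
.conditional_cdf <- function(z, mu, c) {
  denom <- stats::pnorm(mu - c) + stats::pnorm(-mu - c)
  lower <- stats::pnorm(pmin(z, -c) - mu)
  upper <- ifelse(z > c, stats::pnorm(z - mu) - stats::pnorm(c - mu), 0)
  (lower + upper) / denom
}

#' Conditional maximum-likelihood estimate of the standardized effect
#'
#' Maximizes the truncated-normal conditional likelihood `L_c(mu)` of an
#' observed `z` given `|Z| > c`. The argmax lies in `sign(z) * [0, |z|]`
#' (the MLE never exceeds the observation in magnitude nor flips its sign);
#' it is located by a coarse grid followed by golden-section refinement.
#'
#' @param z observed z-statistic, `|z| > c`.
#' @param c selection threshold.
#' @param tol refinement tolerance.
#' @return list with `mu_hat`, `converged`, and the `objective` (log
#'   conditional likelihood at the maximum).
#' @export
conditional_mle <- function(z, c, tol = 1e-6) {
  stopifnot(length(z) == 1L, is.finite(z), c >= 0)
  if (c == 0) return(list(mu_hat = z, converged = TRUE,
                          objective = stats::dnorm(0, log = TRUE)))
  if (abs(z) <= c) stop("out of support: |z| <= c, nothing to correct")
  s <- sign(z); az <- abs(z)
  loglik <- function(mu)
    stats::dnorm(z - mu, log = TRUE) -
      log(stats::pnorm(mu - c) + stats::pnorm(-mu - c))
  grid <- seq(0, az, length.out = 201L) * s
  gv <- vapply(grid, loglik, numeric(1))
  k <- which.max(gv)
  lo <- grid[max(1L, k - 1L)]; hi <- grid[min(length(grid), k + 1L)]
  opt <- stats::optimize(loglik, interval = sort(c(lo, hi)), maximum = TRUE,
                         tol = tol)
  mu_hat <- opt$maximum
  # optimize never returns an interval endpoint exactly; snap to 0 / z when
  # the boundary is the true argmax
  if (loglik(0) >= opt$objective) mu_hat <- 0
  else if (loglik(z) >= opt$objective) mu_hat <- z
  list(mu_hat = mu_hat, converged = TRUE,
       objective = loglik(mu_hat))
}

#' Conditional-likelihood correction of a significant effect estimate
#'
#' Summary-statistic winner's-curse correction: the observed
#' `z = beta_hat / se` is de-biased by the conditional MLE given
#' `|Z| > c(alpha_level)` and rescaled to the effect scale.
#' Requires only the estimate, its standard error and the significance
#' threshold — no individual-level data.
#'
#' @param beta_hat naive effect estimate.
#' @param se its standard error (> 0).
#' @param alpha_level two-sided level that defined selection.
#' @return list of class `correction_result`: `method = "likelihood"`,
#'   `beta_corrected`, `diagnostics` (`mu_hat`, `z`, `c`, `converged`).
#' @export
likelihood_correct <- function(beta_hat, se, alpha_level = 0.05) {
  stopifnot(se > 0)
  c0 <- selection_threshold(alpha_level)
  z <- beta_hat / se
  if (abs(z) <= c0)
    stop("estimate is not significant at alpha_level: nothing to correct")
  m <- conditional_mle(z, c0)
  structure(list(method = "likelihood", beta_corrected = m$mu_hat * se,
                 diagnostics = list(mu_hat = m$mu_hat, z = z, c = c0,
                                    converged = m$converged)),
            class = "correction_result")
}

#' Confidence interval with correct conditional coverage
#'
#' Inverts the acceptance region of the conditional law: the interval is the
#' set of `mu` for which the observed `z` falls between the `(1-level)/2` and
#' `(1+level)/2` quantiles of the truncated-normal conditional density —
#' equivalently, for which the conditional CDF of `z` lies between those
#' probabilities. The conditional CDF is monotone decreasing in `mu`, so each
#' endpoint is a single root find. Returned on the effect scale.
#'
#' @param beta_hat significant naive estimate.
#' @param se its standard error.
#' @param alpha_level level that defined the selection threshold.
#' @param level confidence level of the interval.
#' @return list of class `conditional_ci`: `lower`, `upper`, `level`.
#' @export
conditional_ci <- function(beta_hat, se, alpha_level = 0.05, level = 0.95) {
  stopifnot(se > 0, level > 0, level < 1)
  c0 <- selection_threshold(alpha_level)
  z <- beta_hat / se
  if (c0 > 0 && abs(z) <= c0)
    stop("estimate is not significant at alpha_level")
  p_lo <- (1 - level) / 2
  p_hi <- (1 + level) / 2
  g <- function(mu, target) .conditional_cdf(z, mu, c0) - target
  span <- 2
  repeat {
    lo_end <- z - span; hi_end <- z + span
    # CDF decreasing in mu: upper CI root has CDF = p_lo, lower has p_hi
    ok <- g(lo_end, p_hi) > 0 && g(hi_end, p_lo) < 0
    if (ok || span > 64) break
    span <- span * 2
  }
  if (span > 64) stop("grid exhaustion: could not bracket the interval")
  lower <- stats::uniroot(g, c(lo_end, hi_end), target = p_hi,
                          tol = 1e-8)$root
  upper <- stats::uniroot(g, c(lo_end, hi_end), target = p_lo,
                          tol = 1e-8)$root
  structure(list(lower = lower * se, upper = upper * se, level = level),
            class = "conditional_ci")
}

#' Central summary of bootstrap pair differences
#'
#' @param diffs vector of in-bag minus out-of-bag estimate differences.
#' @param center `"median"` (default) or `"mean"`.
#' @return the bias estimate `Delta_hat`.
#' @export
bootstrap_delta <- function(diffs, center = c("median", "mean")) {
  center <- match.arg(center)
  if (length(diffs) == 0) stop("no bootstrap pairs collected")
  if (center == "median") stats::median(diffs) else mean(diffs)
}

#' Bootstrap (out-of-bag) winner's-curse correction
#'
#' Repeatedly resamples the cohort with replacement; whenever the gene-based
#' test is significant in the resample, records the in-bag collapsed-genotype
#' slope `beta_D` (which mimics the naive, selected estimate) and the slope
#' `beta_E` fitted on the out-of-bag subjects (free of selection). The central
#' tendency of `beta_D - beta_E` estimates the selection bias, which is
#' subtracted from the naive estimate. Draws with a degenerate in-bag or
#' out-of-bag design are skipped but counted.
#'
#' @param G genotype matrix of the original sample.
#' @param Y trait vector.
#' @param naive_beta the original-sample collapsed-genotype slope (must have
#'   been significant — that is what makes correction meaningful).
#' @param alpha_level significance level reused inside resamples.
#' @param B target number of significant bootstrap pairs.
#' @param max_draws cap on resampling attempts.
#' @param center `"median"` or `"mean"` centering of the pair differences.
#' @param seed integer seed.
#' @param resample_fn optional injectable resampler `function(draw) -> index
#'   vector` (for deterministic testing); defaults to iid resampling.
#' @return list of class `correction_result`: `method = "bootstrap"`,
#'   `beta_corrected`, `diagnostics` (`delta_hat`, `pairs`, `draws`,
#'   `skipped_degenerate`, `low_confidence`).
#' @export
bootstrap_correct <- function(G, Y, naive_beta, alpha_level = 0.05,
                              B = 100L, max_draws = 10000L,
                              center = c("median", "mean"), seed = 1L,
                              resample_fn = NULL) {
  center <- match.arg(center)
  stopifnot(B >= 1L, max_draws >= B)
  n <- length(Y)
  K <- cmc_collapse(G)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  if (is.null(resample_fn))
    resample_fn <- function(draw) sample.int(n, n, replace = TRUE)
  diffs <- numeric(0)
  draws <- 0L; skipped <- 0L
  while (length(diffs) < B && draws < max_draws) {
    draws <- draws + 1L
    idx <- resample_fn(draws)
    Kb <- K[idx]
    sb <- sum(Kb)
    if (sb == 0L || sb == n) { skipped <- skipped + 1L; next }
    fit_d <- fit_simple_ols(Y[idx], Kb)
    if (fit_d$p_value >= alpha_level) next
    oob <- which(tabulate(idx, n) == 0L)
    Ko <- K[oob]
    so <- sum(Ko)
    if (length(oob) < 3L || so == 0L || so == length(oob)) {
      skipped <- skipped + 1L; next
    }
    fit_e <- fit_simple_ols(Y[oob], Ko)
    diffs <- c(diffs, fit_d$beta_hat - fit_e$beta_hat)
  }
  if (length(diffs) == 0)
    stop("no significant bootstrap pairs within max_draws")
  delta <- bootstrap_delta(diffs, center)
  structure(list(method = "bootstrap", beta_corrected = naive_beta - delta,
                 diagnostics = list(delta_hat = delta,
                                    pairs = length(diffs), draws = draws,
                                    skipped_degenerate = skipped,
                                    low_confidence = length(diffs) < B)),
            class = "correction_result")
}

#' Correct a reported estimate from summary statistics alone
#'
#' Convenience wrapper for the data-free use case: given a published
#' `(beta_hat, se)` pair that passed a two-sided test at `alpha_level`,
#' returns the conditional-likelihood corrected estimate and the conditional
#' confidence interval.
#'
#' @inheritParams likelihood_correct
#' @param ci_level confidence level for the conditional interval.
#' @return list with `naive`, `corrected` ([likelihood_correct()] result) and
#'   `ci` ([conditional_ci()] result).
#' @export
correct_summary <- function(beta_hat, se, alpha_level = 0.05,
                            ci_level = 0.95) {
  corr <- likelihood_correct(beta_hat, se, alpha_level)
  ci <- conditional_ci(beta_hat, se, alpha_level, ci_level)
  list(naive = beta_hat, corrected = corr, ci = ci)
}
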