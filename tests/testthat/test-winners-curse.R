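test_that("conditional density is the normal law truncated to the tails", {
  # no selection: reduces to the unconditional normal density
  expect_equal(conditional_density(1.3, 0.4, 0), dnorm(1.3 - 0.4))
  # frozen value from an independent density/CDF evaluation
  expect_equal(conditional_density(3, 0, 1.96), 0.08864443, tolerance = 1e-6)
  expect_error(conditional_density(1.5, 0, 1.96), "out of support")
  # integrates to 1 over {|z| > c} for a spread of mu (quadrature oracle)
  for (mu in c(-2, 0, 0.7, 2.5)) {
    total <- stats::integrate(conditional_density, 1.96, Inf,
                              mu = mu, c = 1.96)$value +
      stats::integrate(conditional_density, -Inf, -1.96,
                       mu = mu, c = 1.96)$value
    expect_equal(total, 1, tolerance = 1e-6)
  }
})

test_that("conditional MLE matches the grid-search oracle", {
  # frozen oracle values (grid step 1e-4)
  expect_equal(conditional_mle(2.5, 1.96)$mu_hat, 1.1378, tolerance = 1e-3)
  expect_equal(conditional_mle(3.0, 1.96)$mu_hat, 2.5224, tolerance = 1e-3)
  expect_equal(conditional_mle(2.0, 1.645)$mu_hat, 0.7363, tolerance = 1e-3)
  expect_equal(conditional_mle(2.8, 2.576)$mu_hat, 0.6216, tolerance = 1e-3)
  # far from the threshold, selection is negligible
  expect_lt(abs(conditional_mle(5, 1.96)$mu_hat - 5), 0.05)
  # live oracle across a (z, c) panel
  for (c0 in c(1.645, 1.96, 2.576))
    for (z in c(c0 + 0.05, c0 + 0.5, c0 + 1.2, 4.5, 6)) {
      expect_lt(abs(conditional_mle(z, c0)$mu_hat - grid_mle_oracle(z, c0)),
                1e-3)
    }
  # no selection: the MLE is the observation
  expect_equal(conditional_mle(1.7, 0)$mu_hat, 1.7)
  expect_error(conditional_mle(1.5, 1.96), "out of support")
})

test_that("conditional MLE shrinks toward zero and is monotone in z", {
  zs <- seq(2.0, 6, by = 0.25)
  mus <- vapply(zs, function(z) conditional_mle(z, 1.96)$mu_hat, numeric(1))
  expect_true(all(mus >= 0))
  expect_true(all(mus <= zs))
  expect_true(all(diff(mus) >= -1e-6))
  # sign symmetry
  expect_equal(conditional_mle(-2.5, 1.96)$mu_hat,
               -conditional_mle(2.5, 1.96)$mu_hat, tolerance = 1e-6)
})

test_that("likelihood correction rescales the conditional MLE", {
  lc <- likelihood_correct(2.5, 1, alpha_level = 0.05)
  expect_equal(lc$beta_corrected,
               conditional_mle(2.5, selection_threshold(0.05))$mu_hat,
               tolerance = 1e-6)
  lc2 <- likelihood_correct(2.5 * 0.268, 0.268)
  expect_equal(lc2$beta_corrected, 1.1378 * 0.268, tolerance = 1e-3)
  # antisymmetric in the sign of the estimate
  expect_equal(likelihood_correct(-0.67, 0.268)$beta_corrected,
               -likelihood_correct(0.67, 0.268)$beta_corrected,
               tolerance = 1e-8)
  # shrinkage direction
  expect_lt(likelihood_correct(0.67, 0.268)$beta_corrected, 0.67)
  expect_error(likelihood_correct(0.3, 0.268), "not significant")
})

test_that("conditional CI reduces to Wald without selection and contains the MLE", {
  ci0 <- conditional_ci(0.5, 0.1, alpha_level = 1, level = 0.95)
  expect_equal(ci0$lower, 0.5 - qnorm(0.975) * 0.1, tolerance = 1e-6)
  expect_equal(ci0$upper, 0.5 + qnorm(0.975) * 0.1, tolerance = 1e-6)
  for (z in c(2.1, 2.5, 3.5, 5)) {
    ci <- conditional_ci(z, 1)
    mle <- conditional_mle(z, 1.96)$mu_hat
    expect_lte(ci$lower, mle)
    expect_gte(ci$upper, mle)
    expect_lt(ci$lower, ci$upper)
  }
})

test_that("bootstrap delta centering follows the configured statistic", {
  d <- c(0.1, 0.2, 0.3)
  expect_equal(bootstrap_delta(d, "median"), 0.2)
  expect_equal(bootstrap_delta(d, "mean"), 0.2)
  expect_equal(bootstrap_delta(c(0, 0, 10), "median"), 0)
  expect_error(bootstrap_delta(numeric(0)), "no bootstrap pairs")
})

test_that("bootstrap correction subtracts the pair-difference center", {
  sc <- builtin_scenarios()$table1_uni
  # a replicate known to be clearly significant, so the correction applies
  G <- generate_genotypes(sc, 15L)
  Y <- simulate_trait(G, sc, 1015L)
  fit <- fit_simple_ols(Y, cmc_collapse(G))
  expect_lt(fit$p_value, 0.05)
  bc <- bootstrap_correct(G, Y, fit$beta_hat, B = 40L, seed = 99L)
  expect_equal(bc$beta_corrected, fit$beta_hat - bc$diagnostics$delta_hat)
  expect_equal(bc$diagnostics$pairs, 40L)
  expect_false(bc$diagnostics$low_confidence)
  expect_lt(bc$beta_corrected, fit$beta_hat)   # upward bias removed
  # deterministic under a fixed seed
  bc2 <- bootstrap_correct(G, Y, fit$beta_hat, B = 40L, seed = 99L)
  expect_identical(bc$beta_corrected, bc2$beta_corrected)
  # injected resampler makes the draw sequence fully reproducible
  set.seed(1)
  idx_fix <- replicate(500, sample.int(length(Y), length(Y), replace = TRUE),
                       simplify = FALSE)
  bc3 <- bootstrap_correct(G, Y, fit$beta_hat, B = 40L, max_draws = 500L,
                           seed = 1L, resample_fn = function(d) idx_fix[[d]])
  bc4 <- bootstrap_correct(G, Y, fit$beta_hat, B = 40L, max_draws = 500L,
                           seed = 2L, resample_fn = function(d) idx_fix[[d]])
  expect_identical(bc3$beta_corrected, bc4$beta_corrected)
})

test_that("median and mean bootstrap centerings agree within MC error", {
  sc <- builtin_scenarios()$table1_uni
  diffs <- c()
  for (seed in 1:60) {
    G <- generate_genotypes(sc, seed)
    Y <- simulate_trait(G, sc, seed + 2000L)
    fit <- fit_simple_ols(Y, cmc_collapse(G))
    if (fit$p_value >= 0.05) next
    med <- bootstrap_correct(G, Y, fit$beta_hat, B = 50L, seed = seed)
    avg <- bootstrap_correct(G, Y, fit$beta_hat, B = 50L, seed = seed,
                             center = "mean")
    diffs <- c(diffs, med$beta_corrected - avg$beta_corrected)
  }
  expect_gt(length(diffs), 3)
  expect_lt(abs(mean(diffs)), 0.06)
})

test_that("summary-statistic correction bundles estimate and interval", {
  out <- correct_summary(0.67, 0.268, alpha_level = 0.05)
  expect_equal(out$naive, 0.67)
  expect_lt(out$corrected$beta_corrected, 0.67)
  expect_gt(out$corrected$beta_corrected, 0)
  expect_lte(out$ci$lower, out$corrected$beta_corrected)
  expect_gte(out$ci$upper, out$corrected$beta_corrected)
  # negated input gives negated output
  neg <- correct_summary(-0.67, 0.268)
  expect_equal(neg$corrected$beta_corrected,
               -out$corrected$beta_corrected, tolerance = 1e-8)
  expect_equal(neg$ci$lower, -out$ci$upper, tolerance = 1e-6)
  expect_error(correct_summary(0.3, 0.268), "not significant")
})
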