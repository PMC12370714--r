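test_that("score vector and pooled statistics follow their definitions", {
  Y <- c(0, 0, 0, 4)
  G <- cbind(v1 = c(0L, 0L, 0L, 1L), v2 = c(0L, 0L, 0L, 0L))
  S <- compute_scores(G, Y)
  expect_equal(S, c(3, 0))                         # (4 - 1) * 1; empty column
  expect_equal(compute_scores(G, rep(2, 4)), c(0, 0))  # constant Y centers away
  expect_equal(linear_statistic(c(3, -4)), -1)
  expect_equal(linear_statistic(c(3, -4), c(0, 0)), 0)
  expect_equal(quadratic_statistic(c(3, -4)), 25)
  expect_equal(quadratic_statistic(c(0, 0)), 0)
  w <- c(2, 0.5)
  expect_equal(quadratic_statistic(c(3, -4), diag(w)), sum(w * c(3, -4)^2))
  expect_error(quadratic_statistic(c(1, 1), matrix(c(1, 2, 2, 1), 2)),
               "semi-definite")
})

test_that("quadratic statistic is invariant to score sign flips", {
  set.seed(42)
  for (i in 1:20) {
    S <- rnorm(7)
    flip <- sample(c(-1, 1), 7, replace = TRUE)
    expect_equal(quadratic_statistic(S * flip), quadratic_statistic(S))
  }
})

test_that("CMC collapsing flags any-carrier rows", {
  G <- rbind(c(0L, 1L, 0L), c(0L, 0L, 0L), c(1L, 1L, 1L))
  expect_equal(cmc_collapse(G), c(1L, 0L, 1L))
})

test_that("closed-form simple OLS matches lm()", {
  expect_equal(fit_simple_ols(c(1, 2, 3, 4), c(0, 0, 1, 1))$beta_hat, 2)
  set.seed(7)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    x <- rnorm(n); y <- 0.3 + 0.8 * x + rnorm(n)
    ours <- fit_simple_ols(y, x)
    ref <- summary(stats::lm(y ~ x))$coefficients["x", ]
    expect_equal(ours$beta_hat, unname(ref["Estimate"]), tolerance = 1e-10)
    expect_equal(ours$se, unname(ref["Std. Error"]), tolerance = 1e-10)
  }
  # exact linear data recovers the slope with zero residuals
  x <- c(0, 1, 2, 3, 4)
  expect_equal(fit_simple_ols(3 * x - 1, x)$beta_hat, 3)
  expect_error(fit_simple_ols(rnorm(5), rep(1, 5)), "constant")
})

test_that("permutation p-values match exhaustive enumeration on tiny data", {
  Y <- c(0, 0, 0, 4)
  G <- matrix(c(0L, 0L, 0L, 1L), ncol = 1)
  # oracle: 4 distinct carrier placements, |T| >= 3 in exactly one of them
  expect_equal(permutation_pvalue(G, Y, "CAST", exhaustive = TRUE), 0.25)
  expect_equal(permutation_pvalue(G, Y, "CALPHA", exhaustive = TRUE), 0.25)
  expect_equal(permutation_pvalue(G, rep(1, 4), "CAST", n_perm = 10), 1)

  # n = 6, two variants: Monte-Carlo permutation p converges to the
  # exhaustive value (add-one convention, so compare within MC error)
  set.seed(31)
  Y6 <- rnorm(6)
  G6 <- cbind(c(1L, 0L, 0L, 0L, 1L, 0L), c(0L, 0L, 1L, 0L, 0L, 0L))
  for (m in c("CAST", "CALPHA")) {
    p_ex <- permutation_pvalue(G6, Y6, m, exhaustive = TRUE)
    p_mc <- permutation_pvalue(G6, Y6, m, n_perm = 20000L, seed = 5L)
    expect_lt(abs(p_mc - p_ex), 3 * sqrt(p_ex * (1 - p_ex) / 20000) + 1e-4)
  }
})

test_that("analytic linear p-value is calibrated and matches permutation", {
  # exhaustive check at n = 8: normal approximation close to the exact
  # permutation distribution
  set.seed(11)
  Y8 <- rnorm(8)
  G8 <- cbind(c(1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L), c(0L, 0L, 1L, 0L, 0L, 0L, 0L, 1L))
  p_ex <- permutation_pvalue(G8, Y8, "CAST", exhaustive = TRUE)
  p_an <- analytic_pvalue_linear(G8, Y8)
  expect_lt(abs(p_an - p_ex), 0.1)

  # at the study's n the two calibrations agree within Monte-Carlo error
  sc <- builtin_scenarios()$table1_uni
  G <- generate_genotypes(sc, 2L)
  Y <- simulate_trait(G, sc, 3L)
  p_an <- analytic_pvalue_linear(G, Y)
  p_mc <- permutation_pvalue(G, Y, "CAST", n_perm = 20000L, seed = 9L)
  expect_lt(abs(p_an - p_mc), 3 * sqrt(p_an * (1 - p_an) / 20000) + 0.005)

  # null calibration: rejection rate at 0.05 within 3 binomial SEs
  set.seed(13)
  Gn <- matrix(0L, 50, 2); Gn[1:5, 1] <- 1L; Gn[6:8, 2] <- 1L
  rej <- mean(vapply(1:2000, function(i)
    analytic_pvalue_linear(Gn, rnorm(50)) < 0.05, logical(1)))
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))

  expect_error(analytic_pvalue_linear(matrix(1L, 10, 1), rnorm(10)),
               "constant burden")
})

test_that("CMC Wald z tracks the score z on the collapsed genotype", {
  sc <- builtin_scenarios()$table1_uni
  diffs <- vapply(1:30, function(seed) {
    G <- generate_genotypes(sc, seed)
    Y <- simulate_trait(G, sc, seed + 500L)
    K <- matrix(cmc_collapse(G), ncol = 1)
    z_wald <- fit_simple_ols(Y, K[, 1])$z
    TL <- sum(compute_scores(K, Y))
    sd0 <- sqrt(sum((Y - mean(Y))^2) * sum((K - mean(K))^2) /
                  (length(Y) - 1))
    abs(z_wald - TL / sd0)
  }, numeric(1))
  expect_lt(max(diffs), 0.05)   # O(1/n) agreement at n = 321
})

test_that("run_all_tests returns one labelled result per spec", {
  sc <- builtin_scenarios()$table1_uni
  G <- generate_genotypes(sc, 4L)
  Y <- simulate_trait(G, sc, 5L)
  res <- run_all_tests(G, Y, default_test_specs(n_perm = 200L), seed = 6L)
  expect_length(res, 3)
  expect_equal(vapply(res, `[[`, character(1), "method"),
               c(CMC = "CMC", CAST = "CAST", CALPHA = "CALPHA"))
  for (r in res) {
    expect_true(r$p_value > 0 && r$p_value <= 1)
    expect_identical(r$significant, r$p_value < 0.05)
    expect_false(r$degenerate)
  }
  # a constant collapsed genotype is reported, not an error
  G0 <- matrix(0L, sc$n, 11)
  res0 <- run_all_tests(G0, Y, default_test_specs(), seed = 1L)
  expect_false(res0[[1]]$significant)
  expect_true(res0[[1]]$degenerate)
})
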