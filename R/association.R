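#' Per-variant association score vector
#'
#' `S_j = sum_i (Y_i - Ybar) X_ij` — the building block of both gene-based
#' test classes.
#'
#' @param G `n x J` carrier-indicator matrix.
#' @param Y numeric trait vector of length `n`.
#' @return numeric vector of length `J`.
#' @export
compute_scores <- function(G, Y) {
  if (length(Y) < 2L) stop("degenerate sample: n < 2")
  stopifnot(nrow(G) == length(Y))
  as.numeric(crossprod(G, Y - mean(Y)))
}

#' Linear-class (burden) statistic
#'
#' `T_L = sum_j w_j S_j`. With equal weights this is the CAST statistic:
#' powerful when effects share a direction, sign-sensitive otherwise.
#'
#' @param S score vector from [compute_scores()].
#' @param weights per-variant weights (default all 1).
#' @return scalar statistic.
#' @export
linear_statistic <- function(S, weights = rep(1, length(S))) {
  stopifnot(length(S) == length(weights), all(is.finite(weights)))
  sum(weights * S)
}

#' Quadratic-class (variance-component) statistic
#'
#' `T_Q = S' A S` for a positive semi-definite symmetric kernel `A`
#' (identity by default, giving the unweighted C-Alpha form `sum_j S_j^2`).
#'
#' @param S score vector.
#' @param kernel `J x J` symmetric PSD matrix, or `NULL` for the identity.
#' @return scalar statistic (>= 0 for a PSD kernel).
#' @export
quadratic_statistic <- function(S, kernel = NULL) {
  if (is.null(kernel)) return(sum(S^2))
  stopifnot(is.matrix(kernel), nrow(kernel) == length(S),
            ncol(kernel) == length(S))
  if (max(abs(kernel - t(kernel))) > 1e-8) stop("kernel must be symmetric")
  ev <- eigen(kernel, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) stop("kernel must be positive semi-definite")
  as.numeric(S %*% kernel %*% S)
}

#' CMC collapsing of a variant set to a single carrier indicator
#'
#' `K_i = 1` iff subject `i` carries the minor allele at any of the `J`
#' variants.
#'
#' @param G carrier-indicator matrix.
#' @return integer 0/1 vector of length `n`.
#' @export
cmc_collapse <- function(G) {
  as.integer(rowSums(G) > 0)
}

#' Simple linear regression in closed form
#'
#' Ordinary least squares of `Y` on an intercept and a single predictor, with
#' the residual-variance standard error (`n - 2` denominator), the Wald
#' `z = beta/se`, and a two-sided normal p-value. Used for the collapsed
#' (CMC) regression and the single-variant fits; closed-form because the
#' bootstrap loop performs ~1e5 such fits per study.
#'
#' @param Y response vector.
#' @param x predictor vector (must not be constant).
#' @return list with `beta_hat`, `se`, `z`, `p_value`, class `ols_fit`.
#' @export
fit_simple_ols <- function(Y, x) {
  n <- length(Y)
  stopifnot(length(x) == n, n > 2L)
  xm <- mean(x); ym <- mean(Y)
  sxx <- sum((x - xm)^2)
  if (sxx == 0) stop("degenerate design: constant predictor")
  beta <- sum((x - xm) * (Y - ym)) / sxx
  rss <- sum((Y - ym - beta * (x - xm))^2)
  se <- sqrt(rss / (n - 2) / sxx)
  z <- if (se > 0) beta / se else sign(beta) * Inf
  p <- max(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
  structure(list(beta_hat = beta, se = se, z = z, p_value = p),
            class = "ols_fit")
}

#' Analytic p-value for the linear statistic
#'
#' Normal approximation to the permutation null of `T_L`: the burden score
#' `b_i = sum_j w_j X_ij` is fixed and `Y` permuted, giving the exact
#' permutation-null variance
#' `sd0^2 = sum_i (Y_i - Ybar)^2 * sum_i (b_i - bbar)^2 / (n - 1)`.
#'
#' @param G genotype matrix.
#' @param Y trait vector.
#' @param weights per-variant weights.
#' @return two-sided p-value.
#' @export
analytic_pvalue_linear <- function(G, Y, weights = rep(1, ncol(G))) {
  b <- as.numeric(G %*% weights)
  if (stats::var(b) == 0) stop("degenerate design: constant burden")
  TL <- sum(weights * compute_scores(G, Y))
  n <- length(Y)
  sd0 <- sqrt(sum((Y - mean(Y))^2) * sum((b - mean(b))^2) / (n - 1))
  if (sd0 == 0) return(1)
  max(2 * stats::pnorm(-abs(TL / sd0)), .Machine$double.xmin)
}

# All permutations of 1..n (n <= 8), one per row.
.all_permutations <- function(n) {
  if (n > 8L) stop("exhaustive enumeration limited to n <= 8")
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    idx <- c(seq_len(n)[-k])
    block <- cbind(k, matrix(idx[sub], nrow(sub)))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Permutation p-value for the linear or quadratic statistic
#'
#' Permutes `Y` against the fixed genotype matrix. Extremeness is
#' `|T_L| >= |T_L_obs|` for the linear statistic and `T_Q >= T_Q_obs` for the
#' quadratic one. Monte-Carlo p-values use the add-one convention
#' `p = (1 + #extreme) / (n_perm + 1)` so `p > 0` always; with
#' `exhaustive = TRUE` (n <= 8) all `n!` permutations are enumerated and the
#' p-value is the exact proportion (the identity permutation guarantees
#' `p > 0`).
#'
#' @param G genotype matrix.
#' @param Y trait vector.
#' @param method `"CAST"` (linear) or `"CALPHA"` (quadratic).
#' @param weights linear weights (CAST).
#' @param kernel quadratic kernel (CALPHA), `NULL` = identity.
#' @param n_perm number of random permutations.
#' @param seed integer seed.
#' @param exhaustive enumerate all permutations (requires `n <= 8`).
#' @return p-value in (0, 1].
#' @export
permutation_pvalue <- function(G, Y, method = c("CAST", "CALPHA"),
                               weights = rep(1, ncol(G)), kernel = NULL,
                               n_perm = 1000L, seed = 1L,
                               exhaustive = FALSE) {
  method <- match.arg(method)
  n <- length(Y)
  if (stats::var(Y) == 0) return(1)
  Yc <- Y - mean(Y)
  stat <- function(Sm) {
    if (method == "CAST") abs(as.numeric(crossprod(Sm, weights)))
    else if (is.null(kernel)) colSums(Sm^2)
    else colSums(Sm * (kernel %*% Sm))
  }
  S_obs <- as.numeric(crossprod(G, Yc))
  t_obs <- stat(matrix(S_obs))
  if (exhaustive) {
    P <- .all_permutations(n)
    Yperm <- matrix(Yc[t(P)], nrow = n)        # n x n! columns
    t_perm <- stat(crossprod(G, Yperm))
    return(mean(t_perm >= t_obs - 1e-12))
  }
  stopifnot(n_perm >= 1L)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  Yperm <- vapply(seq_len(n_perm), function(i) Yc[sample.int(n)], numeric(n))
  t_perm <- stat(crossprod(G, Yperm))
  (1 + sum(t_perm >= t_obs - 1e-12)) / (n_perm + 1)
}

#' Specification of one gene-based test
#'
#' @param method `"CMC"`, `"CAST"` or `"CALPHA"`.
#' @param weights per-variant weights (CAST linear statistic).
#' @param kernel quadratic kernel (CALPHA); `NULL` = identity.
#' @param p_method `"analytic"` or `"permutation"`. Defaults: analytic for
#'   CMC/CAST, permutation for CALPHA (the quadratic null is a weighted
#'   chi-square mixture with no convenient closed form).
#' @param n_perm permutations when `p_method = "permutation"`.
#' @param alpha_level two-sided significance level.
#' @return list of class `test_spec`.
#' @export
test_spec <- function(method = c("CMC", "CAST", "CALPHA"), weights = NULL,
                      kernel = NULL, p_method = NULL, n_perm = 1000L,
                      alpha_level = 0.05) {
  method <- match.arg(method)
  if (is.null(p_method))
    p_method <- if (method == "CALPHA") "permutation" else "analytic"
  p_method <- match.arg(p_method, c("analytic", "permutation"))
  if (method == "CALPHA" && p_method == "analytic")
    stop("CALPHA requires permutation calibration")
  structure(list(method = method, weights = weights, kernel = kernel,
                 p_method = p_method, n_perm = as.integer(n_perm),
                 alpha_level = alpha_level),
            class = "test_spec")
}

#' Run a set of gene-based tests on one dataset
#'
#' CMC: Wald test from the closed-form OLS of `Y` on the collapsed genotype.
#' CAST: linear score statistic with analytic (permutation-variance normal
#' approximation) or permutation p-value. CALPHA: quadratic score statistic
#' with permutation p-value. Degenerate designs (e.g. a constant collapsed
#' genotype, possible only in binomial mode) yield a non-significant result
#' flagged `degenerate` rather than an error.
#'
#' @param G genotype matrix.
#' @param Y trait vector.
#' @param specs list of [test_spec()] objects.
#' @param seed seed for permutation p-values.
#' @return list of results, one per spec: `method`, `statistic`, `p_value`,
#'   `significant`, `degenerate`.
#' @export
run_all_tests <- function(G, Y, specs, seed = 1L) {
  stopifnot(length(specs) >= 1L)
  lapply(specs, function(sp) {
    stopifnot(inherits(sp, "test_spec"))
    w <- if (is.null(sp$weights)) rep(1, ncol(G)) else sp$weights
    res <- tryCatch({
      if (sp$method == "CMC") {
        K <- cmc_collapse(G)
        fit <- fit_simple_ols(Y, K)
        list(statistic = fit$z, p_value = fit$p_value)
      } else if (sp$method == "CAST") {
        TL <- linear_statistic(compute_scores(G, Y), w)
        p <- if (sp$p_method == "analytic") analytic_pvalue_linear(G, Y, w)
             else permutation_pvalue(G, Y, "CAST", weights = w,
                                     n_perm = sp$n_perm, seed = seed)
        list(statistic = TL, p_value = p)
      } else {
        TQ <- quadratic_statistic(compute_scores(G, Y), sp$kernel)
        p <- permutation_pvalue(G, Y, "CALPHA", kernel = sp$kernel,
                                n_perm = sp$n_perm, seed = seed)
        list(statistic = TQ, p_value = p)
      }
    }, error = function(e) list(statistic = NA_real_, p_value = 1,
                                degenerate = conditionMessage(e)))
    degen <- !is.null(res$degenerate)
    list(method = sp$method, statistic = res$statistic, p_value = res$p_value,
         significant = !degen && res$p_value < sp$alpha_level,
         degenerate = degen)
  })
}
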