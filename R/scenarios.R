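#' Define a simulation scenario for a pooled rare-variant gene
#'
#' A scenario bundles everything needed to simulate one gene region: the
#' per-variant minor-allele counts (out of `2n` chromosomes), the per-variant
#' trait effects per carrier, and the trait-model parameters of the linear
#' model `Y_i = alpha + sum_j beta_j X_ij + eps_i` with normal errors.
#'
#' Genotypes are carrier indicators (0/1): at the allele frequencies studied
#' here (MAF < 1%) homozygous-rare genotypes are vanishingly unlikely, so a
#' subject either carries one copy of the minor allele or none.
#'
#' @param label scenario name.
#' @param allele_counts integer vector, minor-allele count of each variant
#'   among the `2n` chromosomes of the cohort.
#' @param effects numeric vector, trait change per carrier for each variant
#'   (`beta_j`); zero marks a non-causal variant.
#' @param n number of subjects.
#' @param intercept trait intercept `alpha`.
#' @param error_sd residual standard deviation `sigma` (> 0, or 0 for
#'   noise-free checks).
#' @param genotype_mode `"fixed_disjoint"` places each variant's carriers on
#'   distinct subjects so that column sums equal the allele counts exactly and
#'   no subject carries two variants (the regime real rare-variant data are
#'   close to); `"binomial"` draws each carrier indicator independently with
#'   probability `1 - (1 - q_j)^2`.
#' @param alpha_level two-sided significance level used by the tests.
#' @return An object of class `gene_scenario`.
#' @seealso [builtin_scenarios()], [generate_genotypes()], [simulate_trait()]
#' @export
gene_scenario <- function(label, allele_counts, effects, n = 321L,
                          intercept = 0, error_sd = 1,
                          genotype_mode = c("fixed_disjoint", "binomial"),
                          alpha_level = 0.05) {
  genotype_mode <- match.arg(genotype_mode)
  allele_counts <- as.integer(allele_counts)
  effects <- as.numeric(effects)
  stopifnot(length(allele_counts) == length(effects),
            length(allele_counts) >= 1L)
  if (n <= 0L) stop("n must be positive")
  if (any(allele_counts < 0L) || any(allele_counts > 2L * n))
    stop("allele counts must lie in [0, 2n]")
  if (!all(is.finite(effects))) stop("effects must be finite")
  if (!is.finite(error_sd) || error_sd < 0) stop("error_sd must be >= 0")
  if (alpha_level <= 0 || alpha_level >= 1) stop("alpha_level must be in (0, 1)")
  if (genotype_mode == "fixed_disjoint" && sum(allele_counts) > n)
    stop("fixed_disjoint design infeasible: total carrier count exceeds n")
  structure(list(
    label = label,
    n = as.integer(n),
    allele_counts = allele_counts,
    effects = effects,
    variant_labels = paste0("v", seq_along(effects)),
    intercept = intercept,
    error_sd = error_sd,
    genotype_mode = genotype_mode,
    alpha_level = alpha_level
  ), class = "gene_scenario")
}

#' @export
print.gene_scenario <- function(x, ...) {
  cat(sprintf("gene_scenario '%s': n = %d, J = %d variants (%s mode)\n",
              x$label, x$n, length(x$effects), x$genotype_mode))
  cat(sprintf("  causal: %d of %d; beta_AGE = %.4f; sigma = %g\n",
              sum(x$effects != 0), length(x$effects),
              beta_age_theoretical(x$effects, x$allele_counts), x$error_sd))
  invisible(x)
}

#' Minor allele frequencies of a scenario
#'
#' @param scenario a [gene_scenario()].
#' @return numeric vector `q_j = allele_count_j / (2n)`.
#' @export
scenario_mafs <- function(scenario) {
  scenario$allele_counts / (2 * scenario$n)
}

# Effect vectors of the six study scenarios. Variant 10 (and 8 in the
# many-causal setting) flips sign in the bidirectional versions.
.builtin_counts <- c(1L, 3L, 2L, 1L, 1L, 1L, 1L, 1L, 2L, 1L, 3L)

.builtin_effects <- function(label) {
  e <- switch(label,
    table1 = c(0, 0, 0.83, 0.97, 0, 0, 0, 0, 0, 0.93, 0.53),
    table2 = c(0, 0, 0.83, 2.0, 0, 0, 0, 0, 0, 3.0, 0.53),
    table3 = c(0, 0.97, 0.83, 0.97, 0.83, 0, 0, 0.93, 0.53, 0.93, 0.53),
    null   = rep(0, 11))
  e
}

#' The built-in study scenarios
#'
#' Returns the six scenarios of the simulation study plus a global null.
#' All share `n = 321` subjects and `J = 11` rare variants with allele counts
#' `[1,3,2,1,1,1,1,1,2,1,3]` out of 642 chromosomes, intercept 0, residual SD
#' 1 and a two-sided 0.05 test level. The three effect configurations are:
#'
#' * `table1_*`: four causal variants, effects 0.83, 0.97, 0.93, 0.53;
#' * `table2_*`: same causal set with two very large effects (2.0, 3.0);
#' * `table3_*`: eight causal variants, effects between 0.53 and 0.97.
#'
#' Each comes in a unidirectional (`_uni`) version and a bidirectional (`_bi`)
#' version in which variant 10's effect (and variant 8's, in `table3_bi`) is
#' sign-flipped. `null` has all effects zero (type-I error checks).
#'
#' @return named list of [gene_scenario()] objects.
#' @export
builtin_scenarios <- function() {
  mk <- function(lab, eff) gene_scenario(lab, .builtin_counts, eff)
  t1 <- .builtin_effects("table1"); t2 <- .builtin_effects("table2")
  t3 <- .builtin_effects("table3")
  t1b <- t1; t1b[10] <- -t1b[10]
  t2b <- t2; t2b[10] <- -t2b[10]
  t3b <- t3; t3b[8] <- -t3b[8]; t3b[10] <- -t3b[10]
  list(
    table1_uni = mk("table1_uni", t1),
    table1_bi  = mk("table1_bi",  t1b),
    table2_uni = mk("table2_uni", t2),
    table2_bi  = mk("table2_bi",  t2b),
    table3_uni = mk("table3_uni", t3),
    table3_bi  = mk("table3_bi",  t3b),
    null       = mk("null", .builtin_effects("null"))
  )
}

#' Generate a carrier-indicator genotype matrix
#'
#' In `fixed_disjoint` mode each variant's `allele_count_j` carriers are
#' assigned to distinct subjects (no subject carries more than one variant)
#' and the row order is then permuted with the seed, so column sums equal the
#' allele counts exactly in every realisation. In `binomial` mode each entry
#' is an independent carrier draw with probability `1 - (1 - q_j)^2`.
#'
#' @param scenario a [gene_scenario()].
#' @param seed integer seed; the same seed reproduces the matrix bit-exactly.
#' @return integer matrix `n x J` of 0/1 carrier indicators, columns named by
#'   variant label.
#' @export
generate_genotypes <- function(scenario, seed) {
  stopifnot(inherits(scenario, "gene_scenario"))
  n <- scenario$n
  J <- length(scenario$allele_counts)
  counts <- scenario$allele_counts
  G <- matrix(0L, n, J, dimnames = list(NULL, scenario$variant_labels))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  if (scenario$genotype_mode == "fixed_disjoint") {
    if (sum(counts) > n)
      stop("fixed_disjoint design infeasible: total carrier count exceeds n")
    row <- 0L
    for (j in seq_len(J)) {
      if (counts[j] > 0L) {
        G[row + seq_len(counts[j]), j] <- 1L
        row <- row + counts[j]
      }
    }
    G <- G[sample.int(n), , drop = FALSE]
  } else {
    q <- counts / (2 * n)
    p_carrier <- 1 - (1 - q)^2
    for (j in seq_len(J))
      G[, j] <- stats::rbinom(n, 1L, p_carrier[j])
  }
  G
}

#' Simulate a quantitative trait from the genotype matrix
#'
#' Draws `Y_i = alpha + sum_j beta_j X_ij + eps_i` with independent
#' `eps_i ~ N(0, sigma^2)`.
#'
#' @param G genotype matrix from [generate_genotypes()].
#' @param scenario the [gene_scenario()] providing `alpha`, `beta_j`, `sigma`.
#' @param seed integer seed.
#' @return numeric vector of length `n`.
#' @export
simulate_trait <- function(G, scenario, seed) {
  stopifnot(inherits(scenario, "gene_scenario"),
            nrow(G) == scenario$n,
            ncol(G) == length(scenario$effects))
  if (scenario$error_sd < 0) stop("error_sd must be >= 0")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  eps <- if (scenario$error_sd > 0)
    stats::rnorm(scenario$n, 0, scenario$error_sd) else numeric(scenario$n)
  as.numeric(scenario$intercept + G %*% scenario$effects + eps)
}

# Save/restore the caller's RNG state so seeded generators are side-effect free.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
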