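#' Theoretical average genetic effect (AGE) of a pooled variant set
#'
#' Under CMC collapsing of `J` rare variants, the slope of the trait on the
#' carrier indicator is the MAF-weighted mean of the per-variant effects,
#' `beta_AGE = sum_j beta_j q_j / sum_j q_j`. Allele counts are proportional
#' to the MAFs, so counts can be passed directly.
#'
#' @param effects per-variant effects `beta_j` (zero for null variants).
#' @param counts per-variant minor-allele counts (or any vector proportional
#'   to the MAFs).
#' @return scalar `beta_AGE`.
#' @export
beta_age_theoretical <- function(effects, counts) {
  stopifnot(length(effects) == length(counts), all(counts >= 0),
            all(is.finite(effects)))
  if (sum(counts) == 0) stop("empty gene: all allele counts zero")
  sum(effects * counts) / sum(counts)
}

#' AGE restricted to the causal variants
#'
#' Same MAF-weighted mean, over the variants with nonzero effect only. This
#' is the quantity the pooled `beta_AGE` is attenuated towards when null
#' variants are included; with bidirectional effects it is itself smaller
#' than the mean effect magnitude.
#'
#' @inheritParams beta_age_theoretical
#' @return scalar.
#' @export
beta_age_causal <- function(effects, counts) {
  causal <- effects != 0
  if (!any(causal)) stop("no causal variants: causal AGE undefined")
  beta_age_theoretical(effects[causal], counts[causal])
}

#' Genetic variance of the pooled causal effects
#'
#' `sigma_G^2 = Var(sum_j beta_j X_j)` for carrier indicators `X_j`. Under
#' independent carriers (`binomial` mode) this is `sum_j beta_j^2 p_j (1-p_j)`;
#' under disjoint carriers (`fixed_disjoint` mode) the indicators are
#' mutually exclusive and the variance is
#' `sum_j p_j beta_j^2 - (sum_j p_j beta_j)^2`.
#'
#' @param effects per-variant effects.
#' @param carrier_probs per-variant carrier probabilities `p_j`.
#' @param mode `"binomial"` or `"fixed_disjoint"`.
#' @return scalar variance (trait units squared).
#' @export
genetic_variance <- function(effects, carrier_probs,
                             mode = c("fixed_disjoint", "binomial")) {
  mode <- match.arg(mode)
  stopifnot(length(effects) == length(carrier_probs),
            all(carrier_probs >= 0), all(carrier_probs <= 1))
  if (mode == "binomial")
    sum(effects^2 * carrier_probs * (1 - carrier_probs))
  else
    sum(carrier_probs * effects^2) - sum(carrier_probs * effects)^2
}

#' Magnitude-based bias of a conditional effect estimate
#'
#' `bias = |conditional mean| - |true effect|`: positive values mean the
#' post-selection estimate moved *away* from zero (the winner's curse),
#' negative values mean shrinkage *towards* zero (the signature of a
#' minority-direction variant under linear-test conditioning).
#' `rel_bias = bias / |true effect|`.
#'
#' @param conditional_mean mean of the estimate over significant replicates.
#' @param true_effect the true `beta` (nonzero for `rel_bias`).
#' @return list with `bias_magnitude` and `rel_bias` (`NA` with a flag when
#'   the true effect is zero).
#' @export
bias_metrics <- function(conditional_mean, true_effect) {
  bias <- abs(conditional_mean) - abs(true_effect)
  if (true_effect == 0)
    return(list(bias_magnitude = bias, rel_bias = NA_real_,
                undefined_rel_bias = TRUE))
  list(bias_magnitude = bias, rel_bias = bias / abs(true_effect),
       undefined_rel_bias = FALSE)
}
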