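---
title: "Winner's curse and effect heterogeneity in pooled rare-variant analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Winner's curse and effect heterogeneity in pooled rare-variant analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvcurse)
```

## The estimation problem

Individual rare variants (minor allele frequency below ~1%) are essentially
untestable one at a time: a cohort of a few hundred subjects contains a
handful of carriers per variant. Gene-based tests therefore pool the
association evidence across the $J$ variants of a gene. Writing $Y_i$ for the
quantitative trait and $X_{ij} \in \{0, 1\}$ for the carrier indicator of
variant $j$ in subject $i$, the per-variant score is

$$S_j = \sum_i (Y_i - \bar{Y})\, X_{ij},$$

and the two classical test families aggregate the scores linearly,
$T_L = \sum_j w_j S_j$ (the burden family; CAST is the equal-weight member),
or quadratically, $T_Q = S^\top A S$ (the variance-component family; C-Alpha
is the identity-kernel member). Linear tests are powerful when effects share
a direction and lose power when they oppose; quadratic tests square the
scores and are direction-robust. A third approach, CMC collapsing, codes the
gene as a single indicator $K(X_i) = I(\sum_j X_{ij} > 0)$ and regresses the
trait on it; its Wald test behaves like a linear test.

After a significant gene-level result, the slope of that collapsed
regression — the *average genetic effect* (AGE) — is the natural pooled
effect-size summary. Under the carrier model with per-variant effects
$\beta_j$ and MAFs $q_j$, the AGE is the MAF-weighted mean

$$\beta_{AGE} = \frac{\sum_{j} \beta_j q_j}{\sum_{j} q_j},$$

which two distinct phenomena pull in opposite directions:

* **downward**, before any testing: null variants and opposing effect
  directions dilute the weighted mean ($\beta_{AGE}$ is far below the mean
  causal effect magnitude), and
* **upward**, after testing: averaging the estimate only over datasets in
  which the gene reached significance inflates it — the winner's curse.

`rvcurse` simulates both phenomena and implements two corrections for the
second.

## The synthetic cohort

The generator emulates a small exome gene in a cohort of $n = 321$ subjects
with $J = 11$ rare variants whose minor-allele counts are
$[1,3,2,1,1,1,1,1,2,1,3]$ out of $2n = 642$ chromosomes. Allele *counts*
rather than rounded frequencies are the primitive: the corresponding MAFs
$k/642$ reproduce all published AGE values exactly, whereas two-significant-
figure MAFs happen to agree only after rounding (0.3024 vs 0.3029 in the
four-causal unidirectional setting). Six effect configurations are built in
(`builtin_scenarios()`): four causal variants with effects 0.53–0.97, the
same set with two very large effects (2.0, 3.0), and an eight-causal
version; each in a unidirectional variant and a bidirectional variant with
the minority effect(s) sign-flipped. The trait is
$Y_i = \alpha + \sum_j \beta_j X_{ij} + \varepsilon_i$ with
$\varepsilon_i \sim N(0, \sigma^2)$.

Two defaults deserve justification because the underlying exome resource
does not pin them down:

* **$\sigma = 1$, $\alpha = 0$.** The residual scale only matters through
  the standardized effect $\mu = \beta_{AGE}/SE(\hat\beta)$. With 17
  carriers among 321 subjects, $SE(\hat\beta) \approx
  1/\sqrt{n p (1-p)} \approx 0.25$, close to the ~0.27 empirical spread the
  original cohort exhibits; $\sigma = 1$ is the parsimonious choice.
* **`fixed_disjoint` genotype mode (default).** Each variant's carriers are
  assigned to distinct subjects and rows are then permuted. At these
  frequencies the probability of a double carrier is $O(q^2) \approx
  10^{-5}$ per pair, so disjointness is what real data look like, and it
  guarantees column sums equal the allele counts in every replicate (the
  collapsed genotype is never degenerate). A `binomial` mode with
  independent carrier draws is kept for robustness checks.

What the surrogate does **not** emulate: the genotype configuration of a
real exome region (linkage, relatedness, occasional carrier overlap). In
the original data this configuration pushed the unconditional AGE estimate
to 0.34 against the theoretical 0.30; the disjoint-carrier surrogate is
exactly calibrated to the theoretical value. Consequently conditional means
reproduce the published ones only to within about ±0.05, and the published
power values (26.4%, 12.7%, ...) are matched directionally, not digit by
digit. Passing tests demonstrate the estimator and correction behaviour
under the idealized carrier structure, not equivalence with any particular
real genotype panel.

## Testing choices

* CMC significance uses the Wald $z = \hat\beta/\widehat{SE}$ with a
  standard-normal reference: $n = 321$ is large and the downstream
  correction machinery models $Z \sim N(\mu, 1)$.
* CAST's default calibration is analytic: permuting $Y$ against a fixed
  burden $b_i = \sum_j w_j X_{ij}$ gives the exact null variance
  $\mathrm{Var}_0(T_L) = \sum_i (Y_i-\bar Y)^2 \sum_i (b_i-\bar b)^2/(n-1)$,
  and $T_L$ is a sum over ~17 carrier terms, close enough to normal at this
  size (verified against exhaustive and Monte-Carlo permutation in the
  tests).
* C-Alpha's null is a weighted mixture of chi-squares with no convenient
  closed form, so its default is the permutation p-value with 1,000
  permutations and the add-one convention $(1 + \#extreme)/(n_{perm}+1)$.
  For $n \le 8$ an exhaustive mode enumerates all $n!$ permutations
  exactly.
* All tests are two-sided at $\alpha = 0.05$ — deliberately liberal: power
  at this sample size is low, and selection bias grows as power falls,
  which is the phenomenon under study.
* Equal weights throughout; generic weight vectors and PSD kernels are
  accepted but no MAF-adaptive weighting scheme is tuned.

## The two corrections

**Out-of-bag bootstrap.** Resample $n$ subjects with replacement; when the
gene-based test is significant *in the resample*, record the in-bag
collapsed slope $\hat\beta_D$ (which inherits the selection bias) and the
slope $\hat\beta_E$ fitted on the subjects left out of the resample (no
selection applied). The center of the collected $\hat\beta_D - \hat\beta_E$
differences estimates the selection bias and is subtracted from the naive
estimate. Defaults: $B = 100$ significant pairs, a 10,000-draw cap, and
*median* centering (the mean variant is available and agrees within
Monte-Carlo error in these scenarios — a property the test suite checks).
Draws with a degenerate in-bag or out-of-bag design are skipped and
counted; if fewer than $B$ pairs accrue the result is flagged
`low_confidence` rather than silently accepted.

**Conditional likelihood.** Model the reported statistic as
$Z \sim N(\mu, 1)$ observed only when $|Z| > c$, with
$c = \Phi^{-1}(1-\alpha/2)$ derived from the significance level, never
hard-coded. The conditional density is

$$p_\mu(z) = \frac{\phi(z-\mu)}{\Phi(\mu-c) + \Phi(-\mu-c)}, \qquad |z| > c,$$

and the corrected estimate is $\hat\mu \cdot \widehat{SE}$ where $\hat\mu$
maximizes $p_\mu(z)$ over $\mu$. The denominator is the only reading of the
truncation constant that makes $p_\mu$ integrate to one over
$\{|z| > c\}$ (verified by quadrature in the tests). The maximizer is
bracketed on $\mathrm{sign}(z)\,[0, |z|]$ — the conditional MLE can neither
exceed the observation in magnitude nor flip its sign — located by a
201-point grid and refined by golden-section search to $10^{-6}$, with the
boundary $\mu = 0$ checked explicitly (for $z$ barely past $c$ the
likelihood is maximized at zero). Behaviour exactly at $|z| = c$ is treated
as out of support. This correction needs only $(\hat\beta, SE, \alpha)$, so
it applies to published summary statistics (`correct_summary()`).

**Conditional confidence intervals.** The acceptance region of the
conditional law is inverted: the interval is the set of $\mu$ whose
conditional $\alpha/2$ and $1-\alpha/2$ quantiles bracket the observed $z$,
found by root-finding on the conditional CDF, which is monotone in $\mu$
(bracket doubled up to a hard cap before declaring failure). With $c = 0$
this collapses to the usual Wald interval, and its conditional coverage is
checked by simulation at $\mu \in \{0, 0.5, 1, 2\}$.

## Study runner and its conventions

`run_study()` loops scenarios × replicates. Per-replicate seeds are drawn
from the master seed, and each replicate derives four sub-seeds (genotype,
trait, permutation, bootstrap), so any single replicate can be reproduced in
isolation; a JSON manifest records the scheme. Conventions adopted where the
presentation could go either way:

* Corrections are conditioned on the *CMC* test (the pooled-estimate
  tables); per-variant conditional summaries are produced under all three
  tests' conditioning (the individual-effect table).
* Conditional "SE"s reported alongside conditional means are empirical SDs
  across the significant replicates.
* Power denominators are always the full replicate count, including
  flagged degenerate replicates (possible only in binomial mode).
* Per-variant bias uses the magnitude convention: `bias =
  |conditional mean| − |truth|`, so positive is away from zero regardless
  of the effect's sign, and `rel_bias = bias/|truth|`.

## Problem sizes

The shipped analysis scripts and the acceptance computation use 2,000
replicates per scenario, which puts the Monte-Carlo SE of a conditional
mean near 0.01 and completes in minutes on one CPU. The test suite reuses
cached 2,000-replicate studies for the distributional checks and small
replicate counts for structural checks; coverage experiments use 2,000
conditional draws per $\mu$ (binomial 3-SE bands).

## Known limitations

* The surrogate carrier structure cannot reproduce genotype-configuration
  effects (e.g. the 0.34-vs-0.30 unconditional offset of the original
  cohort); comparisons to the published conditional means carry a ±0.05
  design slack.
* Selection is modelled on a single gene-level test; multi-gene,
  genome-wide selection events and replication-study planning are out of
  scope.
* No covariates, relatedness, population structure or binary traits.
* Bootstrap standard errors (a two-level resampling scheme) are not
  implemented; only point corrections plus conditional-likelihood
  intervals.
* For extremely rare alleles the out-of-bag split can lose all carriers;
  such draws are skipped and counted, but no stratified resampling is
  attempted.
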