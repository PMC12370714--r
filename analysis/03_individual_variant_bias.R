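#!/usr/bin/env Rscript
# Per-variant effect estimates conditional on significant gene-based testing:
# recomputes the individual-variant bias tables from the per-replicate
# records persisted by 02_age_estimation_study.R (no re-simulation), one
# panel per conditioning test, and reports the sign pattern of the relative
# bias. Run 02 first.

suppressPackageStartupMessages(library(rvcurse))

rep_dir <- "results/study"
labs <- c("table1_uni", "table1_bi")
sc <- builtin_scenarios()

for (lab in labs) {
  path <- file.path(rep_dir, paste0("replicates_", lab, ".tsv"))
  if (!file.exists(path))
    stop("missing ", path, " - run analysis/02_age_estimation_study.R first")
  df <- read_tsv(path)
  cat("\n====", lab, "====\n")
  for (m in c("cmc", "cast", "calpha")) {
    tab <- summarize_bias(df, sc[[lab]], paste0("sig_", m))
    tab[, c("beta_all", "beta_naive", "bias", "rel_bias")] <-
      round(tab[, c("beta_all", "beta_naive", "bias", "rel_bias")], 2)
    cat("\nConditioning on", toupper(m), "significance",
        sprintf("(%d of %d replicates):\n", tab$n_sig[1], nrow(df)))
    print(tab[, c("variant", "true_beta", "beta_all", "beta_naive",
                  "bias", "rel_bias")], row.names = FALSE)
    write_tsv(tab, file.path(rep_dir,
                             sprintf("variant_bias_%s_%s.tsv", lab, m)))
  }
}

cat("\nExpected pattern: in the unidirectional scenario every causal variant\n")
cat("is inflated (positive rel_bias) under all three tests. In the\n")
cat("bidirectional scenario the minority-direction variant (v10) shows\n")
cat("negative rel_bias (shrinkage toward zero) under the linear tests\n")
cat("(CMC, CAST) but positive rel_bias under the quadratic C-Alpha test,\n")
cat("whose squared scores reward large effects of either sign.\n")
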