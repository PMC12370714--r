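#!/usr/bin/env Rscript
# Main simulation study: for each of the six scenarios, 2,000 replicates of
# the n = 321 cohort; CMC / CAST / C-Alpha gene-based tests; naive,
# bootstrap-corrected and likelihood-corrected AGE estimates conditional on
# CMC significance. Writes per-replicate records, the power table and the
# AGE summary (the machine-readable analogues of the study's main tables)
# under results/study/.
#
# Runtime: a few minutes on one CPU. Set RVCURSE_REPLICATES to run smaller.

suppressPackageStartupMessages(library(rvcurse))

R <- as.integer(Sys.getenv("RVCURSE_REPLICATES", "2000"))
cfg <- study_config(
  c("table1_uni", "table1_bi", "table2_uni", "table2_bi",
    "table3_uni", "table3_bi"),
  replicates = R, master_seed = 20260922L,
  output_dir = "results/study")

summary <- run_study(cfg)
print(summary)

cat("\nReading of the AGE table: 'all' is unbiased (close to beta_age_true);\n")
cat("'naive' is inflated by the winner's curse, most strongly where power\n")
cat("is lowest; 'boot' and 'like' pull the conditional mean back toward\n")
cat("the truth at the cost of a larger spread.\n")
cat("\nOutputs written under results/study/ (per-replicate TSVs, power.tsv,\n")
cat("age_summary.tsv, per-variant bias tables, manifest.json).\n")
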