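#!/usr/bin/env Rscript
# Distribution of the AGE estimate before and after selection/correction for
# the four-causal scenarios: histograms of the 2,000 per-replicate estimates
# with vertical lines at the truth, the naive conditional mean and the two
# corrected means. Reads the per-replicate records from 02; writes
# results/estimate_distributions.pdf.

suppressPackageStartupMessages({
  library(rvcurse)
  library(ggplot2)
})

sc <- builtin_scenarios()
labs <- c("table1_uni", "table1_bi")
panels <- list()
for (lab in labs) {
  path <- file.path("results/study", paste0("replicates_", lab, ".tsv"))
  if (!file.exists(path))
    stop("missing ", path, " - run analysis/02_age_estimation_study.R first")
  df <- read_tsv(path)
  sig <- df$sig_cmc
  panels[[lab]] <- data.frame(
    scenario = lab, beta = df$beta_age,
    selected = ifelse(sig, "significant", "not significant"))
  attr(panels[[lab]], "lines") <- data.frame(
    scenario = lab,
    what = c("truth", "naive", "boot", "like"),
    at = c(beta_age_theoretical(sc[[lab]]$effects, sc[[lab]]$allele_counts),
           mean(df$beta_age[sig]), mean(df$beta_boot[sig]),
           mean(df$beta_like[sig])))
}
dat <- do.call(rbind, panels)
lines <- do.call(rbind, lapply(panels, attr, "lines"))

p <- ggplot(dat, aes(beta, fill = selected)) +
  geom_histogram(bins = 50, alpha = 0.7, position = "identity") +
  geom_vline(data = lines, aes(xintercept = at, colour = what),
             linewidth = 0.7) +
  facet_wrap(~scenario, ncol = 1) +
  labs(x = "collapsed-genotype AGE estimate", y = "replicates",
       colour = NULL, fill = NULL) +
  theme_minimal()

ggsave("results/estimate_distributions.pdf", p, width = 7, height = 6)
cat("wrote results/estimate_distributions.pdf\n")
print(lines, row.names = FALSE)
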