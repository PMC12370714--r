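# Shared fixtures and a cache for the large simulation runs so that several
# test files can reuse the same 2,000-replicate studies.

.run_cache <- new.env(parent = emptyenv())

cached_run <- function(key, expr) {
  if (!exists(key, envir = .run_cache, inherits = FALSE))
    assign(key, expr, envir = .run_cache)
  get(key, envir = .run_cache, inherits = FALSE)
}

# Table-1 unidirectional scenario, full study with corrections and
# per-variant estimates (CMC/CAST analytic, C-Alpha permutation).
study_t1_uni <- function() cached_run("t1_uni", {
  run_study(study_config("table1_uni", replicates = 2000L,
                         master_seed = 4801L))
})

# Bidirectional counterpart (variant 10 sign-flipped).
study_t1_bi <- function() cached_run("t1_bi", {
  run_study(study_config("table1_bi", replicates = 2000L,
                         master_seed = 4802L))
})

# Global null, all three tests, no corrections (type-I error).
study_null <- function() cached_run("null", {
  run_study(study_config("null", replicates = 2000L, master_seed = 4803L,
                         correct = FALSE, per_variant = FALSE))
})

# Unconditional AGE moments for all six effect scenarios (CMC only, no
# corrections: only the collapsed-genotype fit is needed).
study_unconditional <- function() cached_run("uncond", {
  run_study(study_config(
    c("table1_uni", "table1_bi", "table2_uni", "table2_bi",
      "table3_uni", "table3_bi"),
    replicates = 2000L, master_seed = 4810L,
    tests = list(CMC = test_spec("CMC")),
    correct = FALSE, per_variant = FALSE))
})

# A tiny two-variant scenario for cheap structural checks.
tiny_scenario <- function(n = 12L, counts = c(2L, 1L), effects = c(1, 0),
                          error_sd = 1, mode = "fixed_disjoint") {
  gene_scenario("tiny", counts, effects, n = n, error_sd = error_sd,
                genotype_mode = mode)
}

# Brute-force grid oracle for the conditional MLE (step 1e-4), independent
# of the golden-section implementation path.
grid_mle_oracle <- function(z, c0, step = 1e-4) {
  mus <- seq(0, abs(z), by = step) * sign(z)
  ll <- stats::dnorm(z - mus, log = TRUE) -
    log(stats::pnorm(mus - c0) + stats::pnorm(-mus - c0))
  mus[which.max(ll)]
}

# Draw m observations of Z ~ N(mu, 1) conditional on |Z| > c.
rcond_z <- function(m, mu, c0) {
  out <- numeric(0)
  while (length(out) < m) {
    z <- stats::rnorm(4 * m, mu, 1)
    out <- c(out, z[abs(z) > c0])
  }
  out[seq_len(m)]
}

# Minimal uncompressed VCF fixture written to a temp file.
write_vcf_fixture <- function(path, extra_records = character(0)) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           "S1\tS2\tS3\tS4"),
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1\t./.",
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t0/0\t0/0\t0/1\t0/0",
    "1\t300\trs3\tG\tA\t.\tPASS\t.\tGT\t1|0\t0/0\t0/0\t0/0",
    extra_records)
  writeLines(lines, path)
  path
}
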