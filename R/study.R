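#' Configuration of a simulation study
#'
#' @param scenarios character vector of scenario labels resolved against
#'   [builtin_scenarios()], or a named list of [gene_scenario()] objects.
#' @param replicates number of simulation replicates per scenario.
#' @param master_seed integer; per-replicate seeds are derived from it so any
#'   replicate is individually reproducible.
#' @param tests list of [test_spec()] objects (default: CMC + CAST analytic,
#'   CALPHA with 1000 permutations).
#' @param bootstrap list with `B`, `max_draws`, `center` for
#'   [bootstrap_correct()].
#' @param correct logical; run the two corrections on CMC-significant
#'   replicates.
#' @param per_variant logical; record single-variant OLS estimates.
#' @param output_dir optional directory for per-replicate and summary TSVs
#'   plus a run manifest.
#' @return list of class `study_config`.
#' @export
study_config <- function(scenarios = "table1_uni", replicates = 2000L,
                         master_seed = 1L, tests = default_test_specs(),
                         bootstrap = list(B = 100L, max_draws = 10000L,
                                          center = "median"),
                         correct = TRUE, per_variant = TRUE,
                         output_dir = NULL) {
  stopifnot(replicates >= 1L)
  if (is.character(scenarios)) {
    builtin <- builtin_scenarios()
    missing <- setdiff(scenarios, names(builtin))
    if (length(missing))
      stop("unknown scenario label(s): ", paste(missing, collapse = ", "))
    scenarios <- builtin[scenarios]
  }
  stopifnot(all(vapply(scenarios, inherits, logical(1), "gene_scenario")))
  structure(list(scenarios = scenarios, replicates = as.integer(replicates),
                 master_seed = as.integer(master_seed), tests = tests,
                 bootstrap = bootstrap, correct = correct,
                 per_variant = per_variant, output_dir = output_dir),
            class = "study_config")
}

#' Default test battery: CMC, CAST (analytic), C-Alpha (permutation)
#'
#' @param alpha_level two-sided level shared by the three tests.
#' @param n_perm permutations for the C-Alpha null.
#' @return list of [test_spec()] objects named by method.
#' @export
default_test_specs <- function(alpha_level = 0.05, n_perm = 1000L) {
  list(CMC = test_spec("CMC", alpha_level = alpha_level),
       CAST = test_spec("CAST", alpha_level = alpha_level),
       CALPHA = test_spec("CALPHA", n_perm = n_perm,
                          alpha_level = alpha_level))
}

# Derive independent sub-seeds (genotype, trait, permutation, bootstrap)
# from one replicate seed; all below 2^31.
.derive_seeds <- function(seed, k = 4L) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, k)
}

#' Run one simulation replicate
#'
#' Generates genotypes and trait, runs the test battery, fits the collapsed
#' (AGE) regression and the single-variant regressions, and — when the CMC
#' test is significant — applies the bootstrap and conditional-likelihood
#' corrections to the AGE estimate.
#'
#' @param scenario a [gene_scenario()].
#' @param rep_seed integer seed for this replicate.
#' @param tests list of [test_spec()] objects.
#' @param bootstrap bootstrap settings (see [study_config()]).
#' @param correct apply corrections when CMC is significant.
#' @param per_variant record per-variant OLS slopes.
#' @return named list: per-test `p_value`/`significant`, `beta_age`, `se_age`,
#'   corrected estimates (`NA` unless CMC-significant), per-variant slopes.
#' @export
run_replicate <- function(scenario, rep_seed, tests = default_test_specs(),
                          bootstrap = list(B = 100L, max_draws = 10000L,
                                           center = "median"),
                          correct = TRUE, per_variant = TRUE) {
  seeds <- .derive_seeds(rep_seed)
  G <- generate_genotypes(scenario, seeds[1])
  Y <- simulate_trait(G, scenario, seeds[2])
  results <- run_all_tests(G, Y, tests, seed = seeds[3])
  names(results) <- vapply(results, `[[`, character(1), "method")

  K <- cmc_collapse(G)
  degen <- sum(K) == 0L || sum(K) == length(K)
  if (degen) {
    age <- list(beta_hat = NA_real_, se = NA_real_, z = NA_real_, p_value = 1)
  } else age <- fit_simple_ols(Y, K)

  rec <- list(rep_seed = rep_seed, degenerate = degen,
              beta_age = age$beta_hat, se_age = age$se, p_cmc = age$p_value)
  for (m in names(results)) {
    rec[[paste0("p_", tolower(m))]] <- results[[m]]$p_value
    rec[[paste0("sig_", tolower(m))]] <- results[[m]]$significant
  }

  rec$beta_boot <- NA_real_
  rec$beta_like <- NA_real_
  cmc_sig <- !degen && !is.null(results$CMC) && results$CMC$significant
  if (correct && cmc_sig) {
    cmc_spec <- tests[[which(vapply(tests, `[[`, character(1),
                                    "method") == "CMC")[1]]]
    alpha <- cmc_spec$alpha_level
    bc <- bootstrap_correct(G, Y, age$beta_hat, alpha_level = alpha,
                            B = bootstrap$B, max_draws = bootstrap$max_draws,
                            center = bootstrap$center, seed = seeds[4])
    rec$beta_boot <- bc$beta_corrected
    rec$boot_pairs <- bc$diagnostics$pairs
    lc <- likelihood_correct(age$beta_hat, age$se, alpha_level = alpha)
    rec$beta_like <- lc$beta_corrected
  }

  if (per_variant) {
    slopes <- vapply(seq_len(ncol(G)), function(j) {
      x <- G[, j]
      if (sum(x) == 0L || sum(x) == length(x)) return(NA_real_)
      fit_simple_ols(Y, x)$beta_hat
    }, numeric(1))
    names(slopes) <- colnames(G)
    rec$variant_betas <- slopes
  }
  rec
}

#' Run a full simulation study
#'
#' Loops [run_replicate()] over scenarios and replicates, persists the
#' per-replicate records, and summarizes: power per test, unconditional
#' moments of the AGE estimate, conditional (CMC-significant) moments of the
#' naive / bootstrap-corrected / likelihood-corrected estimates, and the
#' per-variant conditional means under each test's conditioning with their
#' bias decomposition.
#'
#' @param config a [study_config()].
#' @return list of class `study_summary` with elements `age` (one data frame
#'   row per scenario x estimator), `power` (scenario x method), and
#'   `variant_bias` (per scenario, per conditioning method data frames);
#'   `replicates` holds the per-replicate data frames.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$master_seed)
  n_scen <- length(config$scenarios)
  seed_mat <- matrix(sample.int(.Machine$integer.max - 1L,
                                n_scen * config$replicates),
                     nrow = config$replicates)
  out_reps <- list(); age_rows <- list(); power_rows <- list()
  bias_tabs <- list()
  methods <- vapply(config$tests, `[[`, character(1), "method")

  for (s in seq_len(n_scen)) {
    scen <- config$scenarios[[s]]
    recs <- lapply(seq_len(config$replicates), function(r)
      run_replicate(scen, seed_mat[r, s], tests = config$tests,
                    bootstrap = config$bootstrap, correct = config$correct,
                    per_variant = config$per_variant))
    df <- .records_to_df(recs)
    out_reps[[scen$label]] <- df

    truth <- beta_age_theoretical(scen$effects, scen$allele_counts)
    sig_cmc <- df$sig_cmc %in% TRUE
    age_rows[[scen$label]] <- data.frame(
      scenario = scen$label, beta_age_true = truth,
      estimator = c("all", "naive", "boot", "like"),
      mean = c(mean(df$beta_age, na.rm = TRUE),
               mean(df$beta_age[sig_cmc]),
               mean(df$beta_boot[sig_cmc]),
               mean(df$beta_like[sig_cmc])),
      sd = c(stats::sd(df$beta_age, na.rm = TRUE),
             stats::sd(df$beta_age[sig_cmc]),
             stats::sd(df$beta_boot[sig_cmc]),
             stats::sd(df$beta_like[sig_cmc])),
      n = c(sum(!is.na(df$beta_age)), sum(sig_cmc),
            sum(sig_cmc & !is.na(df$beta_boot)),
            sum(sig_cmc & !is.na(df$beta_like))),
      row.names = NULL)

    power_rows[[scen$label]] <- data.frame(
      scenario = scen$label, method = unname(methods),
      power = vapply(methods, function(m)
        mean(df[[paste0("sig_", tolower(m))]] %in% TRUE), numeric(1)),
      row.names = NULL)

    if (config$per_variant) {
      vb <- lapply(methods, function(m)
        summarize_bias(df, scen, paste0("sig_", tolower(m))))
      names(vb) <- methods
      bias_tabs[[scen$label]] <- vb
    }
  }

  summary <- structure(list(
    age = do.call(rbind, age_rows),
    power = do.call(rbind, power_rows),
    variant_bias = bias_tabs,
    replicates = out_reps,
    config = config), class = "study_summary")
  if (!is.null(config$output_dir)) .write_study_outputs(summary, config)
  summary
}

.records_to_df <- function(recs) {
  scal <- unique(unlist(lapply(recs, function(r)
    setdiff(names(r), "variant_betas"))))
  df <- as.data.frame(lapply(stats::setNames(scal, scal), function(f)
    unlist(lapply(recs, function(r) {
      v <- r[[f]]
      if (is.null(v)) NA else v
    }))))
  if (!is.null(recs[[1]]$variant_betas)) {
    vb <- t(vapply(recs, `[[`, recs[[1]]$variant_betas, "variant_betas"))
    colnames(vb) <- paste0("beta_", colnames(vb))
    df <- cbind(df, as.data.frame(vb))
  }
  df
}

#' Per-variant conditional bias table (one conditioning method)
#'
#' For the causal variants of a scenario, compares the mean single-variant
#' slope over all replicates and over the replicates in which the given test
#' was significant, and reports the magnitude bias and relative bias of the
#' conditional mean via [bias_metrics()].
#'
#' @param df per-replicate data frame from [run_study()] (columns
#'   `beta_v<j>` and significance flags).
#' @param scenario the [gene_scenario()] that produced it.
#' @param sig_col name of the significance flag column used for conditioning
#'   (e.g. `"sig_cmc"`).
#' @return data frame with one row per causal variant: `variant`, `true_beta`,
#'   `beta_all`, `beta_naive`, `bias`, `rel_bias`, `n_sig`.
#' @export
summarize_bias <- function(df, scenario, sig_col = "sig_cmc") {
  causal <- which(scenario$effects != 0)
  sig <- df[[sig_col]] %in% TRUE
  rows <- lapply(causal, function(j) {
    col <- paste0("beta_v", j)
    truth <- scenario$effects[j]
    cond <- if (any(sig)) mean(df[[col]][sig], na.rm = TRUE) else NA_real_
    bm <- if (is.na(cond)) list(bias_magnitude = NA_real_, rel_bias = NA_real_)
          else bias_metrics(cond, truth)
    data.frame(variant = paste0("v", j), true_beta = truth,
               beta_all = mean(df[[col]], na.rm = TRUE), beta_naive = cond,
               bias = bm$bias_magnitude, rel_bias = bm$rel_bias,
               n_sig = sum(sig), row.names = NULL)
  })
  do.call(rbind, rows)
}

#' @export
print.study_summary <- function(x, ...) {
  cat("Simulation study:", nrow(x$power) / max(1, length(unique(x$power$method))),
      "scenario(s),", x$config$replicates, "replicates each\n\n")
  cat("Power:\n"); print(x$power, row.names = FALSE)
  cat("\nAGE estimates (mean (SD) [n]):\n")
  a <- x$age
  a$mean <- round(a$mean, 3); a$sd <- round(a$sd, 3)
  print(a, row.names = FALSE)
  invisible(x)
}

.write_study_outputs <- function(summary, config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  for (lab in names(summary$replicates))
    write_tsv(summary$replicates[[lab]],
              file.path(config$output_dir, paste0("replicates_", lab, ".tsv")))
  write_tsv(summary$age, file.path(config$output_dir, "age_summary.tsv"))
  write_tsv(summary$power, file.path(config$output_dir, "power.tsv"))
  for (lab in names(summary$variant_bias))
    for (m in names(summary$variant_bias[[lab]]))
      write_tsv(summary$variant_bias[[lab]][[m]],
                file.path(config$output_dir,
                          sprintf("variant_bias_%s_%s.tsv", lab, tolower(m))))
  write_manifest(config, file.path(config$output_dir, "manifest.json"))
  invisible(NULL)
}
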