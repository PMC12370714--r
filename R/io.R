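#' Write a data frame as tab-separated values
#'
#' @param df data frame.
#' @param path output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated table written by [write_tsv()]
#'
#' @param path file path.
#' @return data frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write a genotype matrix as a TSV fixture
#'
#' Subjects in rows, variants in columns, header row of variant labels.
#'
#' @param G carrier-indicator matrix.
#' @param path output path.
#' @export
write_genotypes <- function(G, path) {
  write_tsv(as.data.frame(G), path)
}

#' Read a genotype TSV fixture back into a matrix
#'
#' @param path path written by [write_genotypes()].
#' @return integer carrier matrix.
#' @export
read_genotypes <- function(path) {
  df <- read_tsv(path)
  G <- as.matrix(df)
  storage.mode(G) <- "integer"
  if (!all(G %in% c(0L, 1L))) stop("genotype fixture is not binary")
  G
}

.config_keys <- c("scenarios", "replicates", "master_seed", "alpha_level",
                  "tests", "bootstrap", "correct", "per_variant",
                  "output_dir")

#' Parse a study configuration file
#'
#' YAML key-value file; unknown keys are rejected, missing keys fall back to
#' the [study_config()] defaults. The `tests` block maps method names
#' (`cmc`, `cast`, `calpha`) to optional `p_method` / `n_perm` entries; the
#' `bootstrap` block may set `B`, `max_draws` and `center`.
#'
#' @param path path to the YAML file.
#' @return a validated [study_config()].
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .config_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(cfg$replicates) && cfg$replicates < 1)
    stop("invalid value for key 'replicates': must be >= 1")
  alpha <- if (is.null(cfg$alpha_level)) 0.05 else cfg$alpha_level
  if (alpha <= 0 || alpha >= 1)
    stop("invalid value for key 'alpha_level': must be in (0, 1)")

  tests <- if (is.null(cfg$tests)) default_test_specs(alpha_level = alpha)
  else {
    known <- c("cmc", "cast", "calpha")
    bad <- setdiff(names(cfg$tests), known)
    if (length(bad)) stop("unknown config key(s): tests.",
                          paste(bad, collapse = ", tests."))
    lapply(stats::setNames(names(cfg$tests), toupper(names(cfg$tests))),
           function(m) {
             entry <- cfg$tests[[m]]
             test_spec(toupper(m),
                       p_method = entry$p_method,
                       n_perm = if (is.null(entry$n_perm)) 1000L
                                else entry$n_perm,
                       alpha_level = alpha)
           })
  }

  boot <- list(B = 100L, max_draws = 10000L, center = "median")
  if (!is.null(cfg$bootstrap)) {
    bad <- setdiff(names(cfg$bootstrap), c("B", "max_draws", "center"))
    if (length(bad)) stop("unknown config key(s): bootstrap.",
                          paste(bad, collapse = ", bootstrap."))
    boot[names(cfg$bootstrap)] <- cfg$bootstrap
  }

  study_config(
    scenarios = if (is.null(cfg$scenarios)) "table1_uni" else cfg$scenarios,
    replicates = if (is.null(cfg$replicates)) 2000L else cfg$replicates,
    master_seed = if (is.null(cfg$master_seed)) 1L else cfg$master_seed,
    tests = tests, bootstrap = boot,
    correct = if (is.null(cfg$correct)) TRUE else cfg$correct,
    per_variant = if (is.null(cfg$per_variant)) TRUE else cfg$per_variant,
    output_dir = cfg$output_dir)
}

#' Write a study configuration back to YAML
#'
#' Round-trips through [parse_config()].
#'
#' @param config a [study_config()].
#' @param path output path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  tests <- lapply(config$tests, function(sp)
    list(p_method = sp$p_method, n_perm = sp$n_perm))
  names(tests) <- tolower(vapply(config$tests, `[[`, character(1), "method"))
  out <- list(scenarios = vapply(config$scenarios, `[[`, character(1), "label"),
              replicates = config$replicates,
              master_seed = config$master_seed,
              alpha_level = config$tests[[1]]$alpha_level,
              tests = tests,
              bootstrap = config$bootstrap,
              correct = config$correct,
              per_variant = config$per_variant)
  if (!is.null(config$output_dir)) out$output_dir <- config$output_dir
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Write a reproducibility manifest for a run
#'
#' Records the configuration echo, master seed, seeding scheme, package
#' version and timestamp — enough to reproduce the run bit-exactly.
#'
#' @param config the [study_config()] that was run.
#' @param path output JSON path.
#' @export
write_manifest <- function(config, path) {
  man <- list(
    package = "rvcurse",
    version = as.character(utils::packageVersion("rvcurse")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    master_seed = config$master_seed,
    seed_scheme = paste("set.seed(master_seed);",
                        "replicate seeds = sample.int(2^31 - 2, R * S)",
                        "matrix (replicates x scenarios); per replicate,",
                        "sub-seeds for genotype/trait/permutation/bootstrap",
                        "drawn by set.seed(rep_seed); sample.int(2^31 - 2, 4)"),
    scenarios = vapply(config$scenarios, `[[`, character(1), "label"),
    replicates = config$replicates,
    tests = lapply(config$tests, function(sp)
      list(method = sp$method, p_method = sp$p_method, n_perm = sp$n_perm,
           alpha_level = sp$alpha_level)),
    bootstrap = config$bootstrap)
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read carrier indicators from a biallelic VCF
#'
#' Converts the GT fields of a VCF into the `n x J` carrier matrix the tests
#' consume: entry 1 iff the genotype contains any non-reference allele.
#' Missing genotypes (`./.` or `.`) are coded as non-carrier (conservative
#' for burden coding) and their count reported via a message and the
#' `n_missing` attribute. Multiallelic records are rejected with their
#' position.
#'
#' @param path VCF file (uncompressed or bgzipped).
#' @param variants optional character vector of variant IDs or
#'   `CHROM:POS` labels to keep, in file order.
#' @return carrier matrix (samples x variants) with `CHROM:POS` column
#'   labels and attribute `n_missing`.
#' @export
read_vcf_carriers <- function(path, variants = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (nrow(v@gt) == 0) stop("VCF contains no genotype records")
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi))
    stop("multiallelic record(s) at: ",
         paste(paste0(fix[multi, "CHROM"], ":", fix[multi, "POS"]),
               collapse = ", "))
  labels <- paste0(fix[, "CHROM"], ":", fix[, "POS"])
  ids <- fix[, "ID"]
  gt <- vcfR::extract.gt(v, element = "GT")
  keep <- seq_len(nrow(gt))
  if (!is.null(variants)) {
    keep <- which(labels %in% variants | (!is.na(ids) & ids %in% variants))
    if (length(keep) == 0) {
      warning("no variants matched the requested list; empty matrix")
      return(structure(matrix(0L, ncol(gt), 0),
                       dimnames = list(colnames(gt), NULL), n_missing = 0L))
    }
  }
  gt <- gt[keep, , drop = FALSE]
  labels <- labels[keep]
  alleles <- gsub("[|/]", "", gt)
  bad <- !is.na(alleles) & grepl("[^01.]", alleles)
  if (any(bad))
    stop("malformed GT field(s), e.g. '", gt[which(bad)[1]], "'")
  missing <- is.na(gt) | alleles == "." | alleles == ".."
  carrier <- !missing & grepl("1", alleles, fixed = TRUE)
  n_missing <- sum(missing)
  if (n_missing > 0)
    message(n_missing, " missing genotype(s) coded as non-carrier")
  G <- t(matrix(as.integer(carrier), nrow = nrow(gt),
                dimnames = list(labels, colnames(gt))))
  attr(G, "n_missing") <- as.integer(n_missing)
  G
}
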