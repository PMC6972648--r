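#' Configuration for a full pipeline run
#'
#' Exactly one of `sim` (synthetic mode) or `input_dir` (a directory holding
#' `catalog.tsv`, `phospho.tsv`, `proteome.tsv`, `design.tsv`, `terms.gmt`
#' and optionally `term_categories.tsv`, in the package's TSV/GMT dialects)
#' must be supplied. The global `seed` is fanned out to each stochastic
#' stage by fixed offsets.
#'
#' @param sim A [sim_config()] for synthetic mode, or `NULL`.
#' @param input_dir Directory of input files, or `NULL`.
#' @param out_dir Output directory for all artifacts.
#' @param min_valid_fraction,span Preprocessing parameters (see
#'   [preprocess_matrix()]).
#' @param impute Impute for PCA/clustering (default `TRUE`; testing always
#'   uses observed values only).
#' @param width,downshift Imputation parameters (see
#'   [impute_downshifted_normal()]).
#' @param s0,fdr,n_permutations Differential-test parameters (see
#'   [sam_test()]).
#' @param alpha Enrichment significance level.
#' @param abundance_threshold Protein-level log2 change required for an
#'   `abundance_driven` call (see [call_regulation()]).
#' @param seed Global integer seed.
#' @return A `run_config` list.
#' @export
run_config <- function(sim = NULL, input_dir = NULL, out_dir = tempfile("phosdia_"),
                       min_valid_fraction = 0.7, span = 0.4, impute = TRUE,
                       width = 0.3, downshift = 1.8, s0 = 0.1, fdr = 0.01,
                       n_permutations = 250, alpha = 0.05,
                       abundance_threshold = 0.3, seed = 1L) {
  if (is.null(sim) == is.null(input_dir))
    stop("exactly one of `sim` or `input_dir` must be given")
  structure(list(sim = sim, input_dir = input_dir, out_dir = out_dir,
                 min_valid_fraction = min_valid_fraction, span = span,
                 impute = impute, width = width, downshift = downshift,
                 s0 = s0, fdr = fdr, n_permutations = n_permutations,
                 alpha = alpha, abundance_threshold = abundance_threshold,
                 seed = as.integer(seed)),
            class = "run_config")
}

read_pipeline_inputs <- function(dir) {
  design <- read_design_tsv(file.path(dir, "design.tsv"))
  terms_path <- file.path(dir, "terms.gmt")
  cat_path <- file.path(dir, "term_categories.tsv")
  category <- NULL
  if (file.exists(cat_path)) {
    cm <- utils::read.delim(cat_path, colClasses = "character")
    category <- stats::setNames(cm$category, cm$term_id)
  }
  list(catalog = read_catalog_tsv(file.path(dir, "catalog.tsv")),
       phospho = read_intensity_tsv(file.path(dir, "phospho.tsv"), design,
                                    scale = "raw"),
       proteome = read_intensity_tsv(file.path(dir, "proteome.tsv"), design,
                                     scale = "raw"),
       design = design,
       terms = if (file.exists(terms_path)) read_gmt(terms_path) else NULL,
       category = category)
}

#' Run the complete analysis pipeline
#'
#' Fixed stage order: obtain inputs (simulate or read), preprocess the
#' phosphopeptide matrix (log2, local-regression normalization, valid-value
#' filter), impute a complete copy for PCA and Pearson clustering,
#' differential test on observed values, proteome normalization and
#' regulation calls, then term enrichment over de-duplicated protein-group
#' hits. All artifacts are written as TSV/JSON/GMT under `config$out_dir`;
#' a rerun with the same config reproduces them byte for byte.
#'
#' @param config A [run_config()].
#' @return A `phosdia_run` summary list (also written to
#'   `out_dir/summary.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$sim)) {
    sim <- simulate_experiment(config$sim)
    inputs <- sim[c("catalog", "phospho", "proteome", "design", "terms")]
    inputs$category <- attr(sim$terms, "category")
    write_simulation(sim, file.path(config$out_dir, "simulated_input"))
  } else {
    inputs <- read_pipeline_inputs(config$input_dir)
  }
  catalog <- inputs$catalog
  catalog_size <- nrow(catalog)

  v_raw <- im_values(inputs$phospho)
  quantified <- rowSums(!is.na(v_raw)) >= 1
  phospho_raw <- im_subset_rows(inputs$phospho, which(quantified))
  rows_in <- sum(quantified)

  prep <- preprocess_matrix(phospho_raw,
                            min_valid_fraction = config$min_valid_fraction,
                            span = config$span)
  phospho <- prep$matrix
  write_intensity_tsv(phospho, file.path(config$out_dir, "phospho_preprocessed.tsv"))

  ordination <- NULL
  if (config$impute) {
    complete <- impute_downshifted_normal(phospho, width = config$width,
                                          downshift = config$downshift,
                                          seed = stage_seed(seed, 12))
    pca <- pca_scores(complete)
    tree <- pearson_hierarchical_cluster(complete)
    ordination <- list(pca = pca, tree = tree)
    utils::write.table(
      data.frame(sample_id = rownames(pca$scores), pca$scores[, 1:2],
                 check.names = FALSE),
      file.path(config$out_dir, "pca_scores.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
  }

  fit <- sam_test(phospho, s0 = config$s0, fdr = config$fdr,
                  n_permutations = config$n_permutations,
                  seed = stage_seed(seed, 10))
  utils::write.table(fit$table, file.path(config$out_dir, "differential.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  proteome <- log2_transform(inputs$proteome)
  mapping <- match_rows(catalog, proteome)
  adjusted <- normalize_against_protein(phospho, proteome, mapping)
  adjusted_fit <- sam_test(adjusted, s0 = config$s0, fdr = config$fdr,
                           n_permutations = config$n_permutations,
                           seed = stage_seed(seed, 11))
  pdiff <- protein_group_differences(proteome, mapping)
  calls <- call_regulation(fit, adjusted_fit, pdiff,
                           threshold = config$abundance_threshold)
  utils::write.table(calls, file.path(config$out_dir, "regulation_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  sig_peptides <- fit$table$row_id[fit$table$significant]
  hits <- deduplicate_hits(sig_peptides, catalog)
  background <- sort(unique(
    catalog$protein_group[match(rownames(im_values(phospho)),
                                catalog$peptide_id)]))
  enrich <- NULL
  n_sig_terms <- 0L
  if (!is.null(inputs$terms) && length(inputs$terms)) {
    enrich <- fisher_enrichment(hits, background, inputs$terms,
                                alpha = config$alpha,
                                category = inputs$category)
    n_sig_terms <- sum(enrich$significant)
    utils::write.table(as.data.frame(enrich),
                       file.path(config$out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  summary <- list(
    version = as.character(utils::packageVersion("phosdia")),
    seed = seed,
    counts = list(
      catalog_size = catalog_size,
      rows_quantified = rows_in,
      rows_after_filter = nrow(im_values(phospho)),
      rows_testable = sum(fit$table$reason == "ok"),
      significant_peptides = length(sig_peptides),
      significant_protein_groups = length(hits),
      significant_terms = n_sig_terms),
    fractions = list(
      quantified = rows_in / catalog_size,
      quantified_percent = percentage_report(rows_in, catalog_size),
      after_filter = nrow(im_values(phospho)) / catalog_size,
      after_filter_percent = percentage_report(nrow(im_values(phospho)),
                                               catalog_size)),
    regulation_calls = as.list(table(calls$call)),
    config = config[setdiff(names(config), c("sim", "out_dir"))])
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  structure(list(summary = summary, fit = fit, adjusted_fit = adjusted_fit,
                 calls = calls, enrichment = enrich, ordination = ordination,
                 matrix = phospho, catalog = catalog,
                 preprocess_report = prep$report, out_dir = config$out_dir),
            class = "phosdia_run")
}

#' @export
print.phosdia_run <- function(x, ...) {
  s <- x$summary$counts
  cat("phosdia pipeline run\n")
  cat(sprintf("  catalog: %d peptides; quantified: %d (%d%%); after filter: %d (%d%%)\n",
              s$catalog_size, s$rows_quantified,
              x$summary$fractions$quantified_percent, s$rows_after_filter,
              x$summary$fractions$after_filter_percent))
  cat(sprintf("  significant: %d peptides in %d protein groups; %d enriched terms\n",
              s$significant_peptides, s$significant_protein_groups,
              s$significant_terms))
  cat("  artifacts in:", x$out_dir, "\n")
  invisible(x)
}

#' Rounded percentage (half-up)
#'
#' `100 * numerator / denominator`, rounded half-up to the nearest integer
#' (so 74.85% of a library reports as 75).
#'
#' @param numerator,denominator Non-negative counts,
#'   `numerator <= denominator`, `denominator > 0`.
#' @return Integer percentage.
#' @examples
#' percentage_report(3779, 5049)
#' @export
percentage_report <- function(numerator, denominator) {
  if (denominator <= 0) stop("denominator must be positive")
  if (numerator > denominator) stop("numerator exceeds denominator")
  if (numerator < 0) stop("numerator must be non-negative")
  as.integer(floor(100 * numerator / denominator + 0.5))
}
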