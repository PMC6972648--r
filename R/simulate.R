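#' Configuration for the synthetic phosphoproteome experiment
#'
#' Defaults emulate a two-condition DIA phosphoproteome study: 5 vs 5
#' biological replicates, ~3,100 phosphopeptide precursors over 1,200
#' protein groups, log-normal intensities, intensity-dependent (MNAR)
#' missingness, and a ground-truth subset of differential rows split into
#' phospho-driven effects (phosphopeptide level only) and abundance-driven
#' effects (mirrored at the protein level).
#'
#' @param n_protein_groups Number of protein groups.
#' @param peptides_per_group_mean Mean phosphopeptides per group
#'   (1 + Poisson(mean - 1), so at least one per group).
#' @param n_samples_per_condition Replicates per condition.
#' @param n_terms Number of annotation terms to generate.
#' @param term_size_range Integer pair: min/max protein groups per term.
#' @param frac_differential Fraction of phosphopeptide rows carrying a true
#'   between-condition effect.
#' @param frac_abundance_driven Fraction of differential rows whose effect is
#'   driven by protein abundance (mirrored in the proteome matrix).
#' @param effect_size_log2 Absolute log2 effect size; the sign is drawn
#'   uniformly (no preference for up- or down-regulation).
#' @param base_log2_mean,base_log2_sd Mean and sd of the latent per-row log2
#'   abundance.
#' @param noise_sd Per-cell Gaussian noise sd (log2 units).
#' @param mnar_midpoint Log2 intensity at which a cell is missing with
#'   probability 0.5.
#' @param mnar_slope Steepness of the logistic censoring curve (> 0).
#' @param missing_mechanism `"mnar"` (logistic in intensity), `"mcar"`
#'   (uniform at `mcar_rate`) or `"none"`.
#' @param mcar_rate Per-cell missingness probability under `"mcar"`.
#' @param residue_props Proportions of phosphosites on S, T and Y; must sum
#'   to 1.
#' @param frac_class1 Fraction of sites whose localization probability
#'   exceeds 0.75.
#' @param condition_labels Two condition names; the effect is added to the
#'   second condition.
#' @param seed Integer seed; fanned out to each generation stage by fixed
#'   offsets.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_protein_groups = 1200,
                       peptides_per_group_mean = 2.6,
                       n_samples_per_condition = 5,
                       n_terms = 25,
                       term_size_range = c(10, 60),
                       frac_differential = 0.2,
                       frac_abundance_driven = 0.25,
                       effect_size_log2 = 2,
                       base_log2_mean = 20,
                       base_log2_sd = 2,
                       noise_sd = 0.5,
                       mnar_midpoint = 16,
                       mnar_slope = 1,
                       missing_mechanism = c("mnar", "mcar", "none"),
                       mcar_rate = 0.05,
                       residue_props = c(S = 0.857, T = 0.135, Y = 0.008),
                       frac_class1 = 0.6,
                       condition_labels = c("aposymbiotic", "symbiotic"),
                       seed = 1L) {
  missing_mechanism <- match.arg(missing_mechanism)
  cfg <- list(n_protein_groups = as.integer(n_protein_groups),
              peptides_per_group_mean = peptides_per_group_mean,
              n_samples_per_condition = as.integer(n_samples_per_condition),
              n_terms = as.integer(n_terms),
              term_size_range = as.integer(term_size_range),
              frac_differential = frac_differential,
              frac_abundance_driven = frac_abundance_driven,
              effect_size_log2 = effect_size_log2,
              base_log2_mean = base_log2_mean,
              base_log2_sd = base_log2_sd,
              noise_sd = noise_sd,
              mnar_midpoint = mnar_midpoint,
              mnar_slope = mnar_slope,
              missing_mechanism = missing_mechanism,
              mcar_rate = mcar_rate,
              residue_props = residue_props,
              frac_class1 = frac_class1,
              condition_labels = condition_labels,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_protein_groups >= 1,
            cfg$peptides_per_group_mean >= 1,
            cfg$n_samples_per_condition >= 1,
            cfg$n_terms >= 0,
            length(cfg$term_size_range) == 2,
            cfg$term_size_range[1] >= 1,
            cfg$term_size_range[1] <= cfg$term_size_range[2],
            cfg$base_log2_sd > 0, cfg$noise_sd > 0, cfg$mnar_slope > 0,
            cfg$effect_size_log2 > 0,
            length(cfg$condition_labels) == 2)
  for (f in c("frac_differential", "frac_abundance_driven", "frac_class1",
              "mcar_rate"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("`", f, "` must lie in [0, 1]")
  if (abs(sum(cfg$residue_props) - 1) > 1e-9)
    stop("`residue_props` must sum to 1 (got ", sum(cfg$residue_props), ")")
  if (any(cfg$residue_props < 0)) stop("`residue_props` must be non-negative")
  invisible(cfg)
}

# one global seed fanned out to per-stage child seeds by fixed offsets
stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 1000000000) + offset * 7919)
}

#' Logistic missingness probability
#'
#' Probability that a cell with latent log2 intensity `x` is censored
#' (missing): `1 / (1 + exp(slope * (x - midpoint)))`. Low intensities are
#' more often missing; the function is monotone decreasing in `x`.
#'
#' @param x Latent log2 intensity.
#' @param midpoint Log2 intensity at 50% detection.
#' @param slope Positive steepness.
#' @return Probability in (0, 1).
#' @export
missingness_probability <- function(x, midpoint, slope) {
  stats::plogis(-(slope * (x - midpoint)))
}

#' Generate a synthetic phosphopeptide catalog
#'
#' Random tryptic-like sequences over the 20-letter amino-acid alphabet with
#' 1-3 phosphosites per peptide placed on S/T/Y at the configured residue
#' proportions; localization probabilities are drawn from a three-component
#' uniform mixture so that `frac_class1` of sites exceed 0.75; peptides map
#' many-to-one onto protein groups.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (defaults to a fixed offset of `config$seed`).
#' @return A `phospho_catalog`.
#' @export
generate_catalog <- function(config, seed = stage_seed(config$seed, 1)) {
  validate_sim_config(config)
  set.seed(seed)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  n_pep_per_group <- 1 + stats::rpois(config$n_protein_groups,
                                      config$peptides_per_group_mean - 1)
  n_pep <- sum(n_pep_per_group)
  group_ids <- sprintf("PG_%05d", seq_len(config$n_protein_groups))
  pep_group <- rep(group_ids, n_pep_per_group)
  pep_ids <- sprintf("pep_%06d", seq_len(n_pep))

  lens <- sample(8:30, n_pep, replace = TRUE)
  n_sites <- sample(1:3, n_pep, replace = TRUE, prob = c(0.80, 0.17, 0.03))
  rows <- lapply(seq_len(n_pep), function(i) {
    seq_chars <- sample(aa, lens[i], replace = TRUE)
    pos <- sort(sample.int(lens[i], n_sites[i]))
    res <- sample(names(config$residue_props), n_sites[i], replace = TRUE,
                  prob = config$residue_props)
    seq_chars[pos] <- res
    # localization probabilities: frac_class1 above 0.75, remainder mostly
    # in the mid band with a small low-probability tail
    comp <- sample(1:3, n_sites[i], replace = TRUE,
                   prob = c(config$frac_class1,
                            (1 - config$frac_class1) * 0.875,
                            (1 - config$frac_class1) * 0.125))
    prob <- ifelse(comp == 1, stats::runif(n_sites[i], 0.75, 1),
            ifelse(comp == 2, stats::runif(n_sites[i], 0.25, 0.75),
                   stats::runif(n_sites[i], 0, 0.25)))
    list(sequence = paste(seq_chars, collapse = ""),
         positions = paste(pos, collapse = ";"),
         residues = paste(res, collapse = ";"),
         probs = paste(formatC(prob, digits = 6, format = "f"),
                       collapse = ";"))
  })
  phospho_catalog(data.frame(
    peptide_id = pep_ids,
    sequence = vapply(rows, `[[`, character(1), "sequence"),
    protein_group = pep_group,
    site_positions = vapply(rows, `[[`, character(1), "positions"),
    site_residues = vapply(rows, `[[`, character(1), "residues"),
    site_probabilities = vapply(rows, `[[`, character(1), "probs"),
    stringsAsFactors = FALSE))
}

#' Generate synthetic term annotations over protein groups
#'
#' Emits `n_terms` terms, each a random set of protein-group ids with size
#' drawn uniformly from `term_size_range`; groups may belong to several
#' terms. Each term is assigned a `process` or `pathway` category at random.
#'
#' @param catalog A `phospho_catalog`.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return Named list of member-id vectors (GMT-compatible, see
#'   [write_gmt()]) with `description` and `category` attributes.
#' @export
generate_term_annotation <- function(catalog, config,
                                     seed = stage_seed(config$seed, 2)) {
  validate_sim_config(config)
  if (nrow(catalog) == 0) stop("catalog is empty")
  groups <- unique(catalog$protein_group)
  if (config$n_terms == 0)
    return(structure(stats::setNames(list(), character(0)),
                     description = character(0), category = character(0)))
  if (config$term_size_range[2] > length(groups))
    stop("term_size_range max (", config$term_size_range[2],
         ") exceeds the number of protein groups (", length(groups), ")")
  set.seed(seed)
  size_choices <- seq(config$term_size_range[1], config$term_size_range[2])
  sizes <- size_choices[sample.int(length(size_choices), config$n_terms,
                                   replace = TRUE)]
  ids <- sprintf("term_%03d", seq_len(config$n_terms))
  terms <- lapply(sizes, function(k) sort(sample(groups, k)))
  category <- sample(c("process", "pathway"), config$n_terms, replace = TRUE)
  structure(stats::setNames(terms, ids),
            description = stats::setNames(paste("synthetic", category), ids),
            category = stats::setNames(category, ids))
}

#' Generate paired phospho/proteome intensity matrices with ground truth
#'
#' Each phosphopeptide row has a latent log2 abundance drawn from
#' `Normal(base_log2_mean, base_log2_sd)`; each protein group has its own
#' latent proteome abundance. Differential rows receive a signed log2 effect
#' in the second condition: phospho-driven rows in the phospho matrix only,
#' abundance-driven rows in both the phospho row and its group's proteome
#' row (at most one abundance-driven row per group). Per-cell Gaussian noise
#' is added, values are exponentiated to the raw scale, and phospho cells
#' are censored with the logistic MNAR probability of
#' [missingness_probability()] (the proteome matrix is not censored).
#'
#' @param catalog A `phospho_catalog`.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return List with `phospho` and `proteome` (raw-scale
#'   [intensity_matrix()] objects), `truth` (data frame `row_id`, `label`,
#'   `true_log2_effect`; zero effect for null rows) and `design`.
#' @export
generate_intensity_matrices <- function(catalog, config,
                                        seed = stage_seed(config$seed, 3)) {
  validate_sim_config(config)
  set.seed(seed)
  n_rows <- nrow(catalog)
  groups <- unique(catalog$protein_group)
  nspc <- config$n_samples_per_condition
  cond <- rep(config$condition_labels, each = nspc)
  prefixes <- substr(config$condition_labels, 1, 3)
  if (prefixes[1] == prefixes[2]) prefixes <- paste0(prefixes, 1:2)
  sample_ids <- paste0(rep(prefixes, each = nspc), "_",
                       rep(seq_len(nspc), 2))
  design <- stats::setNames(cond, sample_ids)
  in_cond2 <- cond == config$condition_labels[2]

  n_diff <- round(config$frac_differential * n_rows)
  n_ab <- round(n_diff * config$frac_abundance_driven)
  n_ab <- min(n_ab, length(groups))
  # abundance-driven effects live at the protein level: pick distinct groups
  # and one peptide row within each, so no proteome row gets two effects
  ab_groups <- sample(groups, n_ab)
  ab_rows <- vapply(ab_groups, function(g) {
    idx <- which(catalog$protein_group == g)
    if (length(idx) == 1) idx else sample(idx, 1)
  }, integer(1))
  ph_rows <- sample(setdiff(seq_len(n_rows), ab_rows), n_diff - n_ab)

  label <- rep("null", n_rows)
  label[ab_rows] <- "abundance_driven"
  label[ph_rows] <- "phospho_driven"
  effect <- numeric(n_rows)
  is_diff <- label != "null"
  effect[is_diff] <- config$effect_size_log2 *
    sample(c(-1, 1), sum(is_diff), replace = TRUE)

  base <- stats::rnorm(n_rows, config$base_log2_mean, config$base_log2_sd)
  pbase <- stats::setNames(
    stats::rnorm(length(groups), config$base_log2_mean, config$base_log2_sd),
    groups)
  geffect <- stats::setNames(numeric(length(groups)), groups)
  geffect[catalog$protein_group[ab_rows]] <- effect[ab_rows]

  n_samp <- length(sample_ids)
  latent_ph <- outer(base, rep(1, n_samp)) +
    outer(effect, as.numeric(in_cond2)) +
    matrix(stats::rnorm(n_rows * n_samp, 0, config$noise_sd), n_rows)
  latent_pr <- outer(pbase, rep(1, n_samp)) +
    outer(geffect, as.numeric(in_cond2)) +
    matrix(stats::rnorm(length(groups) * n_samp, 0, config$noise_sd),
           length(groups))

  p_miss <- switch(config$missing_mechanism,
    mnar = missingness_probability(latent_ph, config$mnar_midpoint,
                                   config$mnar_slope),
    mcar = matrix(config$mcar_rate, n_rows, n_samp),
    none = matrix(0, n_rows, n_samp))
  censored <- matrix(stats::runif(n_rows * n_samp), n_rows) < p_miss

  ph <- 2^latent_ph
  ph[censored] <- NA_real_
  dimnames(ph) <- list(catalog$peptide_id, sample_ids)
  pr <- 2^latent_pr
  dimnames(pr) <- list(groups, sample_ids)

  list(phospho = intensity_matrix(ph, design, "raw"),
       proteome = intensity_matrix(pr, design, "raw"),
       truth = data.frame(row_id = catalog$peptide_id, label = label,
                          true_log2_effect = effect,
                          stringsAsFactors = FALSE),
       design = design)
}

#' Simulate a complete synthetic two-condition experiment
#'
#' Convenience wrapper running [generate_catalog()],
#' [generate_term_annotation()] and [generate_intensity_matrices()] with
#' per-stage child seeds derived from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List of class `phospho_sim` with elements `catalog`, `terms`,
#'   `phospho`, `proteome`, `truth`, `design`, `config`.
#' @export
simulate_experiment <- function(config = sim_config()) {
  catalog <- generate_catalog(config)
  terms <- generate_term_annotation(catalog, config)
  mats <- generate_intensity_matrices(catalog, config)
  structure(list(catalog = catalog, terms = terms, phospho = mats$phospho,
                 proteome = mats$proteome, truth = mats$truth,
                 design = mats$design, config = config),
            class = "phospho_sim")
}

#' @export
print.phospho_sim <- function(x, ...) {
  cat("Synthetic two-condition phosphoproteome experiment\n")
  print(x$catalog)
  cat(sprintf("terms: %d; differential rows: %d (%d phospho-driven, %d abundance-driven)\n",
              length(x$terms), sum(x$truth$label != "null"),
              sum(x$truth$label == "phospho_driven"),
              sum(x$truth$label == "abundance_driven")))
  print(x$phospho)
  invisible(x)
}

#' Write all simulation artifacts to a directory
#'
#' Writes `catalog.tsv`, `phospho.tsv`, `proteome.tsv`, `design.tsv`,
#' `truth.tsv`, `terms.gmt` and `term_categories.tsv`.
#'
#' @param sim A `phospho_sim`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_catalog_tsv(sim$catalog, file.path(dir, "catalog.tsv"))
  write_intensity_tsv(sim$phospho, file.path(dir, "phospho.tsv"))
  write_intensity_tsv(sim$proteome, file.path(dir, "proteome.tsv"))
  write_design_tsv(sim$design, file.path(dir, "design.tsv"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gmt(sim$terms, file.path(dir, "terms.gmt"))
  cat_map <- attr(sim$terms, "category")
  utils::write.table(
    data.frame(term_id = names(cat_map), category = unname(cat_map)),
    file.path(dir, "term_categories.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}
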