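# shared fixtures, all built in code

# quick intensity matrix: two conditions A/B split evenly over the columns
toy_matrix <- function(values, scale = "log2",
                       conditions = rep(c("A", "B"),
                                        each = ncol(values) / 2)) {
  if (is.null(rownames(values)))
    rownames(values) <- paste0("r", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  intensity_matrix(values, stats::setNames(conditions, colnames(values)),
                   scale = scale)
}

# the desk-scale version of the study design: 5 vs 5, ~500 phospho rows,
# |effect| = 2 log2 units, noise sd 0.5
small_sim_config <- function(seed, ...) {
  sim_config(n_protein_groups = 200, peptides_per_group_mean = 2.5,
             effect_size_log2 = 2, noise_sd = 0.5, seed = seed, ...)
}

# simulate, preprocess (log2 + valid-value filter) and fit both the
# phospho-level and the proteome-adjusted differential models
fit_simulated_run <- function(seed, frac_differential = 0.2,
                              n_permutations = 250, with_calls = TRUE) {
  cfg <- small_sim_config(seed, frac_differential = frac_differential)
  sim <- simulate_experiment(cfg)
  lg <- log2_transform(sim$phospho)
  filt <- filter_valid_values(lg, 0.7)
  fit <- sam_test(filt$matrix, s0 = 0.1, fdr = 0.01,
                  n_permutations = n_permutations, seed = seed + 101)
  out <- list(sim = sim, matrix = filt$matrix, fit = fit,
              truth = sim$truth[match(fit$table$row_id, sim$truth$row_id), ])
  if (with_calls) {
    proteome <- log2_transform(sim$proteome)
    mapping <- match_rows(sim$catalog, proteome)
    adjusted <- normalize_against_protein(filt$matrix, proteome, mapping)
    adj_fit <- sam_test(adjusted, s0 = 0.1, fdr = 0.01,
                        n_permutations = n_permutations, seed = seed + 202)
    pdiff <- protein_group_differences(proteome, mapping)
    out$calls <- call_regulation(fit, adj_fit, pdiff)
  }
  out
}
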