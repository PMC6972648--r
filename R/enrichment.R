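#' Collapse significant phosphopeptides to unique protein groups
#'
#' A protein carrying several significant phosphopeptides or phosphosites
#' must count only once in enrichment (the "relative enrichment" principle),
#' so hits are de-duplicated at the protein-group level.
#'
#' @param peptide_ids Character vector of significant phosphopeptide ids.
#' @param catalog A `phospho_catalog` covering all of them.
#' @return Character vector of unique protein-group ids (sorted).
#' @export
deduplicate_hits <- function(peptide_ids, catalog) {
  idx <- match(peptide_ids, catalog$peptide_id)
  if (anyNA(idx))
    stop("peptide(s) missing from the catalog: ",
         paste(peptide_ids[is.na(idx)], collapse = ", "))
  sort(unique(catalog$protein_group[idx]))
}

# two-sided Fisher exact p by hypergeometric enumeration: sum the
# probabilities of all tables (same margins) no more likely than observed
fisher_exact_two_sided <- function(k, K, n, N) {
  lo <- max(0L, n - (N - K))
  hi <- min(n, K)
  support <- lo:hi
  probs <- stats::dhyper(support, K, N - K, n)
  p_obs <- stats::dhyper(k, K, N - K, n)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Fisher's exact test term enrichment with enrichment factors
#'
#' Per term, the 2x2 table (in-term / out-of-term x hit / non-hit) over the
#' background universe of protein groups is tested two-sided (so
#' under-represented terms are detectable too), and the enrichment factor
#' `(k/n) / (K/N)` is reported — the term's share among hits relative to its
#' share of the background; values below 1 indicate under-representation.
#'
#' @param hits Character vector of hit protein-group ids (subset of
#'   `background`).
#' @param background Character vector: the universe of quantified protein
#'   groups.
#' @param terms Named list of member-id vectors (e.g. from [read_gmt()] or
#'   [generate_term_annotation()]). Members outside the background are
#'   clipped with a message.
#' @param alpha Significance level on the raw p-value (default 0.05).
#' @param adjust Multiple-testing adjustment across terms passed to
#'   [stats::p.adjust()]; `"none"` (default) flags on raw p-values.
#' @param category Optional named character vector term id ->
#'   `process`/`pathway`.
#' @return Data frame of class `enrichment_result`: `term_id`, `category`,
#'   `k` (hits in term), `K` (background in term), `n` (total hits), `N`
#'   (background size), `p_value`, `enrichment_factor` (`NA` when `K` or
#'   `n` is 0), `significant`.
#' @export
fisher_enrichment <- function(hits, background, terms, alpha = 0.05,
                              adjust = "none", category = NULL) {
  background <- unique(background)
  hits <- unique(hits)
  stray <- setdiff(hits, background)
  if (length(stray))
    stop("hits outside the background universe: ",
         paste(utils::head(stray, 5), collapse = ", "))
  N <- length(background)
  n <- length(hits)
  res <- lapply(names(terms), function(id) {
    members <- unique(terms[[id]])
    clipped <- intersect(members, background)
    if (length(clipped) < length(members))
      message("term ", id, ": ", length(members) - length(clipped),
              " member(s) outside the background were clipped")
    K <- length(clipped)
    k <- length(intersect(clipped, hits))
    p <- if (K == 0) NA_real_ else fisher_exact_two_sided(k, K, n, N)
    ef <- if (K > 0 && n > 0) (k / n) / (K / N) else NA_real_
    data.frame(term_id = id, k = k, K = K, n = n, N = N, p_value = p,
               enrichment_factor = ef, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(term_id = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p_value = numeric(0),
                      enrichment_factor = numeric(0))
  p_flag <- if (adjust == "none") out$p_value else
    stats::p.adjust(out$p_value, method = adjust)
  out$significant <- !is.na(p_flag) & p_flag < alpha
  out$category <- if (is.null(category)) NA_character_ else
    unname(category[out$term_id])
  out <- out[, c("term_id", "category", "k", "K", "n", "N", "p_value",
                 "enrichment_factor", "significant")]
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Fisher exact enrichment: %d terms, %d significant (n = %d hits over N = %d background groups)\n",
              nrow(x), sum(x$significant),
              if (nrow(x)) x$n[1] else 0L, if (nrow(x)) x$N[1] else 0L))
  print.data.frame(utils::head(x[order(x$p_value), ], 10), digits = 4,
                   row.names = FALSE)
  if (nrow(x) > 10) cat("... (", nrow(x) - 10, " more terms)\n", sep = "")
  invisible(x)
}

#' Scatter table of enrichment results
#'
#' One row per term with a defined enrichment factor, sorted by p-value
#' (ties broken by term id) — the tabular form of the enrichment-factor vs
#' significance scatterplot.
#'
#' @param results An `enrichment_result`.
#' @return Data frame `term_id, category, enrichment_factor, neg_log10_p,
#'   significant`.
#' @export
enrichment_scatter_table <- function(results) {
  if (nrow(results) == 0) stop("no enrichment results")
  keep <- results[!is.na(results$enrichment_factor), ]
  keep <- keep[order(keep$p_value, keep$term_id), ]
  data.frame(term_id = keep$term_id,
             category = keep$category,
             enrichment_factor = keep$enrichment_factor,
             neg_log10_p = -log10(keep$p_value),
             significant = keep$significant,
             stringsAsFactors = FALSE, row.names = NULL)
}
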