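#' Map phosphopeptide rows to proteome rows
#'
#' Each phosphopeptide maps to the proteome row of its protein group;
#' peptides whose group is absent from the proteome matrix are `NA`
#' (unmatched).
#'
#' @param catalog A `phospho_catalog`.
#' @param proteome An [intensity_matrix()] with one row per protein group.
#' @return Named character vector: peptide id -> proteome row id or `NA`.
#' @export
match_rows <- function(catalog, proteome) {
  prot_ids <- rownames(im_values(proteome))
  if (anyDuplicated(prot_ids))
    stop("duplicate proteome rows for group(s): ",
         paste(unique(prot_ids[duplicated(prot_ids)]), collapse = ", "))
  mapped <- ifelse(catalog$protein_group %in% prot_ids,
                   catalog$protein_group, NA_character_)
  stats::setNames(mapped, catalog$peptide_id)
}

#' Normalize phosphopeptide abundance against total protein abundance
#'
#' Per sample log-ratio: `adjusted[row, s] = phospho[row, s] -
#' proteome[group(row), s]`. A between-condition difference that survives
#' this adjustment reflects differential phosphorylation; one that vanishes
#' reflects a change in protein amount. Cells missing in either input are
#' missing in the output. Unmatched rows are carried through unadjusted and
#' listed in the `unmatched` attribute.
#'
#' @param phospho,proteome Log2-scale [intensity_matrix()] objects with
#'   identical sample sets and order.
#' @param mapping Named vector from [match_rows()].
#' @return A log2-scale [intensity_matrix()] of adjusted values, with an
#'   `unmatched` attribute (character vector of unadjusted row ids).
#' @export
normalize_against_protein <- function(phospho, proteome, mapping) {
  if (im_scale(phospho) != "log2" || im_scale(proteome) != "log2")
    stop("both matrices must be on the log2 scale")
  vp <- im_values(phospho)
  vr <- im_values(proteome)
  if (!identical(colnames(vp), colnames(vr)))
    stop("sample sets differ: ",
         paste(union(setdiff(colnames(vp), colnames(vr)),
                     setdiff(colnames(vr), colnames(vp))), collapse = ", "))
  mapping <- mapping[rownames(vp)]
  matched <- !is.na(mapping)
  out <- vp
  out[matched, ] <- vp[matched, , drop = FALSE] -
    vr[mapping[matched], , drop = FALSE]
  res <- im_replace(phospho, out)
  attr(res, "unmatched") <- rownames(vp)[!matched]
  res
}

#' Classify significant rows as phospho- or abundance-driven
#'
#' Joins the phosphopeptide-level and proteome-adjusted differential results
#' row by row and applies the rule table: still significant after
#' adjustment -> `phospho_driven`; significance lost and the protein itself
#' shifted by at least `threshold` log2 units -> `abundance_driven`;
#' significance lost but the protein flat -> `mixed` (indeterminate); not
#' significant at the phospho level -> `none`; no proteome row ->
#' `unmatched`. Calls annotate — they never alter the underlying
#' differences.
#'
#' @param phospho_fit `sam_fit` on the phosphopeptide matrix.
#' @param adjusted_fit `sam_fit` on the proteome-adjusted matrix (same
#'   rows).
#' @param protein_diff Named numeric vector: per-peptide log2
#'   between-condition difference of its protein-group proteome row (`NA`
#'   for unmatched rows). See [protein_group_differences()].
#' @param threshold Minimum absolute protein-level log2 change to call
#'   `abundance_driven` (default 0.3).
#' @return Data frame `row_id, call, phospho_diff, protein_diff,
#'   adjusted_diff`.
#' @export
call_regulation <- function(phospho_fit, adjusted_fit, protein_diff,
                            threshold = 0.3) {
  pt <- phospho_fit$table
  at <- adjusted_fit$table
  if (!identical(pt$row_id, at$row_id))
    stop("phospho and adjusted results cover different rows")
  pd <- unname(protein_diff[pt$row_id])
  unmatched <- is.na(pd)
  call <- ifelse(unmatched, "unmatched",
          ifelse(!pt$significant, "none",
          ifelse(at$significant, "phospho_driven",
          ifelse(abs(pd) >= threshold, "abundance_driven", "mixed"))))
  data.frame(row_id = pt$row_id,
             call = call,
             phospho_diff = pt$mean_difference,
             protein_diff = ifelse(unmatched, NA_real_, pd),
             adjusted_diff = ifelse(unmatched, NA_real_,
                                    at$mean_difference),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-peptide protein-group log2 differences
#'
#' Between-condition mean difference of each proteome row, mapped back onto
#' phosphopeptide rows.
#'
#' @param proteome Log2-scale [intensity_matrix()].
#' @param mapping Named vector from [match_rows()].
#' @param contrast Condition pair `(A, B)`; difference is `A - B`.
#' @return Named numeric vector over peptide ids (`NA` where unmatched).
#' @export
protein_group_differences <- function(proteome, mapping, contrast = NULL) {
  v <- im_values(proteome)
  design <- im_design(proteome)
  conds <- unique(design)
  if (is.null(contrast)) contrast <- conds
  ma <- rowMeans(v[, names(design)[design == contrast[1]], drop = FALSE],
                 na.rm = TRUE)
  mb <- rowMeans(v[, names(design)[design == contrast[2]], drop = FALSE],
                 na.rm = TRUE)
  diff <- ma - mb
  stats::setNames(ifelse(is.na(mapping), NA_real_,
                         diff[mapping]), names(mapping))
}
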