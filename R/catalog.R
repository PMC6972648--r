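#' Phosphopeptide catalog
#'
#' A catalog is a data frame with one row per quantified phosphopeptide
#' precursor and columns `peptide_id`, `sequence`, `protein_group`,
#' `site_positions` (1-based, semicolon-separated), `site_residues`
#' (semicolon-separated letters from S/T/Y) and `site_probabilities`
#' (semicolon-separated localization probabilities in \[0,1\]).
#'
#' @param df Data frame with the columns above.
#' @return The validated data frame with class `phospho_catalog` prepended.
#' @export
phospho_catalog <- function(df) {
  needed <- c("peptide_id", "sequence", "protein_group",
              "site_positions", "site_residues", "site_probabilities")
  miss <- setdiff(needed, names(df))
  if (length(miss))
    stop("catalog is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$peptide_id)) stop("duplicate peptide ids")
  sites <- catalog_sites_unchecked(df)
  bad <- sites$position < 1 | sites$position > nchar(sites$sequence)
  if (any(bad))
    stop("site position out of sequence bounds for peptide(s): ",
         paste(unique(sites$peptide_id[bad]), collapse = ", "))
  seq_letter <- substr(sites$sequence, sites$position, sites$position)
  if (any(seq_letter != sites$residue))
    stop("site residue does not match the sequence letter for peptide(s): ",
         paste(unique(sites$peptide_id[seq_letter != sites$residue]),
               collapse = ", "))
  if (any(!sites$residue %in% c("S", "T", "Y")))
    stop("site residues must be S, T or Y")
  if (any(sites$probability < 0 | sites$probability > 1))
    stop("localization probabilities must lie in [0, 1]")
  class(df) <- unique(c("phospho_catalog", class(df)))
  df
}

catalog_sites_unchecked <- function(df) {
  n_sites <- lengths(strsplit(df$site_residues, ";", fixed = TRUE))
  data.frame(
    peptide_id = rep(df$peptide_id, n_sites),
    sequence = rep(df$sequence, n_sites),
    protein_group = rep(df$protein_group, n_sites),
    position = as.integer(unlist(strsplit(df$site_positions, ";"))),
    residue = unlist(strsplit(df$site_residues, ";")),
    probability = as.numeric(unlist(strsplit(df$site_probabilities, ";"))),
    stringsAsFactors = FALSE)
}

#' Expand a catalog into one row per phosphosite
#'
#' @param catalog A `phospho_catalog`.
#' @return Data frame with columns `peptide_id`, `sequence`,
#'   `protein_group`, `position`, `residue`, `probability`.
#' @export
catalog_sites <- function(catalog) catalog_sites_unchecked(catalog)

#' @export
print.phospho_catalog <- function(x, ...) {
  sites <- catalog_sites(x)
  cat(sprintf(
    "phospho_catalog: %d phosphopeptides, %d phosphosites, %d protein groups\n",
    nrow(x), nrow(sites), length(unique(x$protein_group))))
  invisible(x)
}

#' Read / write the catalog TSV dialect
#'
#' @param path File path.
#' @return `read_catalog_tsv()` returns a `phospho_catalog`.
#' @export
read_catalog_tsv <- function(path) {
  phospho_catalog(utils::read.delim(path, colClasses = "character"))
}

#' @rdname read_catalog_tsv
#' @param catalog A `phospho_catalog`.
#' @export
write_catalog_tsv <- function(catalog, path) {
  utils::write.table(as.data.frame(catalog), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fraction of phosphosites on serine, threonine and tyrosine
#'
#' Computed over sites (a doubly phosphorylated peptide contributes two
#' sites), mirroring how library composition is usually reported.
#'
#' @param catalog A `phospho_catalog` with at least one site.
#' @return Named numeric vector `c(S=, T=, Y=)` summing to 1.
#' @export
residue_composition <- function(catalog) {
  sites <- catalog_sites(catalog)
  if (nrow(sites) == 0) stop("catalog contains no phosphosites")
  n <- c(S = sum(sites$residue == "S"),
         T = sum(sites$residue == "T"),
         Y = sum(sites$residue == "Y"))
  n / sum(n)
}
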