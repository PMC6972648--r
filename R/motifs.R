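#' Kinase motif definitions
#'
#' A motif is a named list with elements `name` (string) and `pattern`, a
#' named list mapping relative offsets (as character keys, `"0"` being the
#' phosphosite itself) to a string of allowed residues. Offset 0 must allow
#' only phospho-acceptor residues (S, T or Y).
#'
#' @param name Motif name.
#' @param pattern Named list, e.g. `list("0" = "ST", "1" = "P")` for a
#'   proline-directed site.
#' @return A `kinase_motif` object.
#' @export
kinase_motif <- function(name, pattern) {
  if (is.null(names(pattern)) || any(names(pattern) == ""))
    stop("pattern offsets must be named")
  offs <- suppressWarnings(as.integer(names(pattern)))
  if (anyNA(offs)) stop("pattern offsets must be integers")
  if (!"0" %in% names(pattern))
    stop("pattern must constrain offset 0 (the phosphosite)")
  zero <- strsplit(pattern[["0"]], "")[[1]]
  if (!all(zero %in% c("S", "T", "Y")))
    stop("offset 0 may only allow S, T or Y")
  structure(list(name = name, pattern = pattern), class = "kinase_motif")
}

#' Built-in kinase motif families
#'
#' Three canonical substrate-motif families used when no motif library is
#' supplied: proline-directed (\[pS/pT\]P), basophilic (R at -3) and
#' acidophilic (D/E at +3). Motifs are a pluggable input; any list of
#' [kinase_motif()] objects can be passed instead.
#'
#' @return List of `kinase_motif` objects.
#' @export
default_kinase_motifs <- function() {
  list(
    kinase_motif("proline-directed", list("0" = "ST", "1" = "P")),
    kinase_motif("basophilic", list("-3" = "R", "0" = "ST")),
    kinase_motif("acidophilic", list("0" = "ST", "3" = "DE")))
}

#' Match kinase motifs at a phosphosite
#'
#' A motif matches iff every offset of its pattern falls inside the sequence
#' and the residue there is among the allowed set.
#'
#' @param sequence Amino-acid string.
#' @param position 1-based phosphosite position within `sequence`.
#' @param motifs List of [kinase_motif()] objects.
#' @return Character vector of matching motif names, in input order.
#' @examples
#' match_motifs("AASPK", 3, default_kinase_motifs())
#' @export
match_motifs <- function(sequence, position, motifs = default_kinase_motifs()) {
  if (length(position) != 1 || position < 1 || position > nchar(sequence))
    stop("position ", position, " is outside the sequence (length ",
         nchar(sequence), ")")
  hits <- vapply(motifs, function(m) {
    offs <- as.integer(names(m$pattern))
    pos <- position + offs
    if (any(pos < 1 | pos > nchar(sequence))) return(FALSE)
    res <- substring(sequence, pos, pos)
    all(mapply(function(r, allowed) grepl(r, allowed, fixed = TRUE),
               res, unlist(m$pattern)))
  }, logical(1))
  vapply(motifs[hits], `[[`, character(1), "name")
}

#' Classify a phosphosite by localization probability and motif evidence
#'
#' Class I: localization probability strictly above 0.75. Classes II and III:
#' probability in \[0.25, 0.75\], with (II) or without (III) a matching
#' kinase motif. Probabilities below 0.25 are reported as `ambiguous` and
#' excluded from class fractions.
#'
#' @param probability Numeric vector of localization probabilities in \[0,1\].
#' @param has_matching_motif Logical vector (recycled) indicating motif
#'   evidence.
#' @return Factor with levels `I`, `II`, `III`, `ambiguous`.
#' @examples
#' classify_site(c(0.9, 0.5, 0.5, 0.1), c(FALSE, TRUE, FALSE, TRUE))
#' @export
classify_site <- function(probability, has_matching_motif) {
  if (any(probability < 0 | probability > 1, na.rm = FALSE))
    stop("probabilities must lie in [0, 1]")
  has_matching_motif <- rep_len(as.logical(has_matching_motif),
                                length(probability))
  cls <- ifelse(probability > 0.75, "I",
         ifelse(probability >= 0.25,
                ifelse(has_matching_motif, "II", "III"),
                "ambiguous"))
  factor(cls, levels = c("I", "II", "III", "ambiguous"))
}

#' Summarize phosphosite classes across a catalog
#'
#' Each site is classified with [classify_site()], using [match_motifs()] on
#' its peptide sequence to establish motif evidence.
#'
#' @param catalog A `phospho_catalog`.
#' @param motifs List of [kinase_motif()] objects.
#' @return List with `counts` (named integer vector over the four classes)
#'   and `fractions` (over all classified sites; sums to 1).
#' @export
summarize_classes <- function(catalog, motifs = default_kinase_motifs()) {
  sites <- catalog_sites(catalog)
  has_motif <- mapply(function(seq, pos) {
    length(match_motifs(seq, pos, motifs)) > 0
  }, sites$sequence, sites$position, USE.NAMES = FALSE)
  cls <- classify_site(sites$probability, has_motif)
  counts <- table(cls)
  fractions <- as.numeric(counts) / sum(counts)
  list(counts = stats::setNames(as.integer(counts), names(counts)),
       fractions = stats::setNames(fractions, names(counts)))
}

#' Read motif definitions from a two-column TSV
#'
#' Columns `name` and `pattern`, where `pattern` is semicolon-separated
#' `offset:residues` pairs, e.g. `0:ST;1:P`.
#'
#' @param path File path.
#' @return List of [kinase_motif()] objects.
#' @export
read_motifs_tsv <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  lapply(seq_len(nrow(df)), function(i) {
    pairs <- strsplit(df$pattern[i], ";", fixed = TRUE)[[1]]
    kv <- strsplit(pairs, ":", fixed = TRUE)
    pattern <- stats::setNames(lapply(kv, `[[`, 2), vapply(kv, `[[`,
                                                           character(1), 1))
    kinase_motif(df$name[i], pattern)
  })
}
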