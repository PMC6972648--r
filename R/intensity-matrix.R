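#' Construct a two-condition intensity matrix
#'
#' The central quantification container: a rows-by-samples numeric matrix of
#' abundances with explicit missingness (`NA`), a sample-to-condition design,
#' and a scale marker so that log2 transformation cannot be applied twice.
#'
#' @param values Numeric matrix with row names (precursor or protein-group
#'   ids) and column names (sample ids). Missing cells are `NA`.
#' @param design Named character vector mapping every sample id (names) to a
#'   condition label (values). Must cover all columns of `values`.
#' @param scale Either `"raw"` (linear intensities, all observed values
#'   strictly positive) or `"log2"`.
#' @return An object of class `intensity_matrix`: the matrix itself with
#'   `design` and `scale` attributes.
#' @examples
#' m <- matrix(2^rnorm(12, 20), 3, 4,
#'             dimnames = list(paste0("p", 1:3), paste0("s", 1:4)))
#' design <- setNames(rep(c("apo", "sym"), each = 2), colnames(m))
#' im <- intensity_matrix(m, design, scale = "raw")
#' im_scale(im)
#' @export
intensity_matrix <- function(values, design, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have row and column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate row ids in `values`")
  if (is.null(names(design)))
    stop("`design` must be a named vector (sample id -> condition)")
  missing_samples <- setdiff(colnames(values), names(design))
  if (length(missing_samples))
    stop("samples without a condition in `design`: ",
         paste(missing_samples, collapse = ", "))
  design <- design[colnames(values)]
  if (scale == "raw") {
    obs <- values[!is.na(values)]
    if (any(obs <= 0))
      stop("raw-scale matrix contains non-positive observed values")
  }
  structure(values,
            design = stats::setNames(as.character(design), colnames(values)),
            scale = scale, class = c("intensity_matrix", "matrix", "array"))
}

#' @rdname intensity_matrix
#' @param x An `intensity_matrix`.
#' @export
im_design <- function(x) attr(x, "design")

#' @rdname intensity_matrix
#' @export
im_scale <- function(x) attr(x, "scale")

#' @rdname intensity_matrix
#' @export
im_values <- function(x) {
  y <- unclass(x)
  attr(y, "design") <- NULL
  attr(y, "scale") <- NULL
  attr(y, "unmatched") <- NULL
  y
}

# rebuild after any matrix surgery, keeping design/scale in sync
im_replace <- function(x, values, scale = im_scale(x)) {
  intensity_matrix(values, im_design(x)[colnames(values)], scale)
}

#' Subset rows of an intensity matrix
#'
#' @param x An `intensity_matrix`.
#' @param rows Character vector of row ids or logical/integer index.
#' @return An `intensity_matrix` with the selected rows, in the given order.
#' @export
im_subset_rows <- function(x, rows) {
  v <- im_values(x)[rows, , drop = FALSE]
  im_replace(x, v)
}

#' @export
print.intensity_matrix <- function(x, ...) {
  v <- im_values(x)
  conds <- table(im_design(x))
  cat(sprintf("intensity_matrix: %d rows x %d samples (%s scale)\n",
              nrow(v), ncol(v), im_scale(x)))
  cat("conditions:",
      paste(sprintf("%s (n=%d)", names(conds), as.integer(conds)),
            collapse = ", "), "\n")
  cat(sprintf("missing cells: %d (%.1f%%)\n", sum(is.na(v)),
              100 * mean(is.na(v))))
  invisible(x)
}

#' Read / write the tab-separated intensity-matrix dialect
#'
#' First column `row_id`, remaining columns sample intensities; missing cells
#' are empty strings; header required.
#'
#' @param path File path.
#' @param design Named character vector sample -> condition (see
#'   [intensity_matrix()]).
#' @param scale Scale of the stored values.
#' @return `read_intensity_tsv()` returns an `intensity_matrix`;
#'   `write_intensity_tsv()` returns `path` invisibly.
#' @export
read_intensity_tsv <- function(path, design, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  df <- utils::read.delim(path, check.names = FALSE, na.strings = "",
                          colClasses = NA)
  if (names(df)[1] != "row_id") stop("first column must be `row_id`")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df$row_id)
  intensity_matrix(m, design, scale)
}

#' @rdname read_intensity_tsv
#' @param x An `intensity_matrix` to write.
#' @export
write_intensity_tsv <- function(x, path) {
  v <- im_values(x)
  df <- data.frame(row_id = rownames(v), v, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a sample design table (`sample_id`, `condition`)
#'
#' @param path File path.
#' @return `read_design_tsv()` returns a named character vector
#'   (sample -> condition).
#' @export
read_design_tsv <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  if (!all(c("sample_id", "condition") %in% names(df)))
    stop("design table needs columns `sample_id` and `condition`")
  stats::setNames(df$condition, df$sample_id)
}

#' @rdname read_design_tsv
#' @param design Named character vector sample -> condition.
#' @export
write_design_tsv <- function(design, path) {
  utils::write.table(
    data.frame(sample_id = names(design), condition = unname(design)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
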