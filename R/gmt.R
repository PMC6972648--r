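#' Read / write gene-set annotations in GMT format
#'
#' One term per line: term id, description, then member ids, tab-separated.
#'
#' @param path File path.
#' @return `read_gmt()` returns a named list of character vectors (term id ->
#'   member ids) with a `description` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(fields, `[[`, character(1), 1)
  desc <- vapply(fields, function(f) if (length(f) >= 2) f[2] else "",
                 character(1))
  members <- lapply(fields, function(f) if (length(f) > 2) f[-(1:2)]
                    else character(0))
  structure(stats::setNames(members, ids),
            description = stats::setNames(desc, ids))
}

#' @rdname read_gmt
#' @param terms Named list of character vectors (term id -> member ids).
#' @param description Optional named character vector of term descriptions.
#' @export
write_gmt <- function(terms, path, description = NULL) {
  if (is.null(description))
    description <- attr(terms, "description")
  if (is.null(description))
    description <- stats::setNames(rep("", length(terms)), names(terms))
  lines <- vapply(names(terms), function(id) {
    paste(c(id, description[[id]], terms[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
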