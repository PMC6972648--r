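#' Select the rows used for normalization
#'
#' Mirrors the "q-value sparse" row-selection strategy: every precursor that
#' passed the identification q-value threshold in at least one sample across
#' the experiment contributes to the normalization fit.
#'
#' @param x An [intensity_matrix()].
#' @param pass_flags Logical matrix of the same shape as `x`: `TRUE` where
#'   the precursor passed the threshold in that sample.
#' @return Character vector of selected row ids (rows with >= 1 `TRUE`).
#' @export
select_normalization_rows <- function(x, pass_flags) {
  v <- im_values(x)
  if (!is.matrix(pass_flags) || !identical(dim(pass_flags), dim(v)))
    stop("`pass_flags` must be a ", nrow(v), " x ", ncol(v),
         " logical matrix matching the intensity matrix")
  rownames(v)[rowSums(pass_flags, na.rm = TRUE) >= 1]
}

#' Log2-transform a raw intensity matrix
#'
#' Missing cells stay missing; non-positive observed values (which a clean
#' quantification matrix should not contain) are set missing with a warning.
#'
#' @param x A raw-scale [intensity_matrix()].
#' @return The matrix on log2 scale.
#' @export
log2_transform <- function(x) {
  if (im_scale(x) == "log2")
    stop("matrix is already on log2 scale (double-transform guard)")
  v <- im_values(x)
  bad <- !is.na(v) & v <= 0
  if (any(bad)) {
    warning(sum(bad), " non-positive value(s) set to missing before log2")
    v[bad] <- NA_real_
  }
  im_replace(x, log2(v), scale = "log2")
}

#' Local-regression (LOESS) normalization against a row-median reference
#'
#' For each sample, the deviation of its observed log2 values from the
#' per-row median reference is smoothed as a function of the reference over
#' the selected rows, and the fitted intensity-dependent bias is subtracted
#' from all rows of that sample. Assumes most precursors form a stable,
#' unregulated background with no preference for up- or down-regulation.
#'
#' @param x A log2-scale [intensity_matrix()].
#' @param rows Row ids used to fit the bias (e.g. from
#'   [select_normalization_rows()]). `NULL` or empty falls back to all rows
#'   with a warning.
#' @param span LOESS span (fraction of points in each local fit).
#' @return List with `matrix` (normalized [intensity_matrix()]) and
#'   `report`: `rows_used` plus a per-sample data frame of median
#'   corrections and the span.
#' @export
local_regression_normalize <- function(x, rows = NULL, span = 0.4) {
  if (im_scale(x) != "log2") stop("normalize on the log2 scale")
  v <- im_values(x)
  if (is.null(rows) || length(rows) == 0) {
    warning("empty normalization-row subset; falling back to all rows")
    rows <- rownames(v)
  }
  sub <- v[rows, , drop = FALSE]
  usable <- rowSums(!is.na(sub)) >= 2
  if (sum(usable) < 8)
    stop("local regression needs at least 8 usable rows, got ", sum(usable))

  ref_all <- apply(v, 1, stats::median, na.rm = TRUE)
  ref_sub <- ref_all[rows][usable]
  out <- v
  correction <- numeric(ncol(v))
  for (j in seq_len(ncol(v))) {
    dev <- sub[usable, j] - ref_sub
    ok <- !is.na(dev)
    fit <- stats::lowess(ref_sub[ok], dev[ok], f = span)
    # constant extrapolation outside the fitted reference range
    bias <- stats::approx(fit$x, fit$y, xout = ref_all, rule = 2,
                          ties = mean)$y
    out[, j] <- v[, j] - bias
    correction[j] <- stats::median(bias[!is.na(v[, j])])
  }
  report <- list(rows_used = sum(usable),
                 per_sample = data.frame(sample_id = colnames(v),
                                         median_correction = correction,
                                         span = span))
  list(matrix = im_replace(x, out), report = report)
}

#' Filter rows by fraction of valid (observed) values
#'
#' A row is kept iff the fraction of observed cells across all samples
#' jointly is at least `min_fraction` (with 10 samples and the default 0.7,
#' a row needs at least 7 observed values). With `per_group = TRUE` the
#' fraction must be met within every condition separately.
#'
#' @param x An [intensity_matrix()].
#' @param min_fraction Minimum fraction of valid values, in (0, 1].
#' @param per_group Apply the threshold within each condition instead of
#'   across all samples jointly.
#' @return List with `matrix` (filtered, row order preserved) and
#'   `n_removed`.
#' @export
filter_valid_values <- function(x, min_fraction = 0.7, per_group = FALSE) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  v <- im_values(x)
  obs <- !is.na(v)
  if (per_group) {
    design <- im_design(x)
    keep <- rep(TRUE, nrow(v))
    for (cond in unique(design)) {
      cols <- names(design)[design == cond]
      keep <- keep &
        rowMeans(obs[, cols, drop = FALSE]) >= min_fraction - 1e-12
    }
  } else {
    keep <- rowMeans(obs) >= min_fraction - 1e-12
  }
  list(matrix = im_subset_rows(x, which(keep)),
       n_removed = sum(!keep))
}

#' Impute missing values from a downshifted normal distribution
#'
#' Per sample: with mean `mu` and standard deviation `sigma` of the observed
#' log2 values, each missing cell is drawn independently from
#' `Normal(mu - downshift * sigma, (width * sigma)^2)`. The shrunken,
#' downshifted distribution mimics low abundances, the usual cause of
#' missing values. Observed cells are never touched.
#'
#' @param x A log2-scale [intensity_matrix()].
#' @param width Width of the imputation distribution relative to the
#'   sample's sd (default 0.3).
#' @param downshift Downshift of its mean in sample-sd units (default 1.8).
#' @param seed Optional integer seed for reproducible draws.
#' @return The matrix with no missing cells.
#' @export
impute_downshifted_normal <- function(x, width = 0.3, downshift = 1.8,
                                      seed = NULL) {
  if (im_scale(x) != "log2") stop("impute on the log2 scale")
  if (!is.null(seed)) set.seed(seed)
  v <- im_values(x)
  for (j in seq_len(ncol(v))) {
    obs <- v[, j][!is.na(v[, j])]
    n_miss <- sum(is.na(v[, j]))
    if (n_miss == 0) next
    if (length(obs) < 2)
      stop("sample ", colnames(v)[j],
           " has fewer than 2 observed values; cannot impute")
    mu <- mean(obs)
    sigma <- stats::sd(obs)
    v[is.na(v[, j]), j] <- stats::rnorm(n_miss, mu - downshift * sigma,
                                        width * sigma)
  }
  im_replace(x, v)
}

#' Run the standard preprocessing chain
#'
#' log2 transform, local-regression normalization (rows with at least one
#' observed value unless `pass_flags` is given), then the valid-value
#' filter. Imputation is deliberately not part of the chain: it is applied
#' only where a complete matrix is required (PCA, clustering), not before
#' differential testing, which uses observed values per group.
#'
#' @param x A raw-scale [intensity_matrix()].
#' @param min_valid_fraction Valid-value threshold (see
#'   [filter_valid_values()]).
#' @param span LOESS span.
#' @param normalize Set `FALSE` to skip normalization.
#' @param pass_flags Optional logical matrix for
#'   [select_normalization_rows()]; defaults to the observed/missing
#'   pattern.
#' @return List with `matrix` (log2, normalized, filtered), `n_removed`,
#'   `n_in` and the normalization `report` (or `NULL`).
#' @export
preprocess_matrix <- function(x, min_valid_fraction = 0.7, span = 0.4,
                              normalize = TRUE, pass_flags = NULL) {
  n_in <- nrow(im_values(x))
  lg <- log2_transform(x)
  report <- NULL
  if (normalize) {
    if (is.null(pass_flags)) pass_flags <- !is.na(im_values(x))
    rows <- select_normalization_rows(lg, pass_flags)
    norm <- local_regression_normalize(lg, rows, span = span)
    lg <- norm$matrix
    report <- norm$report
  }
  filt <- filter_valid_values(lg, min_valid_fraction)
  list(matrix = filt$matrix, n_removed = filt$n_removed, n_in = n_in,
       report = report)
}
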