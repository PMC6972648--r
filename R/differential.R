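#' S0-moderated two-sample statistic
#'
#' The SAM-style moderated t statistic
#' `d = (mean_a - mean_b) / (s + s0)`, where `s` is the pooled
#' (equal-variance) standard error of the mean difference and `s0` is a
#' small positive constant added to the denominator so that the difference
#' of means also plays a role in significance. With `s0 = 0`, `d` is
#' exactly the classical pooled-variance Student t statistic.
#'
#' @param values_a,values_b Numeric vectors of observed log2 values, at
#'   least 2 each.
#' @param s0 Non-negative moderation constant (default 0.1).
#' @param welch Use the Welch (unequal-variance) standard error instead of
#'   the pooled form.
#' @return List with `d` and `mean_difference` (`mean_a - mean_b`).
#' @examples
#' sam_statistic(c(1, 2, 3), c(4, 5, 6), s0 = 0)
#' @export
sam_statistic <- function(values_a, values_b, s0 = 0.1, welch = FALSE) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("need at least 2 observed values per group")
  if (s0 < 0) stop("`s0` must be non-negative")
  na <- length(values_a); nb <- length(values_b)
  md <- mean(values_a) - mean(values_b)
  va <- stats::var(values_a); vb <- stats::var(values_b)
  if (welch) {
    s <- sqrt(va / na + vb / nb)
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    s <- sqrt(sp2 * (1 / na + 1 / nb))
  }
  list(d = md / (s + s0), mean_difference = md)
}

# vectorized group stats over a column subset, NA-aware
.group_stats <- function(v, obs, v0, v0sq, cols) {
  n <- rowSums(obs[, cols, drop = FALSE])
  sm <- rowSums(v0[, cols, drop = FALSE])
  sq <- rowSums(v0sq[, cols, drop = FALSE])
  m <- sm / n
  var <- (sq - n * m^2) / (n - 1)
  var[n < 2] <- NA_real_
  var <- pmax(var, 0)  # guard tiny negative from cancellation
  list(n = n, mean = m, var = var)
}

.sam_d_rows <- function(v, obs, v0, v0sq, cols_a, cols_b, s0, welch) {
  a <- .group_stats(v, obs, v0, v0sq, cols_a)
  b <- .group_stats(v, obs, v0, v0sq, cols_b)
  md <- a$mean - b$mean
  if (welch) {
    s <- sqrt(a$var / a$n + b$var / b$n)
  } else {
    sp2 <- ((a$n - 1) * a$var + (b$n - 1) * b$var) / (a$n + b$n - 2)
    s <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  }
  list(d = md / (s + s0), mean_difference = md, n_a = a$n, n_b = b$n)
}

#' Differential abundance by moderated t-test with permutation FDR
#'
#' Fits the two-condition differential-abundance model: per row, the
#' S0-moderated two-sided t statistic on observed values
#' (see [sam_statistic()]); significance is controlled by a permutation
#' false discovery rate. Sample condition labels are randomly permuted
#' `n_permutations` times (unrestricted relabeling; with 5 vs 5 samples
#' there are only 252 distinct relabelings, so draws may repeat) and the
#' statistic is recomputed. For a symmetric cutoff `c`, the estimated FDR is
#' the mean number of permuted `|d*| >= c` divided by the observed count
#' `|d| >= c`; the significant set uses the smallest cutoff among the sorted
#' observed `|d|` whose estimated FDR is at or below `fdr`. Two-sided
#' p-values come from the pooled permutation distribution of `|d*|`.
#'
#' Rows with fewer than 2 observed values in either group are reported as
#' untestable (`reason` column) rather than dropped silently, and are never
#' significant.
#'
#' @param x A log2-scale [intensity_matrix()] with exactly two conditions.
#' @param contrast Character vector of the two condition labels `(A, B)`;
#'   `mean_difference` is `A - B`. Defaults to the order of appearance in
#'   the design.
#' @param s0 Moderation constant (default 0.1).
#' @param fdr Target permutation FDR (default 0.01).
#' @param n_permutations Number of random relabelings (default 250).
#' @param welch Use Welch standard errors.
#' @param seed Integer seed for the permutations.
#' @param permutations Optional integer matrix (`n_permutations` x
#'   `n_samples`) of explicit column permutations, overriding the random
#'   draws (mainly for degenerate-case testing).
#' @return An object of class `sam_fit`; see [summary.sam_fit()]. The
#'   `table` element has one row per input row: `row_id`,
#'   `mean_difference`, `d_statistic`, `p_value`, `significant`, `reason`,
#'   `n_obs_a`, `n_obs_b`.
#' @export
sam_test <- function(x, contrast = NULL, s0 = 0.1, fdr = 0.01,
                     n_permutations = 250, welch = FALSE, seed = 1L,
                     permutations = NULL) {
  stopifnot(fdr > 0, fdr < 1, n_permutations >= 1, s0 >= 0)
  if (im_scale(x) != "log2") stop("test on the log2 scale")
  v <- im_values(x)
  design <- im_design(x)
  conds <- unique(design)
  if (length(conds) != 2) stop("exactly two conditions required, got ",
                               length(conds))
  if (is.null(contrast)) contrast <- conds
  if (!setequal(contrast, conds) || length(contrast) != 2)
    stop("`contrast` must name the two design conditions")
  idx_a <- unname(which(design == contrast[1]))
  idx_b <- unname(which(design == contrast[2]))

  obs <- !is.na(v)
  v0 <- ifelse(obs, v, 0)
  v0sq <- v0^2

  ob <- .sam_d_rows(v, obs, v0, v0sq, idx_a, idx_b, s0, welch)
  testable <- ob$n_a >= 2 & ob$n_b >= 2 & is.finite(ob$d)
  reason <- ifelse(ob$n_a < 2 | ob$n_b < 2, "too_few_observations",
                   ifelse(is.finite(ob$d), "ok", "degenerate_variance"))
  if (!any(testable)) stop("no testable rows (need >= 2 observations per group)")

  n_samp <- ncol(v)
  if (is.null(permutations)) {
    set.seed(seed)
    # a relabeling that reproduces the observed grouping (or its mirror)
    # re-draws the observed statistic, not a null value, so it is excluded
    # from the randomizations whenever an alternative split exists
    obs_split <- sort(idx_a)
    n_splits <- choose(n_samp, length(idx_a))
    permutations <- matrix(0L, n_permutations, n_samp)
    for (p in seq_len(n_permutations)) {
      repeat {
        pp <- sample.int(n_samp)
        mirrors_observed <- identical(sort(pp[idx_a]), obs_split) ||
          identical(sort(pp[idx_b]), obs_split)
        if (n_splits <= 2 || !mirrors_observed) break
      }
      permutations[p, ] <- pp
    }
  } else {
    permutations <- as.matrix(permutations)
    if (ncol(permutations) != n_samp)
      stop("`permutations` must have one column per sample")
    n_permutations <- nrow(permutations)
  }

  perm_abs <- vector("list", n_permutations)
  for (p in seq_len(n_permutations)) {
    pp <- permutations[p, ]
    dstar <- .sam_d_rows(v, obs, v0, v0sq, pp[idx_a], pp[idx_b], s0, welch)$d
    dstar <- abs(dstar[testable])
    perm_abs[[p]] <- dstar[is.finite(dstar)]
  }
  pooled <- sort(unlist(perm_abs))
  n_pooled <- length(pooled)

  abs_d <- abs(ob$d)
  # p-values from the pooled null of |d*|, add-one so p is in (0, 1]
  n_ge <- n_pooled - findInterval(abs_d[testable] - 1e-12, pooled)
  p_value <- rep(NA_real_, nrow(v))
  p_value[testable] <- (1 + n_ge) / (1 + n_pooled)

  # symmetric-cutoff FDR scan over the sorted observed |d|
  cand <- sort(unique(abs_d[testable]))
  R <- length(abs_d[testable]) -
    findInterval(cand - 1e-12, sort(abs_d[testable]))
  V <- (n_pooled - findInterval(cand - 1e-12, pooled)) / n_permutations
  est_fdr <- pmin(1, V / R)
  ok <- which(est_fdr <= fdr)
  cutoff <- if (length(ok)) cand[min(ok)] else Inf

  significant <- testable & abs_d >= cutoff
  table <- data.frame(
    row_id = rownames(v),
    mean_difference = ob$mean_difference,
    d_statistic = ob$d,
    p_value = p_value,
    significant = significant,
    reason = reason,
    n_obs_a = ob$n_a,
    n_obs_b = ob$n_b,
    stringsAsFactors = FALSE, row.names = NULL)

  structure(list(table = table, cutoff = cutoff, s0 = s0, fdr = fdr,
                 n_permutations = n_permutations, contrast = contrast,
                 welch = welch, seed = seed, call = match.call()),
            class = "sam_fit")
}

#' @export
print.sam_fit <- function(x, ...) {
  tab <- x$table
  cat(sprintf(
    "S0-moderated permutation-FDR differential test (%s vs %s)\n",
    x$contrast[1], x$contrast[2]))
  cat(sprintf("s0 = %g, FDR = %g, %d permutations\n", x$s0, x$fdr,
              x$n_permutations))
  cat(sprintf("rows: %d tested (%d untestable), significant: %d (|d| cutoff %.4g)\n",
              sum(tab$reason == "ok"), sum(tab$reason != "ok"),
              sum(tab$significant), x$cutoff))
  invisible(x)
}

#' Summarize a differential-test fit
#'
#' @param object A `sam_fit`.
#' @param ... Unused.
#' @return A list with counts of tested/untestable/significant rows, the
#'   |d| cutoff, and the direction split of significant rows.
#' @export
summary.sam_fit <- function(object, ...) {
  tab <- object$table
  sig <- tab[tab$significant, ]
  out <- list(n_rows = nrow(tab),
              n_tested = sum(tab$reason == "ok"),
              n_untestable = sum(tab$reason != "ok"),
              n_significant = nrow(sig),
              n_up = sum(sig$mean_difference > 0),
              n_down = sum(sig$mean_difference < 0),
              cutoff = object$cutoff,
              s0 = object$s0, fdr = object$fdr,
              contrast = object$contrast)
  class(out) <- "summary.sam_fit"
  out
}

#' @export
print.summary.sam_fit <- function(x, ...) {
  cat(sprintf("%d rows (%d tested, %d untestable)\n", x$n_rows, x$n_tested,
              x$n_untestable))
  cat(sprintf("significant at FDR %g: %d (%d higher in %s, %d higher in %s)\n",
              x$fdr, x$n_significant, x$n_up, x$contrast[1], x$n_down,
              x$contrast[2]))
  invisible(x)
}

#' @export
coef.sam_fit <- function(object, ...) {
  stats::setNames(object$table$mean_difference, object$table$row_id)
}

#' Volcano table from a differential fit
#'
#' @param fit A `sam_fit`.
#' @return Data frame with one row per testable input row:
#'   `row_id`, `mean_difference`, `neg_log10_p`, `significant`.
#' @export
volcano_table <- function(fit) {
  tab <- fit$table[fit$table$reason == "ok", ]
  data.frame(row_id = tab$row_id,
             mean_difference = tab$mean_difference,
             neg_log10_p = -log10(tab$p_value),
             significant = tab$significant,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Volcano plot of a differential fit
#'
#' @param x A `sam_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.sam_fit <- function(x, ...) {
  vt <- volcano_table(x)
  graphics::plot(vt$mean_difference, vt$neg_log10_p,
                 col = ifelse(vt$significant, "firebrick", "grey50"),
                 pch = 16, cex = 0.6,
                 xlab = sprintf("log2 difference (%s - %s)", x$contrast[1],
                                x$contrast[2]),
                 ylab = expression(-log[10] ~ p), ...)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' Principal component scores of the samples
#'
#' Rows (features) are centred; samples are projected onto the principal
#' axes. Requires a complete matrix — impute first.
#'
#' @param x A complete [intensity_matrix()] (no missing values).
#' @return List with `scores` (samples x components) and
#'   `explained_variance` (non-increasing fractions summing to <= 1).
#' @export
pca_scores <- function(x) {
  v <- im_values(x)
  if (anyNA(v))
    stop("matrix has missing values; run impute_downshifted_normal() first")
  pr <- stats::prcomp(t(v), center = TRUE, scale. = FALSE)
  ev <- pr$sdev^2 / sum(pr$sdev^2)
  list(scores = pr$x, explained_variance = ev)
}

#' Pearson-correlation hierarchical clustering of samples
#'
#' Distance `1 - r` (Pearson correlation between sample profiles), average
#' linkage. Requires a complete matrix.
#'
#' @param x A complete [intensity_matrix()].
#' @return An [stats::hclust] tree over the samples.
#' @export
pearson_hierarchical_cluster <- function(x) {
  v <- im_values(x)
  if (anyNA(v))
    stop("matrix has missing values; run impute_downshifted_normal() first")
  sds <- apply(v, 2, stats::sd)
  if (any(sds == 0))
    stop("constant sample profile(s): ",
         paste(colnames(v)[sds == 0], collapse = ", "))
  d <- stats::as.dist(1 - stats::cor(v))
  stats::hclust(d, method = "average")
}
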