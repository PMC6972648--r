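test_that("the moderated statistic reduces to the pooled t at s0 = 0", {
  # textbook-formula oracle
  pooled_t <- function(a, b) {
    sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
      (length(a) + length(b) - 2)
    (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  }
  r <- sam_statistic(c(1, 2, 3), c(4, 5, 6), s0 = 0)
  expect_equal(r$d, pooled_t(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(r$d, unname(stats::t.test(c(1, 2, 3), c(4, 5, 6),
                                         var.equal = TRUE)$statistic))
  set.seed(10)
  for (i in 1:50) {
    a <- stats::rnorm(sample(3:8, 1), 20, 2)
    b <- stats::rnorm(sample(3:8, 1), 21, 2)
    got <- sam_statistic(a, b, s0 = 0)
    expect_equal(got$d, unname(stats::t.test(a, b, var.equal = TRUE)$statistic),
                 tolerance = 1e-12)
    expect_equal(got$mean_difference, mean(a) - mean(b))
  }
})

test_that("s0 shrinks the statistic and identical groups give zero", {
  r <- sam_statistic(c(5, 5, 5.5), c(5, 5, 5.5), s0 = 0.1)
  expect_equal(r$d, 0)
  expect_equal(r$mean_difference, 0)
  set.seed(11)
  for (i in 1:20) {
    a <- stats::rnorm(5); b <- stats::rnorm(5)
    expect_lte(abs(sam_statistic(a, b, 0.1)$d),
               abs(sam_statistic(a, b, 0)$d))
  }
  expect_error(sam_statistic(1, c(1, 2)), "at least 2")
})

test_that("the permutation test is reproducible and flags untestable rows", {
  set.seed(12)
  v <- matrix(stats::rnorm(200, 20), 20, 10)
  dimnames(v) <- list(paste0("r", 1:20), paste0("s", 1:10))
  v[1, 1:4] <- NA   # only one observation in condition A
  m <- toy_matrix(v)
  f1 <- sam_test(m, seed = 3)
  f2 <- sam_test(m, seed = 3)
  expect_identical(f1$table, f2$table)
  expect_equal(f1$table$reason[1], "too_few_observations")
  expect_false(f1$table$significant[1])
  expect_true(all(f1$table$p_value[f1$table$reason == "ok"] > 0))
  expect_true(all(f1$table$p_value[f1$table$reason == "ok"] <= 1))
})

test_that("an overwhelming effect is detected against a null background", {
  set.seed(13)
  noise_sd <- 0.5
  v <- matrix(stats::rnorm(500, 20, noise_sd), 50, 10)
  dimnames(v) <- list(paste0("r", 1:50), paste0("s", 1:10))
  v[1, 6:10] <- v[1, 6:10] + 10 * noise_sd
  m <- toy_matrix(v)
  fit <- sam_test(m, fdr = 0.01, seed = 4)
  expect_true(fit$table$significant[1])
  expect_lte(sum(fit$table$significant), 3)
})

test_that("swapping the contrast flips signs but not the significant set", {
  run <- fit_simulated_run(31, n_permutations = 100, with_calls = FALSE)
  m <- run$matrix
  f_ab <- sam_test(m, contrast = c("aposymbiotic", "symbiotic"), seed = 9)
  f_ba <- sam_test(m, contrast = c("symbiotic", "aposymbiotic"), seed = 9)
  expect_equal(f_ab$table$mean_difference, -f_ba$table$mean_difference)
  expect_equal(f_ab$table$d_statistic, -f_ba$table$d_statistic)
  expect_identical(f_ab$table$significant, f_ba$table$significant)
})

test_that("raising the FDR level never shrinks the significant set", {
  run <- fit_simulated_run(32, n_permutations = 100, with_calls = FALSE)
  prev <- character(0)
  for (level in c(0.001, 0.01, 0.05, 0.1, 0.25)) {
    fit <- sam_test(run$matrix, fdr = level, n_permutations = 100, seed = 7)
    sig <- fit$table$row_id[fit$table$significant]
    expect_true(all(prev %in% sig),
                label = sprintf("fdr %g contains fdr-smaller set", level))
    prev <- sig
  }
})

test_that("a single forced identity permutation can declare nothing significant", {
  set.seed(14)
  v <- matrix(stats::rnorm(300, 20), 30, 10)
  dimnames(v) <- list(paste0("r", 1:30), paste0("s", 1:10))
  v[1, 6:10] <- v[1, 6:10] + 5
  m <- toy_matrix(v)
  fit <- sam_test(m, fdr = 0.01, permutations = matrix(1:10, nrow = 1))
  # with the observed labels as the only "permutation", estimated FDR is 1
  # at every reachable cutoff, so at most argmax rows could ever pass
  expect_equal(sum(fit$table$significant), 0)
  expect_equal(fit$cutoff, Inf)
})

test_that("PCA scores behave like the covariance eigendecomposition", {
  set.seed(15)
  v <- matrix(stats::rnorm(60, 20), 10, 6)
  dimnames(v) <- list(paste0("r", 1:10), paste0("s", 1:6))
  v[, 4] <- v[, 3]  # two identical samples
  m <- toy_matrix(v)
  res <- pca_scores(m)
  expect_equal(res$scores[3, ], res$scores[4, ])
  expect_true(all(diff(res$explained_variance) <= 1e-12))
  expect_lte(sum(res$explained_variance), 1 + 1e-9)

  # rank-1 pattern: first component carries everything
  pattern <- stats::rnorm(10)
  v1 <- outer(pattern, c(1, 2, 3, 4, 5, 6))
  dimnames(v1) <- dimnames(v)
  r1 <- pca_scores(toy_matrix(v1))
  expect_equal(r1$explained_variance[1], 1, tolerance = 1e-6)

  # eigen oracle on the centred cross-product
  res2 <- pca_scores(m)
  centred <- t(v) - colMeans(t(v))[col(t(v))]
  centred <- scale(t(v), center = TRUE, scale = FALSE)
  eig <- eigen(stats::cov(centred))
  ev_oracle <- eig$values / sum(eig$values)
  expect_equal(res2$explained_variance[1:3], ev_oracle[1:3], tolerance = 1e-9)
  for (k in 1:2) {
    expect_equal(abs(res2$scores[, k]), abs(centred %*% eig$vectors[, k])[, 1],
                 tolerance = 1e-6)
  }

  vna <- v; vna[1, 1] <- NA
  expect_error(pca_scores(toy_matrix(vna)), "impute")
})

test_that("correlation clustering merges identical samples first and recovers conditions", {
  set.seed(16)
  v <- matrix(stats::rnorm(100, 20, 1), 20, 5)
  dimnames(v) <- list(paste0("r", 1:20), paste0("s", 1:5))
  v[, 2] <- v[, 1]
  m <- toy_matrix(v, conditions = c("A", "A", "A", "B", "B"))
  tree <- pearson_hierarchical_cluster(m)
  expect_equal(tree$height[1], 0, tolerance = 1e-12)
  expect_setequal(abs(tree$merge[1, ]), c(1, 2))

  # two well-separated condition templates: the 2-cut recovers the design
  tpl_a <- stats::rnorm(30, 20, 1); tpl_b <- tpl_a + stats::rnorm(30, 0, 1) * 5
  v2 <- cbind(sapply(1:5, function(i) tpl_a + stats::rnorm(30, 0, 0.3)),
              sapply(1:5, function(i) tpl_b + stats::rnorm(30, 0, 0.3)))
  dimnames(v2) <- list(paste0("r", 1:30), paste0("s", 1:10))
  m2 <- toy_matrix(v2)
  k2 <- stats::cutree(pearson_hierarchical_cluster(m2), k = 2)
  expect_equal(length(unique(k2[1:5])), 1)
  expect_equal(length(unique(k2[6:10])), 1)
  expect_false(k2[1] == k2[6])

  cst <- v; cst[, 3] <- 7
  expect_error(pearson_hierarchical_cluster(
    toy_matrix(cst, conditions = c("A", "A", "A", "B", "B"))), "s3")
})

test_that("average-linkage heights match a manual trace on three samples", {
  v <- matrix(c(1, 2, 3, 4,
                1.1, 2.1, 2.9, 4.2,
                4, 1, 3, 2), 4, 3)
  dimnames(v) <- list(paste0("r", 1:4), paste0("s", 1:3))
  m <- toy_matrix(v, conditions = c("A", "A", "B"))
  cors <- stats::cor(v)
  d12 <- 1 - cors[1, 2]; d13 <- 1 - cors[1, 3]; d23 <- 1 - cors[2, 3]
  tree <- pearson_hierarchical_cluster(m)
  # s1,s2 are nearly identical profiles -> merged first at 1 - r12,
  # then the average of the two remaining dissimilarities
  expect_equal(tree$height[1], d12, tolerance = 1e-12)
  expect_equal(tree$height[2], mean(c(d13, d23)), tolerance = 1e-12)
})

test_that("volcano tables carry one row per testable input row", {
  run <- fit_simulated_run(33, n_permutations = 50, with_calls = FALSE)
  vt <- volcano_table(run$fit)
  expect_equal(nrow(vt), sum(run$fit$table$reason == "ok"))
  expect_identical(vt$significant,
                   run$fit$table$significant[run$fit$table$reason == "ok"])
  expect_true(all(vt$neg_log10_p >= 0))
  p1 <- data.frame(row_id = "x", mean_difference = 0, d_statistic = 0,
                   p_value = 1, significant = FALSE, reason = "ok",
                   n_obs_a = 5, n_obs_b = 5)
  fake <- structure(list(table = p1), class = "sam_fit")
  expect_equal(volcano_table(fake)$neg_log10_p, 0)
})
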