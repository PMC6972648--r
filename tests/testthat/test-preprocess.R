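test_that("normalization-row selection equals a per-row any() recount", {
  set.seed(1)
  m <- toy_matrix(matrix(stats::rnorm(80, 20), 20, 4))
  flags <- matrix(stats::runif(80) < 0.3, 20, 4)
  got <- select_normalization_rows(m, flags)
  oracle <- rownames(im_values(m))[apply(flags, 1, any)]
  expect_identical(got, oracle)
  expect_identical(select_normalization_rows(m, matrix(TRUE, 20, 4)),
                   rownames(im_values(m)))
  expect_length(select_normalization_rows(m, matrix(FALSE, 20, 4)), 0)
  expect_error(select_normalization_rows(m, matrix(TRUE, 5, 4)), "matching")
})

test_that("log2 transform maps values and guards against double application", {
  m <- toy_matrix(matrix(c(8, 1, NA, 4), 2, 2), scale = "raw")
  lg <- log2_transform(m)
  expect_equal(im_values(lg)[1, 1], 3)
  expect_equal(im_values(lg)[2, 1], 0)
  expect_true(is.na(im_values(lg)[1, 2]))
  expect_identical(im_scale(lg), "log2")
  expect_error(log2_transform(lg), "already on log2")
})

test_that("normalization leaves identical samples untouched", {
  set.seed(2)
  base <- stats::rnorm(50, 20, 2)
  m <- toy_matrix(matrix(rep(base, 4), 50, 4))
  out <- local_regression_normalize(m, rownames(im_values(m)))
  expect_equal(im_values(out$matrix), im_values(m), tolerance = 1e-9)
  expect_equal(out$report$rows_used, 50)
})

test_that("a constant sample shift is removed exactly", {
  set.seed(3)
  base <- stats::rnorm(200, 20, 2)
  v <- matrix(rep(base, 4), 200, 4)
  v[, 2] <- v[, 2] + 1.5
  m <- toy_matrix(v)
  out <- local_regression_normalize(m, rownames(im_values(m)), span = 0.4)
  ref <- apply(im_values(out$matrix), 1, stats::median)
  dev <- im_values(out$matrix)[, 2] - ref
  expect_lt(abs(stats::median(dev)), 1e-6)
  # within-sample rank order preserved under the constant-shift removal
  expect_identical(order(im_values(out$matrix)[, 2]), order(v[, 2]))
})

test_that("intensity-dependent linear bias is strongly attenuated", {
  set.seed(4)
  n <- 1000
  base <- stats::rnorm(n, 20, 2)
  v <- sapply(1:6, function(j) base + stats::rnorm(n, 0, 0.2))
  slope_in <- 0.2
  v[, 1] <- v[, 1] + slope_in * (base - 20)  # bias linear in intensity
  m <- toy_matrix(v)
  out <- local_regression_normalize(m, rownames(im_values(m)), span = 0.4)
  ref <- apply(im_values(out$matrix), 1, stats::median)
  slope_out <- stats::coef(stats::lm(im_values(out$matrix)[, 1] - ref ~ ref))[2]
  expect_lt(abs(slope_out), 0.1 * slope_in)
})

test_that("normalization refuses too few usable rows and warns on empty subset", {
  m <- toy_matrix(matrix(stats::rnorm(16, 20), 4, 4))
  expect_error(local_regression_normalize(m, rownames(im_values(m))),
               "at least 8")
  big <- toy_matrix(matrix(stats::rnorm(80, 20), 20, 4))
  expect_warning(res <- local_regression_normalize(big, character(0)),
                 "falling back")
  expect_equal(res$report$rows_used, 20)
})

test_that("valid-value filter keeps rows with >= 70% observed, jointly", {
  set.seed(5)
  v <- matrix(stats::rnorm(100, 20), 10, 10,
              dimnames = list(paste0("r", 1:10), paste0("s", 1:10)))
  n_miss <- c(0, 1, 2, 3, 4, 5, 3, 2, 1, 0)
  for (i in 1:10) if (n_miss[i] > 0) v[i, seq_len(n_miss[i])] <- NA
  m <- toy_matrix(v)
  out <- filter_valid_values(m, 0.7)
  # with 10 samples a row needs at least 7 observed values
  expect_identical(rownames(im_values(out$matrix)),
                   rownames(v)[10 - n_miss >= 7])
  expect_equal(out$n_removed, sum(10 - n_miss < 7))

  complete <- toy_matrix(matrix(stats::rnorm(40, 20), 10, 4))
  expect_equal(filter_valid_values(complete, 0.7)$n_removed, 0)
})

test_that("valid-value filter matches an enumeration oracle and is idempotent", {
  set.seed(6)
  v <- matrix(stats::rnorm(24, 20), 6, 4,
              dimnames = list(paste0("r", 1:6), paste0("s", 1:4)))
  miss <- c(0, 1, 2, 3, 4, 2)
  for (i in 1:6) if (miss[i] > 0) v[i, sample(4, miss[i])] <- NA
  m <- toy_matrix(v)
  out <- filter_valid_values(m, 0.7)
  keep_oracle <- vapply(1:6, function(i) sum(!is.na(v[i, ])) / 4 >= 0.7,
                        logical(1))
  expect_identical(rownames(im_values(out$matrix)), rownames(v)[keep_oracle])
  again <- filter_valid_values(out$matrix, 0.7)
  expect_identical(im_values(again$matrix), im_values(out$matrix))
  expect_equal(again$n_removed, 0)
})

test_that("imputed values follow the downshifted, shrunken normal", {
  set.seed(7)
  n <- 20000
  obs <- stats::rnorm(n, 20, 1)
  v <- cbind(obs, obs)  # two samples so the container is happy
  v[seq_len(n / 2), 2] <- NA
  colnames(v) <- c("s1", "s2"); rownames(v) <- paste0("r", 1:n)
  m <- toy_matrix(v, conditions = c("A", "B"))
  imp <- impute_downshifted_normal(m, width = 0.3, downshift = 1.8, seed = 1)
  mu <- mean(v[!is.na(v[, 2]), 2]); sigma <- stats::sd(v[!is.na(v[, 2]), 2])
  drawn <- im_values(imp)[seq_len(n / 2), 2]
  expect_lt(abs(mean(drawn) - (mu - 1.8 * sigma)), 0.02)
  expect_lt(abs(stats::sd(drawn) - 0.3 * sigma), 0.01)
})

test_that("imputation is deterministic under a seed and never edits observed cells", {
  set.seed(8)
  v <- matrix(stats::rnorm(200, 20, 2), 50, 4)
  v[stats::runif(200) < 0.2] <- NA
  m <- toy_matrix(v)
  i1 <- impute_downshifted_normal(m, seed = 99)
  i2 <- impute_downshifted_normal(m, seed = 99)
  expect_identical(im_values(i1), im_values(i2))
  expect_false(anyNA(im_values(i1)))
  obs <- !is.na(v)
  expect_equal(im_values(i1)[obs], v[obs])
  complete <- toy_matrix(matrix(stats::rnorm(40, 20), 10, 4))
  expect_identical(im_values(impute_downshifted_normal(complete)),
                   im_values(complete))
})

test_that("imputation refuses samples with fewer than two observed values", {
  v <- matrix(stats::rnorm(12, 20), 3, 4)
  v[1:2, 1] <- NA
  v[3, 1] <- NA  # sample 1 now has zero observed values
  m <- toy_matrix(v)
  expect_error(impute_downshifted_normal(m), "fewer than 2")
})

test_that("filter-then-impute preserves every originally observed cell", {
  set.seed(9)
  v <- matrix(stats::rnorm(300, 20, 2), 30, 10,
              dimnames = list(paste0("r", 1:30), paste0("s", 1:10)))
  v[stats::runif(300) < 0.25] <- NA
  m <- toy_matrix(v)
  filt <- filter_valid_values(m, 0.7)
  imp <- impute_downshifted_normal(filt$matrix, seed = 5)
  kept <- rownames(im_values(filt$matrix))
  obs <- !is.na(v[kept, ])
  expect_equal(im_values(imp)[obs], v[kept, ][obs])
})
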