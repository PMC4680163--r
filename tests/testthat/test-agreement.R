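# Brute-force two-way ANOVA ICC via stats::aov, used as an independent
# route to the variance-component mean squares.
icc_via_aov <- function(y, consistency = FALSE) {
  df <- data.frame(
    value = as.vector(y),
    subject = factor(rep(seq_len(nrow(y)), ncol(y))),
    rater = factor(rep(seq_len(ncol(y)), each = nrow(y)))
  )
  ms <- summary(stats::aov(value ~ subject + rater, data = df))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  n <- nrow(y); k <- ncol(y)
  if (consistency) (msr - mse) / (msr + (k - 1) * mse)
  else (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

test_that("ICC is exactly 1 for duplicated raters and matches an ANOVA oracle", {
  y <- cbind(c(1, 5, 9, 13, 2.5), c(1, 5, 9, 13, 2.5))
  expect_identical(icc(y)$icc, 1)
  y2 <- withr::with_seed(1, matrix(stats::rnorm(60), ncol = 3))
  expect_equal(icc(y2)$icc, icc_via_aov(y2), tolerance = 1e-10)
  expect_equal(icc(y2, "two_way_mixed_consistency_single")$icc,
               icc_via_aov(y2, consistency = TRUE), tolerance = 1e-10)
})

test_that("ICC approaches its closed-form value under a known error model", {
  # rater 2 = rater 1 + noise with noise SD equal to the subject SD:
  # consistency ICC tends to 2 sigma^2 / (2 sigma^2 + sigma^2) = 2/3
  y <- withr::with_seed(42, {
    s <- stats::rnorm(2000)
    cbind(s, s + stats::rnorm(2000))
  })
  expect_equal(icc(y, "two_way_mixed_consistency_single")$icc, 2 / 3,
               tolerance = 0.04)
  # independent columns: ICC near 0
  y0 <- withr::with_seed(43, cbind(stats::rnorm(2000), stats::rnorm(2000)))
  expect_lt(abs(icc(y0)$icc), 3 / sqrt(2000))
})

test_that("ICC input contracts: long data, missing cells, zero variance", {
  df <- tidyr::expand_grid(subject = 1:4, rater = c("a", "b"))
  df$value <- c(1, 1.1, 2, 2.2, 3, 3.1, 4, 4.4)
  expect_equal(icc(df)$icc,
               icc(matrix(df$value, ncol = 2, byrow = TRUE))$icc)
  expect_error(icc(df[-1, ]), "missing cells")
  expect_error(icc(matrix(5, 3, 2)), "zero total variance")
  expect_error(icc(matrix(1:2, 1, 2)), "at least 2 subjects")
})

test_that("absolute-agreement ICC is invariant under a shared affine map only", {
  y <- withr::with_seed(7, {
    s <- stats::rnorm(20, 10, 2)
    cbind(s + stats::rnorm(20, 0, 0.5), s + stats::rnorm(20, 0, 0.5))
  })
  shared <- icc(3 * y + 5)$icc
  expect_equal(shared, icc(y)$icc, tolerance = 1e-12)
  # a per-rater shift changes absolute agreement but not consistency
  # (shift large enough to dominate the sample's incidental rater offset)
  y_shift <- y; y_shift[, 2] <- y_shift[, 2] + 10
  expect_lt(icc(y_shift)$icc, icc(y)$icc)
  expect_equal(icc(y_shift, "two_way_mixed_consistency_single")$icc,
               icc(y, "two_way_mixed_consistency_single")$icc,
               tolerance = 1e-12)
})

test_that("ICC recovers the generating variance ratio", {
  truth <- 0.7
  sigma_s <- sqrt(truth); sigma_e <- sqrt(1 - truth)
  est <- withr::with_seed(99, vapply(1:50, function(i) {
    s <- stats::rnorm(300, sd = sigma_s)
    y <- cbind(s + stats::rnorm(300, sd = sigma_e),
               s + stats::rnorm(300, sd = sigma_e))
    icc(y, "two_way_mixed_consistency_single")$icc
  }, numeric(1)))
  expect_equal(mean(est), truth, tolerance = 0.05)
})

test_that("Bland-Altman recovers known agreement structure", {
  x <- c(1, 2, 3, 4, 5)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$mean_diff, 0)
  expect_equal(ba0$slope, 0)
  expect_equal(c(ba0$loa_low, ba0$loa_high), c(0, 0))
  # pure proportional bias: x' = 0.56 y gives a negative slope
  y <- withr::with_seed(3, stats::runif(100, 1, 60))
  bap <- bland_altman(0.56 * y, y)
  expect_lt(bap$slope, 0)
  # OLS recovery of an injected difference-vs-mean slope of -0.4
  m <- withr::with_seed(4, stats::runif(400, 5, 50))
  d <- withr::with_seed(5, -0.4 * m + stats::rnorm(400, sd = 1))
  x2 <- m + d / 2; y2 <- m - d / 2
  bar <- bland_altman(x2, y2)
  se <- sqrt(diag(stats::vcov(stats::lm(d ~ m))))[2]
  expect_equal(bar$slope, -0.4, tolerance = 4 * se / 0.4)
  expect_lt(bar$p_slope, 1e-10)
})

test_that("Bland-Altman is antisymmetric and validates its inputs", {
  x <- withr::with_seed(8, stats::rnorm(20, 10))
  y <- withr::with_seed(9, stats::rnorm(20, 10))
  expect_equal(bland_altman(x, y)$mean_diff, -bland_altman(y, x)$mean_diff)
  expect_error(bland_altman(1:4, 1:5), "same length")
  expect_error(bland_altman(c(1, 1, 1), c(1, 1, 1)), "slope undefined")
  td <- tidy(bland_altman(x, y))
  expect_true(all(c("mean_diff", "loa_low", "loa_high", "slope", "p_slope")
                  %in% names(td)))
  p <- autoplot(bland_altman(x, y))
  expect_s3_class(p, "ggplot")
})

test_that("paired comparison handles shifts and degenerate differences", {
  x <- withr::with_seed(10, stats::rnorm(50))
  same <- paired_compare(x, x)
  expect_equal(same$mean_diff, 0)
  expect_equal(same$p_value, 1)
  shifted <- paired_compare(x + 1, x)
  expect_equal(shifted$mean_diff, 1)
  expect_lt(shifted$p_value, 1e-6)  # t = sd(d)=0 handled separately below
  expect_identical(shifted$p_value, .Machine$double.xmin)
  noisy <- paired_compare(x + 1 + withr::with_seed(11, stats::rnorm(50, 0, 0.1)), x)
  expect_lt(noisy$p_value, 1e-6)
  wil <- paired_compare(x + 1, x, test = "wilcoxon")
  expect_identical(wil$p_value, .Machine$double.xmin)
})

test_that("Spearman correlation matches the brute-force rank formula on ties", {
  x <- c(1, 2, 2, 3, 3, 3, 4, 10)
  y <- c(2, 1, 3, 3, 5, 4, 4, 9)
  rs <- spearman_rs(x, y)$rs
  brute <- stats::cor(rank(x), rank(y))
  expect_equal(rs, brute, tolerance = 1e-12)
  expect_equal(spearman_rs(1:10, exp(1:10))$rs, 1)
  expect_equal(spearman_rs(1:10, rev(1:10))$rs, -1)
  expect_error(spearman_rs(rep(1, 5), 1:5), "constant")
})
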