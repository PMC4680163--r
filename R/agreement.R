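#' Intraclass correlation coefficient from a subjects-by-raters grid
#'
#' Single-measurement ICC computed from the two-way mean squares
#' (subjects, raters, error). Two forms are provided and every result is
#' labelled with the one used:
#'
#' * `"two_way_random_absolute_single"` (default): two-way random effects,
#'   absolute agreement - raters are interchangeable and systematic rater
#'   offsets count against agreement;
#' * `"two_way_mixed_consistency_single"`: two-way mixed effects,
#'   consistency - rater offsets are ignored.
#'
#' @param data A data frame in long format with columns named by
#'   `subject`, `rater`, `value` (defaults `subject`, `rater`, `value`),
#'   or a numeric matrix with one row per subject and one column per
#'   rater.
#' @param model ICC form, see above.
#' @param subject,rater,value Column names when `data` is a data frame.
#' @return An object of class `icc_result` with fields `icc`, `model`,
#'   `n_subjects`, `n_raters` and the component mean squares.
#' @export
icc <- function(data,
                model = c("two_way_random_absolute_single",
                          "two_way_mixed_consistency_single"),
                subject = "subject", rater = "rater", value = "value") {
  model <- match.arg(model)
  if (is.data.frame(data)) {
    wide <- tidyr::pivot_wider(
      dplyr::select(data, dplyr::all_of(c(subject, rater, value))),
      names_from = dplyr::all_of(rater), values_from = dplyr::all_of(value)
    )
    y <- as.matrix(wide[, -1, drop = FALSE])
  } else {
    y <- as.matrix(data)
  }
  if (anyNA(y)) stop("ICC grid has missing cells; no imputation is performed",
                     call. = FALSE)
  n <- nrow(y); k <- ncol(y)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 raters",
                             call. = FALSE)
  grand <- mean(y)
  if (sum((y - grand)^2) == 0) stop("zero total variance", call. = FALSE)
  rm <- rowMeans(y); cm <- colMeans(y)
  msr <- k * sum((rm - grand)^2) / (n - 1)
  msc <- n * sum((cm - grand)^2) / (k - 1)
  sse <- sum((y - outer(rm, rep(1, k)) - outer(rep(1, n), cm) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  est <- switch(model,
    two_way_random_absolute_single =
      (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n),
    two_way_mixed_consistency_single =
      (msr - mse) / (msr + (k - 1) * mse)
  )
  structure(
    list(icc = est, model = model, n_subjects = n, n_raters = k,
         msr = msr, msc = msc, mse = mse),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC = %.3f (%s; %d subjects x %d raters)\n",
              x$icc, x$model, x$n_subjects, x$n_raters))
  invisible(x)
}

#' @rdname icc
#' @param x An `icc_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.icc_result <- function(x, ...) {
  tibble::tibble(
    estimate = x$icc, model = x$model,
    n_subjects = x$n_subjects, n_raters = x$n_raters
  )
}

#' @rdname icc
#' @exportS3Method generics::glance
glance.icc_result <- function(x, ...) tidy.icc_result(x)

#' Bland-Altman method comparison
#'
#' For paired measurements of the same quantity by two methods, computes
#' the differences `d = x - y` and pairwise means `m = (x + y) / 2`, the
#' mean difference with its 95% limits of agreement (mean +/- 1.96 SD),
#' and the ordinary least-squares regression of difference on mean whose
#' slope captures proportional bias (an underestimate that grows with
#' lesion size gives a negative slope when `x` is the modified method and
#' `y` the reference).
#'
#' @param x,y Equal-length numeric vectors (length >= 3): `x` the method
#'   under scrutiny, `y` the reference.
#' @return An object of class `bland_altman`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be the same length",
                                   call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  d <- x - y
  m <- (x + y) / 2
  if (stats::sd(m) == 0) stop("pairwise means are constant; slope undefined",
                              call. = FALSE)
  mean_diff <- mean(d)
  sd_diff <- stats::sd(d)
  fit <- stats::lm(d ~ m)
  # an exact proportional bias gives a perfect fit; that is a valid input,
  # not a numerical problem worth a warning
  sfit <- suppressWarnings(summary(fit))
  structure(
    list(
      data = tibble::tibble(m = m, d = d),
      mean_diff = mean_diff, sd_diff = sd_diff,
      loa_low = mean_diff - 1.96 * sd_diff,
      loa_high = mean_diff + 1.96 * sd_diff,
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r2 = sfit$r.squared,
      p_slope = if (nrow(sfit$coefficients) > 1)
        sfit$coefficients[2, 4] else NA_real_,
      n = length(x)
    ),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman (n=%d): mean diff %.3f, LoA [%.3f, %.3f]\n  slope %.3f (p=%.2g), r2 %.2f\n",
    x$n, x$mean_diff, x$loa_low, x$loa_high, x$slope, x$p_slope, x$r2))
  invisible(x)
}

#' @rdname bland_altman
#' @param x A `bland_altman` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.bland_altman <- function(x, ...) {
  tibble::tibble(
    mean_diff = x$mean_diff, sd_diff = x$sd_diff,
    loa_low = x$loa_low, loa_high = x$loa_high,
    slope = x$slope, intercept = x$intercept,
    r2 = x$r2, p_slope = x$p_slope, n = x$n
  )
}

#' @rdname bland_altman
#' @exportS3Method generics::glance
glance.bland_altman <- function(x, ...) tidy.bland_altman(x)

#' @rdname bland_altman
#' @param object A `bland_altman` object.
#' @exportS3Method ggplot2::autoplot
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = m, y = d)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$mean_diff, linetype = 1) +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = 2) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "Mean of methods (cm³)",
      y = "Difference between methods (cm³)",
      title = sprintf("Bland-Altman: slope %.2f, mean diff %.2f",
                      object$slope, object$mean_diff)
    ) +
    ggplot2::theme_minimal()
}

#' Paired comparison of two methods
#'
#' Mean difference and p-value for paired measurements; a paired t test by
#' default, Wilcoxon signed-rank as an alternative. When the differences
#' have zero variance but a nonzero mean the p-value is reported at the
#' machine floor rather than failing.
#'
#' @param x,y Paired numeric vectors, length >= 3.
#' @param test `"t"` (default) or `"wilcoxon"`.
#' @return A one-row tibble: `mean_diff`, `p_value`, `test`, `n`.
#' @export
paired_compare <- function(x, y, test = c("t", "wilcoxon")) {
  test <- match.arg(test)
  if (length(x) != length(y)) stop("x and y must be the same length",
                                   call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  d <- x - y
  # mirror t.test's degeneracy guard: a standard error this far below the
  # mean difference means the differences are constant to rounding
  degenerate <- stats::sd(d) / sqrt(length(d)) <=
    10 * .Machine$double.eps * max(abs(mean(d)), 1e-300)
  if (stats::sd(d) == 0 || degenerate) {
    p <- if (mean(d) == 0) 1 else .Machine$double.xmin
  } else {
    p <- if (test == "t") stats::t.test(x, y, paired = TRUE)$p.value
    else suppressWarnings(stats::wilcox.test(x, y, paired = TRUE)$p.value)
  }
  tibble::tibble(mean_diff = mean(d), p_value = p, test = test, n = length(x))
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties, plus its p-value.
#'
#' @param x,y Numeric vectors, length >= 3.
#' @return A one-row tibble: `rs`, `p_value`, `n`.
#' @export
spearman_rs <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be the same length",
                                   call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("rank correlation undefined for a constant vector", call. = FALSE)
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  tibble::tibble(rs = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x))
}
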