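#' Root mean square error
#'
#' `sqrt(mean((estimated - actual)^2))`, in the units of its inputs
#' (t/ha for yield validation).
#'
#' @param estimated,actual Equal-length numeric vectors.
#' @return Scalar RMSE.
#' @export
rmse <- function(estimated, actual) {
  if (length(estimated) != length(actual)) {
    rlang::abort("`estimated` and `actual` must have equal length")
  }
  if (length(estimated) == 0L) rlang::abort("empty input")
  sqrt(mean((estimated - actual)^2))
}

#' Pearson correlation and its square
#'
#' Standard product-moment correlation; `r2` is reported from the
#' correlation (not from a regression through the origin).
#'
#' @param x,y Equal-length numeric vectors, length at least 3, neither
#'   constant.
#' @return A list with `r` and `r2`.
#' @export
pearson_r2 <- function(x, y) {
  if (length(x) != length(y)) rlang::abort("`x` and `y` must have equal length")
  if (length(x) < 3L) rlang::abort("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rlang::abort("correlation is undefined for a constant input")
  }
  r <- stats::cor(x, y)
  list(r = r, r2 = r^2)
}

#' Group summary for summary-statistics tests
#'
#' @param mean Group mean.
#' @param sd Group standard deviation (a reported `mean +/- spread` is
#'   read as mean and standard deviation).
#' @param n Group size, at least 2.
#' @return A list of class `group_summary`.
#' @export
group_summary <- function(mean, sd, n) {
  if (n < 2L) rlang::abort("`n` must be at least 2")
  if (sd < 0) rlang::abort("`sd` must be >= 0")
  structure(list(mean = mean, sd = sd, n = as.integer(n)),
            class = "group_summary")
}

#' Two-sample t-test from summary statistics
#'
#' The test used to validate UAV-derived heights against manual tape
#' measurements when only group means, standard deviations and sizes are
#' reported: e.g. manually measured wall heights (1.13 +/- 0.13 m, n = 13)
#' against UAV-estimated wall heights (1.18 +/- 0.22 m, n = 13).
#'
#' @param a,b [group_summary()] objects (or lists with `mean`, `sd`, `n`).
#' @param variant `"welch"` (default; Welch-Satterthwaite degrees of
#'   freedom, appropriate for unequal spreads) or `"pooled"`
#'   (`n1 + n2 - 2` df).
#' @return A one-row tibble: `t`, `df`, `p` (two-tailed), `variant`,
#'   `degenerate` (TRUE when both sds are zero and the statistic is
#'   undefined; `p = 1` by convention when the means are also equal).
#' @export
t_test_from_summary <- function(a, b, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  for (g in list(a, b)) {
    if (is.null(g$mean) || is.null(g$sd) || is.null(g$n) || g$n < 2L) {
      rlang::abort("`a` and `b` must be group summaries with mean, sd and n >= 2")
    }
  }
  degenerate <- a$sd == 0 && b$sd == 0
  if (degenerate && a$mean == b$mean) {
    return(tibble::tibble(t = 0, df = NA_real_, p = 1, variant = variant,
                          degenerate = TRUE))
  }
  if (degenerate) {
    return(tibble::tibble(t = Inf * sign(a$mean - b$mean), df = NA_real_, p = 0,
                          variant = variant, degenerate = TRUE))
  }
  if (variant == "welch") {
    v1 <- a$sd^2 / a$n
    v2 <- b$sd^2 / b$n
    tt <- (a$mean - b$mean) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (a$n - 1) + v2^2 / (b$n - 1))
  } else {
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
    tt <- (a$mean - b$mean) / sqrt(sp2 * (1 / a$n + 1 / b$n))
  }
  tibble::tibble(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df),
                 variant = variant, degenerate = FALSE)
}

#' Validation report for estimated vs actual yields
#'
#' @param estimated,actual Equal-length numeric vectors (t/ha).
#' @return An object of class `validation_report`: `n`, `r`, `r2`, `rmse`,
#'   `slope`, `intercept` (ordinary least squares of actual on estimated).
#' @export
validation_report <- function(estimated, actual) {
  pr <- pearson_r2(estimated, actual)
  fit <- stats::lm.fit(cbind(1, estimated), actual)
  structure(list(n = length(estimated), r = pr$r, r2 = pr$r2,
                 rmse = rmse(estimated, actual),
                 slope = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 estimated = estimated, actual = actual),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "<validation_report> n = %d, r = %.4f, R^2 = %.4f, RMSE = %.4f, fit: actual = %.4f + %.4f * estimated\n",
    x$n, x$r, x$r2, x$rmse, x$intercept, x$slope))
  invisible(x)
}
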