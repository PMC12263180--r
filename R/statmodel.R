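#' Fit a staining-time course by ordinary least squares
#'
#' Linear regression of a per-spheroid response (penetration depth in um, or
#' fractional depth) on staining time in minutes. The fit is not forced
#' through the origin. R-squared is reported as 0 when the responses have
#' zero total variance (a constant response carries no trend information).
#'
#' @param times Staining times, minutes (>= 3 values, >= 2 distinct).
#' @param responses Response values, same length.
#' @param response Label for the response (carried in output).
#' @return Object of class `timecourse_fit` wrapping the [stats::lm] fit,
#'   with `slope`, `intercept`, `r_squared`, `n` and `response`.
#' @examples
#' fit <- fit_timecourse(c(0, 1, 2), c(0, 1, 3))
#' fit$slope
#' @export
fit_timecourse <- function(times, responses, response = "response") {
  if (length(times) != length(responses)) abort("times and responses lengths differ")
  ok <- is.finite(times) & is.finite(responses)
  times <- times[ok]
  responses <- responses[ok]
  if (length(times) < 3) abort("need at least 3 points to fit a time course")
  if (length(unique(times)) < 2) abort("all staining times identical; slope undefined")
  fit <- lm(responses ~ times)
  sst <- sum((responses - mean(responses))^2)
  r2 <- if (sst <= 0) 0 else 1 - sum(stats::residuals(fit)^2) / sst
  structure(
    list(
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      r_squared = r2,
      n = length(times),
      response = response,
      data = tibble(time_min = times, response = responses),
      lm = fit
    ),
    class = "timecourse_fit"
  )
}

#' @export
print.timecourse_fit <- function(x, ...) {
  cat(sprintf("<timecourse_fit> %s = %.4g + %.4g * t, R2 = %.3f, n = %d\n",
              x$response, x$intercept, x$slope, x$r_squared, x$n))
  invisible(x)
}

#' @export
tidy.timecourse_fit <- function(x, ...) {
  se <- suppressWarnings(summary(x$lm)$coefficients[, "Std. Error"])
  tibble(
    term = c("(Intercept)", "time_min"),
    estimate = c(x$intercept, x$slope),
    std.error = unname(se)
  )
}

#' @export
glance.timecourse_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, slope = x$slope, intercept = x$intercept,
         n = x$n, response = x$response)
}

#' Predicted time of complete penetration
#'
#' For a fit of fractional penetration depth on staining time, solves
#' `intercept + slope * t = 1` for the staining time at which the
#' regression line reaches complete penetration.
#'
#' @param fit A [fit_timecourse()] result with positive slope.
#' @return Predicted time in minutes.
#' @export
predict_complete_time <- function(fit) {
  stopifnot(inherits(fit, "timecourse_fit"))
  if (fit$slope <= 0) {
    abort("slope is not positive: the fit predicts no completion time")
  }
  (1 - fit$intercept) / fit$slope
}

#' @export
autoplot.timecourse_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$time_min, .data$response)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope) +
    ggplot2::labs(x = "staining time (min)", y = object$response,
                  title = sprintf("R2 = %.2f", object$r_squared))
}

#' Variance-gated two-group comparison
#'
#' The two-stage test used throughout the intensity comparisons: first a
#' two-sided F-test of variance equality at level `alpha`; if the variances
#' differ significantly, group means are compared with Welch's two-tailed
#' t-test, otherwise with the unpaired Student's (pooled-variance)
#' two-tailed t-test. Significance of the mean comparison is declared at
#' `alpha`.
#'
#' @param a,b Numeric vectors (each n >= 2; not both zero-variance).
#' @param alpha Significance level, default 0.05.
#' @return Object of class `group_comparison`: test_used ("student" or
#'   "welch"), f_statistic, f_p_value, t_statistic, df, p_value,
#'   significant, group means/SDs/sizes, alpha.
#' @examples
#' compare_groups(c(1, 2, 3), c(2, 4, 6))$test_used
#' @export
compare_groups <- function(a, b, alpha = 0.05) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) abort("each group needs at least 2 values")
  if (var(a) == 0 && var(b) == 0) {
    abort("both groups have zero variance; comparison is degenerate")
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")

  ft <- var.test(a, b)
  welch <- ft$p.value < alpha
  tt <- t.test(a, b, var.equal = !welch)
  structure(
    list(
      test_used = if (welch) "welch" else "student",
      f_statistic = unname(ft$statistic),
      f_p_value = ft$p.value,
      t_statistic = unname(tt$statistic),
      df = unname(tt$parameter),
      p_value = tt$p.value,
      significant = tt$p.value < alpha,
      mean_a = mean(a), mean_b = mean(b),
      sd_a = sd(a), sd_b = sd(b),
      n_a = length(a), n_b = length(b),
      alpha = alpha
    ),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s t-test: t = %.3f, p = %.4g%s\n",
              x$test_used, x$t_statistic, x$p_value,
              if (x$significant) paste0(" ", significance_stars(x$p_value)) else ""))
  cat(sprintf("  F = %.3f (p = %.4g); a: %.3g +/- %.3g (n=%d), b: %.3g +/- %.3g (n=%d)\n",
              x$f_statistic, x$f_p_value, x$mean_a, x$sd_a, x$n_a,
              x$mean_b, x$sd_b, x$n_b))
  invisible(x)
}

#' @export
tidy.group_comparison <- function(x, ...) {
  tibble(
    test_used = x$test_used,
    f_statistic = x$f_statistic,
    f_p_value = x$f_p_value,
    t_statistic = x$t_statistic,
    df = x$df,
    p_value = x$p_value,
    significant = x$significant,
    stars = significance_stars(x$p_value),
    mean_a = x$mean_a, sd_a = x$sd_a, n_a = x$n_a,
    mean_b = x$mean_b, sd_b = x$sd_b, n_b = x$n_b
  )
}

#' @export
glance.group_comparison <- function(x, ...) tidy(x)

#' Significance stars for a p-value
#'
#' Convention: `****` for p <= 1e-4, `***` for p <= 1e-3, `**` for p <= 1e-2,
#' `*` for p < 0.05, `ns` otherwise.
#'
#' @param p P-value(s).
#' @return Character vector of star labels.
#' @export
significance_stars <- function(p) {
  dplyr::case_when(
    p <= 1e-4 ~ "****",
    p <= 1e-3 ~ "***",
    p <= 1e-2 ~ "**",
    p < 0.05 ~ "*",
    .default = "ns"
  )
}

#' Mean, sample SD and n of a vector
#'
#' Summaries are reported as mean +/- SD with the n - 1 denominator; a
#' single observation reports SD 0 with a flag.
#'
#' @param values Numeric vector (non-empty).
#' @return One-row tibble: mean, sd, n, single_observation.
#' @export
summarize_values <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0) abort("no values to summarize")
  tibble(
    mean = mean(values),
    sd = if (length(values) > 1) sd(values) else 0,
    n = length(values),
    single_observation = length(values) == 1
  )
}
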