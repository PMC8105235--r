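#' Agreement statistics between a test and a reference measurement
#'
#' The evaluation battery for paired measurements: ordinary least squares of
#' test on reference (slope, intercept, 95% CIs), Pearson r, Lin's
#' concordance correlation coefficient, RMSE about the identity line
#' (accuracy versus the reference), RMSD about the regression fit
#' (precision), and Bland-Altman bias with 95% limits of agreement.
#'
#' Lin's CCC uses population (1/n) moments by default, per its original
#' definition: `CCC = 2*s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)`.
#' Confidence intervals are normal-theory (Fisher z for r, Lin's z-transform
#' for the CCC).
#'
#' @param x Reference values.
#' @param y Test values (same length, n >= 3, finite).
#' @param moments `"population"` (1/n, default) or `"sample"` (1/(n-1))
#'   moments for the CCC.
#' @param conf_level Confidence level for intervals, default 0.95.
#'
#' @return An `fpa_agreement` object; see [tidy()] and [glance()] methods.
#' @export
agreement <- function(x, y, moments = c("population", "sample"),
                      conf_level = 0.95) {
  moments <- match.arg(moments)
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (n < 3L) abort("need at least 3 paired values.")
  if (length(y) != n) abort("`x` and `y` lengths differ.")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    abort("values must be finite.")
  if (var(x) == 0) abort("zero variance in the reference values: regression undefined.")

  fit <- lm(y ~ x)
  # confint warns on exact fits (zero residual variance); the CI is then
  # degenerate at the estimate, which is the right answer here
  ci <- withCallingHandlers(
    confint(fit, level = conf_level),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  ci[!is.finite(ci)] <- rep(coef(fit), 2)[!is.finite(ci)]
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  r <- cor(x, y)

  denom_n <- if (moments == "population") n else n - 1L
  sx2 <- sum((x - mean(x))^2) / denom_n
  sy2 <- sum((y - mean(y))^2) / denom_n
  sxy <- sum((x - mean(x)) * (y - mean(y))) / denom_n
  ccc <- 2 * sxy / (sx2 + sy2 + (mean(x) - mean(y))^2)

  zq <- qnorm(1 - (1 - conf_level) / 2)
  # Fisher z interval for r.
  r_ci <- if (abs(r) < 1) {
    zr <- atanh(r); se <- 1 / sqrt(n - 3)
    tanh(zr + c(-1, 1) * zq * se)
  } else c(r, r)
  # Lin's z-transform interval for the CCC.
  ccc_ci <- if (abs(ccc) < 1 && abs(r) > 0 && abs(r) < 1) {
    u <- (mean(x) - mean(y)) / (sx2 * sy2)^(1/4)
    C <- ccc
    se_z2 <- ((1 - r^2) * C^2 / ((1 - C^2) * r^2) +
              4 * C^3 * (1 - C) * u^2 / (r * (1 - C^2)^2) -
              2 * C^4 * u^4 / (r^2 * (1 - C^2)^2)) / (n - 2)
    tanh(atanh(C) + c(-1, 1) * zq * sqrt(max(se_z2, 0)))
  } else c(ccc, ccc)

  resid <- y - stats::fitted(fit)
  diffs <- y - x
  bias <- mean(diffs)
  sd_diff <- sd(diffs)

  structure(list(
    n = n, slope = slope, intercept = intercept,
    slope_ci = unname(ci[2, ]), intercept_ci = unname(ci[1, ]),
    r = r, r_ci = r_ci, ccc = ccc, ccc_ci = ccc_ci,
    rmse = sqrt(mean(diffs^2)), rmsd = sqrt(mean(resid^2)),
    bias = bias, sd_diff = sd_diff,
    loa = bias + c(-1, 1) * 1.96 * sd_diff,
    conf_level = conf_level, moments = moments,
    x = x, y = y, fit = fit
  ), class = "fpa_agreement")
}

#' @export
print.fpa_agreement <- function(x, ...) {
  cat(sprintf("<fpa_agreement> n = %d\n", x$n))
  cat(sprintf("  y = %.3f x + %.3f   r = %.3f, CCC = %.3f\n",
              x$slope, x$intercept, x$r, x$ccc))
  cat(sprintf("  RMSE = %.3f (vs reference), RMSD = %.3f (vs fit)\n",
              x$rmse, x$rmsd))
  cat(sprintf("  Bland-Altman bias = %.3f, LOA [%.3f, %.3f]\n",
              x$bias, x$loa[1], x$loa[2]))
  invisible(x)
}

#' @describeIn agreement Term-level tibble (slope, intercept, r, CCC with
#'   confidence intervals).
#' @param x An `fpa_agreement` object.
#' @param ... Unused.
#' @method tidy fpa_agreement
#' @export
tidy.fpa_agreement <- function(x, ...) {
  tibble(
    term = c("slope", "intercept", "pearson_r", "ccc"),
    estimate = c(x$slope, x$intercept, x$r, x$ccc),
    conf.low = c(x$slope_ci[1], x$intercept_ci[1], x$r_ci[1], x$ccc_ci[1]),
    conf.high = c(x$slope_ci[2], x$intercept_ci[2], x$r_ci[2], x$ccc_ci[2])
  )
}

#' @describeIn agreement One-row summary tibble.
#' @method glance fpa_agreement
#' @export
glance.fpa_agreement <- function(x, ...) {
  tibble(n = x$n, slope = x$slope, intercept = x$intercept, r = x$r,
         ccc = x$ccc, rmse = x$rmse, rmsd = x$rmsd, bias = x$bias,
         loa_lower = x$loa[1], loa_upper = x$loa[2])
}
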