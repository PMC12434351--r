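#' Fit a power law relating count SD to camera coverage
#'
#' Fits SD = a / coverage^b by ordinary least squares on log-transformed
#' variables: log(SD) is regressed on log(coverage percent), the exponent is
#' the negated slope and the coefficient is the back-transformed intercept
#' (so \code{a} is the predicted SD at 1\% coverage). Natural logarithms are
#' used internally; the fit is invariant to the log base.
#'
#' @param coverage_percents Coverage levels in percent, all > 0, length >= 3.
#' @param sds Standard deviations at each level, all > 0.
#' @return An object of class \code{power_law_fit}: list with
#'   \code{coefficient_a}, \code{exponent_b}, \code{r_squared},
#'   \code{f_statistic}, \code{df_num} (1), \code{df_den} (n - 2),
#'   \code{p_value}, \code{n_points}, and the underlying \code{lm} fit in
#'   \code{model}.
#' @examples
#' cov <- c(2, 5, 10, 20, 30, 40)
#' fit <- fit_power_law(cov, 2.5 / cov^0.5)
#' fit$exponent_b   # 0.5
#' @export
fit_power_law <- function(coverage_percents, sds) {
  if (length(coverage_percents) != length(sds)) {
    stop("coverage_percents and sds must have equal length")
  }
  if (length(sds) < 3) stop("need at least 3 points to fit")
  if (any(coverage_percents <= 0) || any(sds <= 0)) {
    stop("all coverages and SDs must be strictly positive (log scale)")
  }
  d <- data.frame(lc = log(coverage_percents), ls = log(sds))
  model <- stats::lm(ls ~ lc, data = d)
  # an exactly power-law input is legitimate here; silence lm's
  # perfect-fit diagnostic but let any other warning through
  sm <- withCallingHandlers(
    summary(model),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  fstat <- sm$fstatistic
  structure(
    list(
      coefficient_a = exp(unname(stats::coef(model)[1])),
      exponent_b = -unname(stats::coef(model)[2]),
      r_squared = sm$r.squared,
      f_statistic = unname(fstat["value"]),
      df_num = as.integer(fstat["numdf"]),
      df_den = as.integer(fstat["dendf"]),
      p_value = unname(stats::pf(fstat["value"], fstat["numdf"],
                                 fstat["dendf"], lower.tail = FALSE)),
      n_points = length(sds),
      model = model
    ),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf(
    "Power-law fit: SD = %.6g / Coverage^%.5g  (R^2 = %.4f, F(%d,%d) = %.4g, p = %.3g, n = %d)\n",
    x$coefficient_a, x$exponent_b, x$r_squared, x$df_num, x$df_den,
    x$f_statistic, x$p_value, x$n_points
  ))
  invisible(x)
}

#' Predict count SD from a fitted power law
#'
#' @param fit A \code{power_law_fit}.
#' @param coverage_percent Coverage in percent, > 0 (vectorised).
#' @return Predicted SD(s): \code{a / coverage^b}.
#' @examples
#' fit <- fit_power_law(c(2, 5, 10, 20, 30, 40),
#'                      2.5 / c(2, 5, 10, 20, 30, 40)^0.5)
#' predict_sd(fit, 25)  # 0.5
#' @export
predict_sd <- function(fit, coverage_percent) {
  stopifnot(inherits(fit, "power_law_fit"))
  if (any(coverage_percent <= 0)) stop("coverage must be positive")
  fit$coefficient_a / coverage_percent^fit$exponent_b
}
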