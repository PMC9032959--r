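#' Weibull psychometric function
#'
#' Probability of a correct response at stimulus intensity \code{x}:
#' \deqn{F(x) = \gamma + (1 - \gamma - \lambda)\,(1 - e^{-(x/a)^\beta})}
#' with guess rate \eqn{\gamma}, lapse rate \eqn{\lambda}, scale \eqn{a} and
#' shape \eqn{\beta}. The study fixes \eqn{\gamma = 0.05} and
#' \eqn{\lambda = 0}, leaving two free parameters.
#'
#' @param x stimulus intensities (grating width, mm).
#' @param scale,shape Weibull scale \eqn{a > 0} and shape \eqn{\beta > 0}.
#' @param gamma,lambda guess and lapse rates.
#' @return vector of response probabilities.
#' @export
weibull_psy <- function(x, scale, shape, gamma = 0.05, lambda = 0) {
  gamma + (1 - gamma - lambda) * (1 - exp(-(x / scale)^shape))
}

## scale a such that F(threshold) = level
weibull_scale_from_threshold <- function(threshold, shape, gamma = 0.05,
                                         lambda = 0, level = 0.82) {
  q <- (level - gamma) / (1 - gamma - lambda)
  if (q <= 0 || q >= 1)
    stop("threshold level unreachable for these gamma/lambda")
  threshold / (-log(1 - q))^(1 / shape)
}

#' Fit a Weibull psychometric function to 2AFC trials
#'
#' Per-width accuracies are fitted by least squares to the Weibull
#' psychometric function with fixed guess rate \eqn{\gamma = 0.05} and lapse
#' rate \eqn{\lambda = 0} (two free parameters: scale and shape). The
#' threshold is the grating width at which the fitted curve passes
#' \code{level} (default 82\%) accuracy, interpolated by root finding — so
#' by construction the fitted curve evaluated at the returned threshold is
#' exactly the threshold level. The slope is the derivative of the fitted
#' curve at threshold, and \eqn{R^2} measures how well the curve represents
#' the per-width accuracies. If the threshold level is only reached beyond
#' the tested width range, it is still returned, flagged as extrapolated.
#'
#' @param trials a \code{trial_table} (columns \code{grating_width_mm},
#'   \code{correct}) from [generate_psychophys_trials()] or equivalent.
#' @param gamma,lambda fixed guess and lapse rates.
#' @param level accuracy level defining the threshold.
#' @return an object of class \code{"weibull_fit"}: list with
#'   \code{threshold}, \code{slope}, \code{r_squared}, \code{scale},
#'   \code{shape}, \code{gamma}, \code{lambda}, \code{level},
#'   \code{extrapolated}, \code{data} (per-width accuracies).
#' @export
fit_weibull <- function(trials, gamma = 0.05, lambda = 0, level = 0.82) {
  df <- as.data.frame(trials)
  stopifnot(all(c("grating_width_mm", "correct") %in% names(df)))
  acc <- stats::aggregate(correct ~ grating_width_mm, df, mean)
  names(acc) <- c("width", "accuracy")
  acc$n <- as.numeric(table(df$grating_width_mm)[as.character(acc$width)])
  if (nrow(acc) < 2)
    stop("need trials at >= 2 distinct grating widths")
  sse <- function(par) {
    p <- weibull_psy(acc$width, exp(par[1]), exp(par[2]), gamma, lambda)
    sum((acc$accuracy - p)^2)
  }
  ## multi-start over plausible scales/shapes to avoid local minima
  starts <- expand.grid(scale = log(c(0.5, 1, 2, 4)),
                        shape = log(c(0.5, 1, 2, 4)))
  fits <- lapply(seq_len(nrow(starts)), function(i) {
    stats::optim(as.numeric(starts[i, ]), sse, method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 5000))
  })
  best <- fits[[which.min(vapply(fits, `[[`, 0, "value"))]]
  if (!is.finite(best$value)) stop("fit error: Weibull fit did not converge")
  a <- exp(best$par[1]); b <- exp(best$par[2])
  ## the threshold solves F(x) = level in closed form
  q <- (level - gamma) / (1 - gamma - lambda)
  threshold <- a * (-log(1 - q))^(1 / b)
  extrapolated <- threshold > max(acc$width) || threshold < min(acc$width)
  ## slope: dF/dx at threshold
  slope <- (1 - gamma - lambda) * exp(-(threshold / a)^b) *
    b * (threshold / a)^(b - 1) / a
  pred <- weibull_psy(acc$width, a, b, gamma, lambda)
  sst <- sum((acc$accuracy - mean(acc$accuracy))^2)
  r2 <- if (sst > 0) 1 - sum((acc$accuracy - pred)^2) / sst else NA_real_
  structure(list(threshold = threshold, slope = slope, r_squared = r2,
                 scale = a, shape = b, gamma = gamma, lambda = lambda,
                 level = level, extrapolated = extrapolated,
                 sse = best$value, data = acc),
            class = "weibull_fit")
}

#' @export
print.weibull_fit <- function(x, digits = 3, ...) {
  cat("Weibull psychometric fit (gamma =", x$gamma, ", lambda =",
      x$lambda, ")\n")
  cat(sprintf("  threshold (%d%% point): %s mm%s\n",
              round(100 * x$level), signif(x$threshold, digits),
              if (x$extrapolated) " [extrapolated]" else ""))
  cat("  slope at threshold:", signif(x$slope, digits),
      "  R^2:", signif(x$r_squared, digits), "\n")
  cat("  scale:", signif(x$scale, digits),
      "  shape:", signif(x$shape, digits), "\n")
  invisible(x)
}

#' @export
coef.weibull_fit <- function(object, ...) {
  c(scale = object$scale, shape = object$shape,
    threshold = object$threshold, slope = object$slope)
}

#' Predicted accuracy at new grating widths
#'
#' @param object a [fit_weibull()] result.
#' @param widths grating widths (mm); defaults to the fitted widths.
#' @param ... ignored.
#' @return vector of predicted accuracies.
#' @export
predict.weibull_fit <- function(object, widths = object$data$width, ...) {
  weibull_psy(widths, object$scale, object$shape, object$gamma,
              object$lambda)
}

#' @export
plot.weibull_fit <- function(x, ...) {
  xs <- seq(0, max(x$data$width) * 1.2, length.out = 200)
  graphics::plot(x$data$width, x$data$accuracy, ylim = c(0, 1),
                 xlab = "grating width (mm)", ylab = "proportion correct",
                 main = "Weibull psychometric fit", ...)
  graphics::lines(xs, predict(x, xs))
  graphics::abline(h = x$level, v = x$threshold, lty = 3)
  invisible(x)
}

#' d-prime sensitivity from hit and false-alarm rates
#'
#' Signal-detection sensitivity: the difference of the z-normalised
#' (standard-normal quantile) hit and false-alarm rates. Perfect rates are
#' clamped to \code{[1/(2n), 1 - 1/(2n)]} so the quantiles stay finite.
#'
#' @param hit_rate,fa_rate proportions in \code{[0, 1]}.
#' @param n_trials trial count underlying each rate; must be positive.
#' @return d' value.
#' @export
#' @examples
#' dprime(0.9, 0.1, 100)
dprime <- function(hit_rate, fa_rate, n_trials) {
  if (n_trials <= 0) stop("domain error: n_trials must be positive")
  if (hit_rate < 0 || hit_rate > 1 || fa_rate < 0 || fa_rate > 1)
    stop("rates must lie in [0, 1]")
  clamp <- function(p) pmin(pmax(p, 1 / (2 * n_trials)),
                            1 - 1 / (2 * n_trials))
  stats::qnorm(clamp(hit_rate)) - stats::qnorm(clamp(fa_rate))
}
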