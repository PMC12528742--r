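#' Thermal constant of one individual
#'
#' The law of total effective temperature states that development completes
#' when the accumulated degree-days above the lower developmental threshold
#' reach the thermal constant: \eqn{k = D (T - t_0)}.
#'
#' @param dev_time development time D in days (> 0).
#' @param temp rearing temperature T in degrees Celsius; must exceed
#'   \code{t0}.
#' @param t0 lower developmental threshold in degrees Celsius.
#' @return Accumulated degree-days \eqn{D (T - t_0)}.
#' @examples
#' effective_k(109.79, 15.0, 11.25)  # 411.7125 degree-days
#' @export
effective_k <- function(dev_time, temp, t0) {
  if (any(dev_time <= 0)) stop("dev_time must be > 0")
  if (any(temp <= t0))
    stop("below developmental threshold: temp must exceed t0")
  dev_time * (temp - t0)
}

#' Linear degree-day fit
#'
#' The classical linear model for development rate: ordinary least squares of
#' \eqn{1/D} on \eqn{T} yields slope \eqn{s} and intercept \eqn{a}, whence the
#' thermal constant \eqn{\hat k = 1/s} and threshold \eqn{\hat t_0 = -a/s}.
#'
#' @param data a \code{\link{development_data}} with at least 2 distinct
#'   temperatures.
#' @return A list of class \code{"degree_day_fit"} with \code{k_hat}
#'   (degree-days), \code{t0_hat} (degrees C) and \code{r_squared}.
#' @export
degree_day_fit <- function(data) {
  .assert_dataset(data, min_temps = 2L)
  rate <- 1 / data$dev_time
  fit <- stats::lm(rate ~ temp, data = data.frame(rate = rate,
                                                  temp = data$temp))
  s <- unname(stats::coef(fit)[2L])
  a <- unname(stats::coef(fit)[1L])
  if (!is.finite(s)) stop("singular design: cannot fit degree-day model")
  if (s <= 0)
    stop("no positive thermal constant: fitted rate does not increase with temperature")
  # suppress summary.lm's "essentially perfect fit" note on noise-free data
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(k_hat = 1 / s, t0_hat = -a / s, r_squared = r2),
            class = "degree_day_fit")
}

#' Ikemoto-Takai fit by reduced major axis regression
#'
#' The Ikemoto-Takai linearization regresses \eqn{y = DT} on \eqn{x = D}, so
#' that the slope estimates the threshold \eqn{t_0} and the intercept the
#' thermal constant \eqn{k}. The line is fitted by reduced major axis (RMA)
#' regression as its proposers suggested: slope \eqn{b = sign(r) s_y / s_x},
#' intercept \eqn{a = \bar y - b \bar x}. Standard errors use the large-sample
#' RMA approximations \eqn{se_b = |b| \sqrt{(1 - r^2)/n}} and
#' \eqn{se_a = \sqrt{s_y^2 (1-r^2)/n + \bar x^2 se_b^2}}. The fit uses every
#' individual record; set \code{aggregate = TRUE} to reproduce the common
#' published practice of reducing each temperature to its median development
#' time first.
#'
#' @param data a \code{\link{development_data}} with at least 3 records.
#' @param method \code{"rma"} (default) or \code{"ols"} for ordinary least
#'   squares of DT on D with its usual standard errors.
#' @param aggregate collapse each temperature to its median D before fitting.
#' @return A list of class \code{"it_fit"} with \code{t0_hat}, \code{k_hat},
#'   \code{se_t0}, \code{se_k}, \code{r} and \code{n_points}.
#' @export
ikemoto_takai_fit <- function(data, method = c("rma", "ols"),
                              aggregate = FALSE) {
  method <- match.arg(method)
  .assert_dataset(data)
  D <- data$dev_time
  Temp <- data$temp
  if (aggregate) {
    med <- tapply(D, Temp, stats::median)
    Temp <- as.numeric(names(med))
    D <- as.numeric(med)
  }
  n <- base::length(D)
  if (n < 3L) stop("at least 3 records are required")
  x <- D
  y <- D * Temp
  sx <- stats::sd(x)
  sy <- stats::sd(y)
  if (sx == 0) stop("zero variance in development time: cannot fit")
  if (sy == 0) stop("zero variance in DT: cannot fit")
  r <- stats::cor(x, y)
  if (method == "rma") {
    b <- sign(r) * sy / sx
    a <- mean(y) - b * mean(x)
    se_b <- abs(b) * sqrt((1 - r^2) / n)
    se_a <- sqrt(sy^2 * (1 - r^2) / n + mean(x)^2 * se_b^2)
  } else {
    fit <- stats::lm(y ~ x)
    cf <- suppressWarnings(summary(fit))$coefficients
    b <- cf[2L, 1L]; a <- cf[1L, 1L]
    se_b <- cf[2L, 2L]; se_a <- cf[1L, 2L]
  }
  if (a <= 0) stop("no positive thermal constant: fitted intercept <= 0")
  structure(list(t0_hat = b, k_hat = a, se_t0 = se_b, se_k = se_a, r = r,
                 n_points = n, method = method),
            class = "it_fit")
}

#' @export
print.it_fit <- function(x, ...) {
  cat(sprintf(
    "Ikemoto-Takai fit (%s, %d points): k = %.3f dd (se %.3f), t0 = %.3f C (se %.3f), r = %.4f\n",
    x$method, x$n_points, x$k_hat, x$se_k, x$t0_hat, x$se_t0, x$r))
  invisible(x)
}

#' Normal-approximation interval for the Ikemoto-Takai thermal constant
#'
#' The Ikemoto-Takai procedure yields a point estimate of k; a commonly used
#' (but not recommended) interval takes the estimate plus or minus z standard
#' errors. With the default z = 1.96 the nominal level is 95 percent.
#'
#' @param fit an \code{\link{ikemoto_takai_fit}} result.
#' @param z positive normal quantile multiplier (default 1.96).
#' @return A \code{\link{thermal_interval}} with scope
#'   \code{"ikemoto_takai"} and nominal level \eqn{2\Phi(z) - 1}.
#' @export
it_k_interval <- function(fit, z = 1.96) {
  if (!inherits(fit, "it_fit")) stop("expected an it_fit object")
  if (z <= 0) stop("z must be > 0")
  thermal_interval(lower = fit$k_hat - z * fit$se_k,
                   upper = fit$k_hat + z * fit$se_k,
                   level = 2 * stats::pnorm(z) - 1,
                   scope = "ikemoto_takai")
}
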