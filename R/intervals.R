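#' Construct a thermal interval
#'
#' A range of the thermal constant k (accumulated degree-days) at a stated
#' coverage level, together with the scope it applies to: the combined mixture,
#' a single component, or the Ikemoto-Takai baseline.
#'
#' @param lower,upper interval endpoints in degree-days, \code{lower <= upper}.
#' @param level coverage level in (0, 1).
#' @param scope one of \code{"combined"}, \code{"component:<index>"} or
#'   \code{"ikemoto_takai"}.
#' @return An object of class \code{"thermal_interval"}.
#' @export
thermal_interval <- function(lower, upper, level, scope = "combined") {
  if (!is.finite(lower) || !is.finite(upper) || lower > upper)
    stop("interval endpoints must be finite with lower <= upper")
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
  structure(list(lower = lower, upper = upper, level = level, scope = scope),
            class = "thermal_interval")
}

#' @export
print.thermal_interval <- function(x, ...) {
  cat(sprintf("%.0f%% interval (%s): [%.4f, %.4f] degree-days\n",
              100 * x$level, x$scope, x$lower, x$upper))
  invisible(x)
}

# parse a scope selector: "combined", "component:2", or an integer index
.parse_scope <- function(scope, model) {
  L <- nrow(model$components)
  if (is.numeric(scope)) {
    idx <- as.integer(scope)
    if (idx < 1L || idx > L) stop(sprintf("invalid component index %d", idx))
    return(list(kind = "component", index = idx))
  }
  if (identical(scope, "combined")) return(list(kind = "combined"))
  if (grepl("^component:[0-9]+$", scope)) {
    idx <- as.integer(sub("^component:", "", scope))
    if (idx < 1L || idx > L) stop(sprintf("invalid component index %d", idx))
    return(list(kind = "component", index = idx))
  }
  stop(sprintf("unknown scope '%s'; use 'combined' or 'component:<index>'",
               scope))
}

#' Mixture CDF of the thermal constant
#'
#' \eqn{F(x) = \sum_l w_l F_W(x; \kappa_l, \lambda_l)}.
#'
#' @param x quantile(s) in degree-days.
#' @param model a \code{\link{weibull_mixture}}.
#' @return Probability vector.
#' @export
mixture_cdf <- function(x, model) {
  .assert_mixture(model)
  cc <- model$components
  vapply(x, function(xx)
    sum(cc$weight * stats::pweibull(xx, cc$shape, cc$scale)), numeric(1L))
}

#' Mixture quantile of the thermal constant
#'
#' Inverts the mixture CDF by bisection on \code{[0, 10 * max(scale)]} to
#' 1e-9 relative tolerance; the CDF is strictly increasing so the bracket is
#' guaranteed.
#'
#' @param p probability in (0, 1).
#' @param model a \code{\link{weibull_mixture}}.
#' @return Quantile in degree-days.
#' @export
mixture_quantile <- function(p, model) {
  .assert_mixture(model)
  if (any(p <= 0 | p >= 1)) stop("p must lie in (0, 1)")
  hi <- 10 * max(model$components$scale)
  vapply(p, function(pp)
    stats::uniroot(function(x) mixture_cdf(x, model) - pp, c(0, hi),
                   tol = 1e-9 * hi)$root, numeric(1L))
}

#' Interval estimate of the thermal constant
#'
#' Central (equal-tailed) interval capturing a stated fraction of realizations
#' of K: \code{[Q((1-level)/2), Q((1+level)/2)]} with Q the quantile function
#' of the selected component's Weibull distribution, or of the full mixture CDF
#' inverted numerically for the combined scope. Endpoints are returned at full
#' precision; round only for presentation.
#'
#' @param model a \code{\link{weibull_mixture}}.
#' @param level coverage level in (0, 1), default 0.95.
#' @param scope \code{"combined"} (default), \code{"component:<i>"}, or an
#'   integer component index.
#' @return A \code{\link{thermal_interval}}.
#' @examples
#' m <- weibull_mixture(weight = c(0.41, 0.59), shape = c(14.57, 13.67),
#'                      scale = c(394.44, 423.95), t0 = c(9.52, 10.21))
#' k_interval(m, 0.95)  # approximately [315, 461] degree-days
#' @export
k_interval <- function(model, level = 0.95, scope = "combined") {
  .assert_mixture(model)
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
  sc <- .parse_scope(scope, model)
  p <- c((1 - level) / 2, (1 + level) / 2)
  if (sc$kind == "combined") {
    q <- mixture_quantile(p, model)
    scope_lab <- "combined"
  } else {
    cc <- model$components[sc$index, ]
    q <- weibull_quantile(p, cc$shape, cc$scale)
    scope_lab <- paste0("component:", sc$index)
  }
  thermal_interval(q[1L], q[2L], level, scope_lab)
}

#' Development-time (age) interval at a temperature
#'
#' Converts k-quantiles to days at a given rearing temperature. For a single
#' component the k-interval endpoints are divided by \eqn{(T - t_0^{(l)})}.
#' For the combined scope the components carry different thresholds, so the
#' development-time mixture CDF \eqn{F_D(d | T) = \sum_l w_l F_W(d (T -
#' t_0^{(l)}); \kappa_l, \lambda_l)} is inverted numerically; dividing combined
#' k-quantiles by a single temperature excess would not be equivalent.
#'
#' @param model a \code{\link{weibull_mixture}}.
#' @param temp temperature in degrees Celsius; must exceed every relevant
#'   threshold.
#' @param level coverage level in (0, 1).
#' @param scope \code{"combined"}, \code{"component:<i>"} or integer index.
#' @return A list of class \code{"age_interval"} with \code{lower},
#'   \code{upper} (days), \code{temp}, \code{level}, \code{scope}.
#' @export
age_interval <- function(model, temp, level = 0.95, scope = "combined") {
  .assert_mixture(model)
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
  sc <- .parse_scope(scope, model)
  cc <- model$components
  p <- c((1 - level) / 2, (1 + level) / 2)
  if (sc$kind == "component") {
    t0 <- cc$t0[sc$index]
    if (temp <= t0)
      stop(sprintf(
        "below developmental threshold: temp %.3f <= t0 %.3f of component %d",
        temp, t0, sc$index))
    q <- weibull_quantile(p, cc$shape[sc$index], cc$scale[sc$index])
    d <- q / (temp - t0)
    scope_lab <- paste0("component:", sc$index)
  } else {
    if (any(temp <= cc$t0))
      stop(sprintf("below developmental threshold: temp %.3f <= max t0 %.3f",
                   temp, max(cc$t0)))
    cdf_d <- function(d)
      sum(cc$weight * stats::pweibull(d * (temp - cc$t0), cc$shape, cc$scale))
    hi <- 10 * max(cc$scale) / min(temp - cc$t0)
    d <- vapply(p, function(pp)
      stats::uniroot(function(x) cdf_d(x) - pp, c(0, hi),
                     tol = 1e-6)$root, numeric(1L))
    scope_lab <- "combined"
  }
  structure(list(lower = d[1L], upper = d[2L], temp = temp, level = level,
                 scope = scope_lab),
            class = "age_interval")
}

#' @export
print.age_interval <- function(x, ...) {
  cat(sprintf("%.0f%% development-time interval at %.2f C (%s): [%.3f, %.3f] days\n",
              100 * x$level, x$temp, x$scope, x$lower, x$upper))
  invisible(x)
}

#' Interval table across coverage levels and scopes
#'
#' One row per (level, scope) pair for the combined mixture and each
#' component, in the style of interval-estimation reference tables at
#' different expected coverage probabilities. Component rows carry that
#' component's threshold; combined rows list all thresholds in the
#' \code{t0_annotation} column since the combined population has no single
#' threshold.
#'
#' @param model a \code{\link{weibull_mixture}}.
#' @param levels numeric vector of coverage levels in (0, 1).
#' @return A data frame with columns \code{level}, \code{scope}, \code{lower},
#'   \code{upper}, \code{t0}, \code{t0_annotation}.
#' @export
interval_table <- function(model, levels = c(0.5, 0.8, 0.9, 0.95, 0.99)) {
  .assert_mixture(model)
  if (base::length(levels) == 0L) stop("levels must be non-empty")
  if (any(levels <= 0 | levels >= 1)) stop("levels must lie in (0, 1)")
  cc <- model$components
  all_t0 <- paste(format(cc$t0, digits = 6L, trim = TRUE), collapse = ";")
  scopes <- c("combined", paste0("component:", seq_len(nrow(cc))))
  rows <- list()
  for (lev in levels) {
    for (s in scopes) {
      iv <- k_interval(model, lev, s)
      comp <- if (s == "combined") NA_real_ else
        cc$t0[as.integer(sub("^component:", "", s))]
      rows[[base::length(rows) + 1L]] <-
        data.frame(level = lev, scope = s, lower = iv$lower, upper = iv$upper,
                   t0 = comp, t0_annotation = all_t0,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Bootstrap confidence interval for the expected thermal constant
#'
#' Parametric bootstrap for the estimator of E[K], the mixture mean
#' \eqn{\sum_l w_l \lambda_l \Gamma(1 + 1/\kappa_l)}: the model is fitted to
#' the data, \code{n_boot} replicate datasets of the same size and temperature
#' design are sampled from the fit, the model is refitted to each (warm-started
#' at the point fit, single restart) and the percentile interval of the
#' replicate mixture means is returned. This is a confidence interval for a
#' parameter estimator — it shrinks with n — as opposed to the interval
#' estimate of realizations produced by \code{\link{k_interval}}.
#'
#' @param data a \code{\link{development_data}}.
#' @param config a \code{\link{fit_config}} used for the point fit.
#' @param level confidence level in (0, 1).
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed integer seed for replicate sampling.
#' @return A \code{\link{thermal_interval}} (scope \code{"combined"}) with the
#'   point estimate attached as \code{attr(x, "mean_k_hat")}.
#' @export
mean_k_ci <- function(data, config = fit_config(), level = 0.95,
                      n_boot = 1000L, seed = 1L) {
  .assert_dataset(data, min_temps = 2L)
  if (n_boot < 2L) stop("n_boot must be at least 2")
  fit <- em_fit(data, config)
  n <- nrow(data)
  temps <- data$temp
  warm_cfg <- config
  warm_cfg$n_restarts <- 1L
  means <- rep(NA_real_, n_boot)
  failures <- 0L
  t0_bounds <- c(min(temps) - 30, min(temps) - config$t0_margin)
  for (b in seq_len(n_boot)) {
    set.seed((seed + b) %% .Machine$integer.max)
    sim <- .sample_from_model(fit, n, temps)
    refit <- tryCatch(
      .em_one_restart(sim, fit$components, warm_cfg, t0_bounds),
      error = function(e) NULL)
    if (is.null(refit)) {
      failures <- failures + 1L
      next
    }
    cc <- refit$comps
    means[b] <- sum(cc$weight * cc$scale * gamma(1 + 1 / cc$shape))
  }
  if (failures > 0.2 * n_boot)
    stop(sprintf("bootstrap failed: %.0f%% of replicate fits degenerated",
                 100 * failures / n_boot))
  q <- stats::quantile(means, c((1 - level) / 2, (1 + level) / 2),
                       na.rm = TRUE, names = FALSE)
  out <- thermal_interval(q[1L], q[2L], level, "combined")
  attr(out, "mean_k_hat") <- mixture_mean_k(fit)
  attr(out, "n_failures") <- failures
  out
}

# sample a dataset of size n from a fitted model, re-using the observed
# temperature values (fixed design)
.sample_from_model <- function(model, n, temps) {
  cc <- model$components
  comp <- sample.int(nrow(cc), n, replace = TRUE, prob = cc$weight)
  k <- stats::rweibull(n, cc$shape[comp], cc$scale[comp])
  tt <- sample(temps, n, replace = TRUE)
  development_data(dev_time = k / (tt - cc$t0[comp]), temp = tt)
}
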