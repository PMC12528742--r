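#' Construct a Weibull mixture model of the thermal constant
#'
#' The model states that the thermal constant \eqn{K = D(T - t_0)} (accumulated
#' degree-days to complete development) is a random variable following a finite
#' mixture of Weibull distributions, each component \eqn{l} with weight
#' \eqn{w_l}, shape \eqn{\kappa_l}, scale \eqn{\lambda_l} (degree-days) and its
#' own lower developmental threshold \eqn{t_0^{(l)}} (degrees Celsius), treated
#' as a parameter of the distribution. Components are stored sorted by expected
#' K, \eqn{\lambda_l \Gamma(1 + 1/\kappa_l)}, ascending.
#'
#' @param weight component weights; must sum to 1 (tolerance 1e-9).
#' @param shape component Weibull shapes, each in [0.5, 200].
#' @param scale component Weibull scales in degree-days, > 0.
#' @param t0 component developmental thresholds in degrees Celsius.
#' @param loglik,n_obs,n_iter,converged,seed fit metadata; defaults are
#'   placeholders for hand-built models.
#' @param sort_components sort components by expected K (default TRUE).
#' @return An object of class \code{"weibull_mixture"}.
#' @examples
#' # two-component model for Necrodes littoralis
#' m <- weibull_mixture(weight = c(0.41, 0.59), shape = c(14.57, 13.67),
#'                      scale = c(394.44, 423.95), t0 = c(9.52, 10.21))
#' mixture_mean_k(m)
#' @export
weibull_mixture <- function(weight, shape, scale, t0,
                            loglik = NA_real_, n_obs = 0L, n_iter = 0L,
                            converged = FALSE, seed = NA_integer_,
                            sort_components = TRUE) {
  L <- base::length(weight)
  if (L == 0L) stop("at least one component is required")
  if (base::length(shape) != L || base::length(scale) != L ||
      base::length(t0) != L)
    stop("weight, shape, scale and t0 must have equal length")
  weight <- as.numeric(weight); shape <- as.numeric(shape)
  scale <- as.numeric(scale); t0 <- as.numeric(t0)
  if (abs(sum(weight) - 1) > 1e-9)
    stop(sprintf("component weights must sum to 1 (got %.12g)", sum(weight)))
  if (any(weight <= 0)) stop("component weights must be in (0, 1]")
  if (any(shape < 0.5 | shape > 200))
    stop("component shapes must lie in [0.5, 200]")
  if (any(scale <= 0)) stop("component scales must be > 0")
  if (any(!is.finite(t0))) stop("component thresholds must be finite")
  comps <- data.frame(weight = weight, shape = shape, scale = scale, t0 = t0,
                      em_label = seq_len(L))
  if (sort_components) {
    ek <- scale * gamma(1 + 1 / shape)
    comps <- comps[order(ek), , drop = FALSE]
    rownames(comps) <- NULL
  }
  structure(list(components = comps, loglik = loglik,
                 n_obs = as.integer(n_obs), n_iter = as.integer(n_iter),
                 converged = isTRUE(converged), seed = seed),
            class = "weibull_mixture")
}

.assert_mixture <- function(model) {
  if (!inherits(model, "weibull_mixture"))
    stop("expected a weibull_mixture object; see weibull_mixture()")
  if (abs(sum(model$components$weight) - 1) > 1e-9)
    stop("invalid model: component weights do not sum to 1")
  invisible(model)
}

#' @export
print.weibull_mixture <- function(x, ...) {
  cat(sprintf(
    "Weibull mixture for the thermal constant K (%d component%s)\n",
    nrow(x$components), if (nrow(x$components) > 1L) "s" else ""))
  tab <- x$components
  tab$mean_K <- tab$scale * gamma(1 + 1 / tab$shape)
  print(format(tab, digits = 5L), row.names = TRUE)
  if (is.finite(x$loglik))
    cat(sprintf("loglik %.4f on %d obs, %d EM iterations, converged: %s\n",
                x$loglik, x$n_obs, x$n_iter, x$converged))
  invisible(x)
}

#' Expected thermal constant of a mixture
#'
#' Returns the mixture mean \eqn{\sum_l w_l \lambda_l \Gamma(1 + 1/\kappa_l)}
#' in accumulated degree-days.
#'
#' @param model a \code{\link{weibull_mixture}}.
#' @return Numeric scalar, degree-days.
#' @export
mixture_mean_k <- function(model) {
  .assert_mixture(model)
  with(model$components, sum(weight * scale * gamma(1 + 1 / shape)))
}

#' EM fitting configuration
#'
#' @param n_components number of mixture components (default 2, the typical
#'   finding for carrion beetle rearing data).
#' @param n_restarts number of EM restarts with jittered initializations.
#' @param tol absolute log-likelihood change declaring convergence.
#' @param max_iter maximum EM iterations per restart.
#' @param t0_margin minimum gap (degrees C) between any threshold and the
#'   lowest rearing temperature; the likelihood requires T > t0 everywhere.
#' @param seed integer seed controlling restart jitter.
#' @return A list of class \code{"fit_config"}.
#' @export
fit_config <- function(n_components = 2L, n_restarts = 10L, tol = 1e-8,
                       max_iter = 500L, t0_margin = 0.5, seed = 1L) {
  stopifnot(n_components >= 1L, n_restarts >= 1L, tol > 0, max_iter >= 1L,
            t0_margin > 0)
  structure(list(n_components = as.integer(n_components),
                 n_restarts = as.integer(n_restarts), tol = tol,
                 max_iter = as.integer(max_iter), t0_margin = t0_margin,
                 seed = as.integer(seed)),
            class = "fit_config")
}

#' Weibull quantile function
#'
#' Closed-form quantile \eqn{\lambda(-\ln(1-p))^{1/\kappa}} of the
#' two-parameter Weibull distribution, used to read off interval endpoints for
#' the thermal constant at any coverage level.
#'
#' @param p probability in [0, 1).
#' @param shape Weibull shape (> 0).
#' @param scale Weibull scale in degree-days (> 0).
#' @return Quantile in degree-days.
#' @examples
#' weibull_quantile(0.025, shape = 14.03, scale = 442.74)  # ~341 degree-days
#' @export
weibull_quantile <- function(p, shape, scale) {
  if (any(p < 0 | p >= 1)) stop("p must lie in [0, 1)")
  if (any(shape <= 0) || any(scale <= 0)) stop("shape and scale must be > 0")
  scale * (-log1p(-p))^(1 / shape)
}

# log-density of k_i = D_i (T_i - t0_l) per record x component, including the
# Jacobian (T - t0_l) of the change of variables k -> D; n x L matrix
.log_dens_matrix <- function(data, comps) {
  n <- nrow(data)
  L <- nrow(comps)
  out <- matrix(NA_real_, n, L)
  for (l in seq_len(L)) {
    dt <- data$temp - comps$t0[l]
    if (any(dt <= 0)) {
      bad <- which(dt <= 0)[1L]
      stop(sprintf(
        "record %d: temperature %.3f is below developmental threshold %.3f of component %d",
        bad, data$temp[bad], comps$t0[l], l))
    }
    k <- data$dev_time * dt
    out[, l] <- stats::dweibull(k, comps$shape[l], comps$scale[l],
                                log = TRUE) + log(dt)
  }
  # floor at log(1e-300): keeps far-tail records from zeroing a whole row
  pmax(out, log(1e-300))
}

.logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Mixture log-likelihood
#'
#' Log-likelihood of a dataset under the mixture model, i.e.
#' \eqn{\sum_i \log \sum_l w_l f_W(D_i(T_i - t_0^{(l)}); \kappa_l, \lambda_l)
#' (T_i - t_0^{(l)})}. The \eqn{(T - t_0)} factor is the Jacobian of the change
#' of variables from K to D and is always included.
#'
#' @param data a \code{\link{development_data}} object.
#' @param model a \code{\link{weibull_mixture}}.
#' @return Numeric scalar.
#' @export
mixture_loglik <- function(data, model) {
  .assert_dataset(data)
  .assert_mixture(model)
  ld <- .log_dens_matrix(data, model$components)
  sum(.logsumexp_rows(sweep(ld, 2L, log(model$components$weight), `+`)))
}

#' E-step responsibilities
#'
#' Posterior probabilities that each record belongs to each component, computed
#' in log space with the Jacobian-corrected densities. Rows sum to 1.
#'
#' @inheritParams mixture_loglik
#' @return An \code{n_obs x n_components} matrix of responsibilities.
#' @export
e_step <- function(data, model) {
  .assert_dataset(data)
  .assert_mixture(model)
  lw <- sweep(.log_dens_matrix(data, model$components), 2L,
              log(model$components$weight), `+`)
  r <- exp(lw - .logsumexp_rows(lw))
  r / rowSums(r)
}

# weighted Weibull MLE for k-values: shape solves the standard score equation
# 1/kappa + m1 - S(kappa) = 0 with m1 = weighted mean log k and
# S(kappa) = sum(r k^kappa log k) / sum(r k^kappa); scale follows in closed
# form. Solved by uniroot with bracket expansion inside [0.5, 200].
.weighted_weibull_mle <- function(k, r) {
  lk <- log(k)
  m1 <- sum(r * lk) / sum(r)
  mx <- max(lk)
  score <- function(kap) {
    # k^kap overflows for large shapes; factor out the max in log space
    w <- r * exp(kap * (lk - mx))
    1 / kap + m1 - sum(w * lk) / sum(w)
  }
  lo <- 0.5
  hi <- 200
  s_lo <- score(lo)
  s_hi <- score(hi)
  if (s_lo <= 0) {
    kap <- lo
    bounded <- TRUE
  } else if (s_hi >= 0) {
    kap <- hi
    bounded <- TRUE
  } else {
    kap <- stats::uniroot(score, c(lo, hi), tol = 1e-10)$root
    bounded <- FALSE
  }
  lam <- exp(mx + log(sum(r * exp(kap * (lk - mx))) / sum(r)) / kap)
  list(shape = kap, scale = lam, shape_at_bound = bounded)
}

# weighted objective of one component at (shape, scale, t0)
.component_objective <- function(data, r, shape, scale, t0) {
  dt <- data$temp - t0
  k <- data$dev_time * dt
  sum(r * (stats::dweibull(k, shape, scale, log = TRUE) + log(dt)))
}

#' M-step for one component
#'
#' Maximizes the responsibility-weighted log-likelihood of a single Weibull
#' component over (shape, scale, t0) by profiling: for fixed t0 the weighted
#' Weibull MLE is solved in closed form up to a one-dimensional root for the
#' shape, and the profile is then maximized over t0 by bounded 1-D search.
#'
#' @param data a \code{\link{development_data}} object.
#' @param responsibilities nonnegative weights per record, summing > 0.
#' @param t0_bounds length-2 numeric: search interval for t0; the upper end
#'   must stay below the lowest rearing temperature.
#' @return A list with \code{shape}, \code{scale}, \code{t0}, the achieved
#'   weighted objective \code{objective}, and a \code{warnings} character
#'   vector (boundary t0, shape at its bound).
#' @export
m_step_component <- function(data, responsibilities, t0_bounds) {
  .assert_dataset(data)
  r <- as.numeric(responsibilities)
  if (base::length(r) != nrow(data))
    stop("responsibilities must have one entry per record")
  if (any(r < 0) || sum(r) <= 0)
    stop("responsibilities must be nonnegative with positive sum")
  if (base::length(t0_bounds) != 2L || t0_bounds[1L] >= t0_bounds[2L])
    stop("t0_bounds must be an increasing length-2 interval")
  if (t0_bounds[2L] >= min(data$temp))
    stop("t0 upper bound must lie below the minimum rearing temperature")
  profile <- function(t0) {
    k <- data$dev_time * (data$temp - t0)
    mle <- .weighted_weibull_mle(k, r)
    .component_objective(data, r, mle$shape, mle$scale, t0)
  }
  opt <- stats::optimize(profile, t0_bounds, maximum = TRUE,
                         tol = .Machine$double.eps^0.4)
  t0 <- opt$maximum
  warnings <- character(0)
  # monotone profiles push the optimum to an endpoint; report the better one
  for (b in t0_bounds) {
    if (profile(b) > opt$objective) {
      t0 <- b
      warnings <- c(warnings, "t0 profile optimum at search boundary")
    }
  }
  span <- diff(t0_bounds)
  if (min(abs(t0 - t0_bounds)) < 1e-6 * span &&
      !base::length(warnings))
    warnings <- c(warnings, "t0 profile optimum at search boundary")
  k <- data$dev_time * (data$temp - t0)
  mle <- .weighted_weibull_mle(k, r)
  if (mle$shape_at_bound)
    warnings <- c(warnings, "shape estimate at its [0.5, 200] bound")
  list(shape = mle$shape, scale = mle$scale, t0 = t0,
       objective = .component_objective(data, r, mle$shape, mle$scale, t0),
       warnings = warnings)
}

# method-of-moments Weibull init: shape from the coefficient of variation,
# scale from the mean
.mom_weibull <- function(k) {
  cv <- stats::sd(k) / mean(k)
  if (!is.finite(cv) || cv <= 0) cv <- 0.1
  f <- function(kap) sqrt(gamma(1 + 2 / kap) / gamma(1 + 1 / kap)^2 - 1) - cv
  kap <- tryCatch(stats::uniroot(f, c(0.5, 200), tol = 1e-8)$root,
                  error = function(e) max(0.5, min(200, 1 / cv)))
  list(shape = kap, scale = mean(k) / gamma(1 + 1 / kap))
}

.init_components <- function(data, L, t0_init, t0_bounds, shuffle = FALSE) {
  t0_init <- min(max(t0_init, t0_bounds[1L]), t0_bounds[2L])
  k <- data$dev_time * (data$temp - t0_init)
  grp <- if (L == 1L) rep(1L, nrow(data))
  else if (shuffle) sample.int(L, nrow(data), replace = TRUE)
  else cut(rank(k, ties.method = "first"), breaks = L, labels = FALSE)
  comps <- data.frame(weight = numeric(L), shape = numeric(L),
                      scale = numeric(L), t0 = rep(t0_init, L))
  for (l in seq_len(L)) {
    kl <- k[grp == l]
    if (base::length(kl) < 2L) kl <- k
    mm <- .mom_weibull(kl)
    comps$shape[l] <- mm$shape
    comps$scale[l] <- mm$scale
    comps$weight[l] <- max(base::length(kl), 1L)
  }
  comps$weight <- comps$weight / sum(comps$weight)
  comps
}

#' Fit a Weibull mixture by EM
#'
#' Fits the mixture of Weibull distributions for the thermal constant, with
#' component-specific developmental thresholds, by the EM algorithm with
#' multiple restarts. Initialization takes a provisional threshold from the
#' linear degree-day fit, slices the provisional k-values into quantile groups,
#' and seeds each component by the method of moments; later restarts jitter the
#' initial threshold within plus or minus 2 degrees C and reshuffle group
#' assignment. The restart achieving the highest log-likelihood is returned,
#' components sorted by expected K.
#'
#' @param data a \code{\link{development_data}} with at least 2 distinct
#'   temperatures and at least \code{10 * n_components} records.
#' @param config a \code{\link{fit_config}}.
#' @return A \code{\link{weibull_mixture}} with fit metadata; the per-restart
#'   log-likelihood trajectories are attached as
#'   \code{attr(model, "trajectories")}.
#' @examples
#' set.seed(1)
#' d <- sample_dataset(species_preset("necrodes_littoralis", n = 300, seed = 7))
#' fit <- em_fit(d, fit_config(n_components = 2, n_restarts = 2, seed = 7))
#' fit
#' @export
em_fit <- function(data, config = fit_config()) {
  .assert_dataset(data, min_temps = 2L)
  L <- config$n_components
  n <- nrow(data)
  if (n < 10L * L)
    stop(sprintf("need at least %d records to fit %d components", 10L * L, L))
  t0_hi <- min(data$temp) - config$t0_margin
  t0_lo <- min(data$temp) - 30
  t0_bounds <- c(t0_lo, t0_hi)
  t0_prov <- tryCatch(degree_day_fit(data)$t0_hat,
                      error = function(e) min(data$temp) - 5)
  best <- NULL
  trajectories <- vector("list", config$n_restarts)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)
  for (restart in seq_len(config$n_restarts)) {
    jitter <- if (restart == 1L) 0 else stats::runif(1L, -2, 2)
    comps <- .init_components(data, L, t0_prov + jitter, t0_bounds,
                              shuffle = restart > 1L && restart %% 2L == 0L)
    fit <- tryCatch(
      .em_one_restart(data, comps, config, t0_bounds),
      error = function(e) NULL)
    if (is.null(fit)) next
    trajectories[[restart]] <- fit$trajectory
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best))
    stop(paste("all EM restarts degenerated (a component weight fell below",
               "1/n_obs); try fewer components"))
  model <- weibull_mixture(best$comps$weight, best$comps$shape,
                           best$comps$scale, best$comps$t0,
                           loglik = best$loglik, n_obs = n,
                           n_iter = best$n_iter, converged = best$converged,
                           seed = config$seed)
  attr(model, "trajectories") <- trajectories
  model
}

.em_one_restart <- function(data, comps, config, t0_bounds) {
  n <- nrow(data)
  model <- weibull_mixture(comps$weight, comps$shape, comps$scale, comps$t0,
                           sort_components = FALSE)
  ll_old <- mixture_loglik(data, model)
  trajectory <- ll_old
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(config$max_iter)) {
    r <- e_step(data, model)
    w <- colMeans(r)
    if (any(w < 1 / n)) stop("degenerate component")
    comps <- model$components
    for (l in seq_len(nrow(comps))) {
      upd <- m_step_component(data, r[, l], t0_bounds)
      # keep the incoming parameters if the numeric search failed to improve
      if (upd$objective >= .component_objective(data, r[, l], comps$shape[l],
                                                comps$scale[l], comps$t0[l])) {
        comps$shape[l] <- upd$shape
        comps$scale[l] <- upd$scale
        comps$t0[l] <- upd$t0
      }
    }
    comps$weight <- w
    model <- weibull_mixture(comps$weight, comps$shape, comps$scale, comps$t0,
                             sort_components = FALSE)
    ll_new <- mixture_loglik(data, model)
    trajectory <- c(trajectory, ll_new)
    if (abs(ll_new - ll_old) < config$tol) {
      converged <- TRUE
      ll_old <- ll_new
      break
    }
    ll_old <- ll_new
  }
  list(comps = model$components, loglik = ll_old, n_iter = iter,
       converged = converged, trajectory = trajectory)
}

#' Select the number of mixture components by BIC
#'
#' Fits mixtures with 1 to \code{max_components} components and returns the fit
#' minimizing \eqn{BIC = -2 \log L + p \ln n} with \eqn{p = 4L - 1} free
#' parameters (per component: weight, shape, scale, threshold; weights lose one
#' degree of freedom). Ties break toward fewer components.
#'
#' @param data a \code{\link{development_data}}.
#' @param config a \code{\link{fit_config}}; its \code{n_components} is
#'   overridden by the candidate counts.
#' @param max_components largest component count to try.
#' @return The BIC-minimizing \code{\link{weibull_mixture}}, with the BIC table
#'   attached as \code{attr(model, "bic_table")}.
#' @export
select_n_components <- function(data, config = fit_config(),
                                max_components = 3L) {
  stopifnot(max_components >= 1L)
  fits <- list()
  bics <- rep(NA_real_, max_components)
  for (L in seq_len(max_components)) {
    cfg <- config
    cfg$n_components <- as.integer(L)
    fit <- tryCatch(em_fit(data, cfg), error = function(e) {
      warning(sprintf("fit with %d component(s) failed: %s", L,
                      conditionMessage(e)))
      NULL
    })
    if (is.null(fit)) next
    fits[[L]] <- fit
    bics[L] <- bic_mixture(fit$loglik, L, fit$n_obs)
  }
  if (all(is.na(bics))) stop("no component count could be fitted")
  best_L <- which(bics == min(bics, na.rm = TRUE))[1L]
  model <- fits[[best_L]]
  attr(model, "bic_table") <- data.frame(n_components = seq_len(max_components),
                                         bic = bics)
  model
}

#' BIC of a Weibull mixture fit
#'
#' @param loglik log-likelihood at the optimum.
#' @param n_components number of components L; the free parameter count is
#'   \code{4 * L - 1}.
#' @param n_obs number of observations.
#' @return Numeric BIC value.
#' @export
bic_mixture <- function(loglik, n_components, n_obs) {
  -2 * loglik + (4 * n_components - 1) * log(n_obs)
}
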