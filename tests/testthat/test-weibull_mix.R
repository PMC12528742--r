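test_that("Weibull quantile matches its closed form and inverts the CDF", {
  expect_equal(weibull_quantile(0, 14, 400), 0)
  # p = 1 - exp(-1) forces the quantile to equal the scale
  expect_equal(weibull_quantile(1 - exp(-1), 3.7, 512.3), 512.3,
               tolerance = 1e-12)
  expect_error(weibull_quantile(1, 14, 400), "p must")
  expect_error(weibull_quantile(-0.1, 14, 400), "p must")
  # round-trip against the forward CDF across shapes and positions
  for (shape in c(0.7, 1, 5, 14)) {
    for (x in c(0.5, 1, 1.5) * 400) {
      p <- pweibull(x, shape, 400)
      # deep in the upper tail the CDF rounds to 1 in doubles (e.g. shape 14
      # at 1.5 * scale); the inverse is undefined there
      if (p < 1)
        expect_equal(weibull_quantile(p, shape, 400), x, tolerance = 1e-9)
    }
  }
  # strictly increasing in p
  q <- weibull_quantile(seq(0.05, 0.95, by = 0.05), 14, 400)
  expect_true(all(diff(q) > 0))
})

test_that("mixture log-likelihood matches the closed form with its Jacobian", {
  # one record, one component with shape 1: k = lambda gives density
  # (1/lambda) exp(-1), times the Jacobian (T - t0)
  lambda <- 350; t0 <- 10; Temp <- 20
  d <- development_data(dev_time = lambda / (Temp - t0), temp = Temp)
  m <- weibull_mixture(1, shape = 1, scale = lambda, t0 = t0)
  expect_equal(mixture_loglik(d, m),
               log((1 / lambda) * exp(-1) * (Temp - t0)),
               tolerance = 1e-12)
})

test_that("log-likelihood is additive over records and order-invariant", {
  d <- sample_dataset(random_design(1, n = 40))
  m <- necrodes_model()
  ll <- mixture_loglik(d, m)
  doubled <- development_data(rep(d$dev_time, 2), rep(d$temp, 2))
  expect_equal(mixture_loglik(doubled, m), 2 * ll, tolerance = 1e-9)
  perm <- sample(nrow(d))
  shuffled <- development_data(d$dev_time[perm], d$temp[perm])
  expect_equal(mixture_loglik(shuffled, m), ll, tolerance = 1e-10)
})

test_that("log-likelihood rejects temperatures at or below a threshold", {
  d <- development_data(dev_time = c(30, 40), temp = c(9.6, 20))
  expect_error(mixture_loglik(d, necrodes_model()),
               "below developmental threshold")
})

test_that("E-step responsibilities follow Bayes' rule", {
  m <- weibull_mixture(c(0.3, 0.7), c(14, 8), c(400, 500), c(10, 9),
                       sort_components = FALSE)
  d <- development_data(dev_time = c(30, 45), temp = c(22, 20))
  r <- e_step(d, m)
  # brute-force oracle: direct density evaluation per record and component
  oracle <- matrix(NA_real_, 2, 2)
  cc <- m$components
  for (i in 1:2) {
    f <- numeric(2)
    for (l in 1:2) {
      dt <- d$temp[i] - cc$t0[l]
      f[l] <- cc$weight[l] * dweibull(d$dev_time[i] * dt, cc$shape[l],
                                      cc$scale[l]) * dt
    }
    oracle[i, ] <- f / sum(f)
  }
  expect_equal(r, oracle, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(rowSums(r), c(1, 1), tolerance = 1e-12)
})

test_that("E-step handles degenerate mixtures as expected", {
  d <- sample_dataset(random_design(2, n = 25))
  single <- weibull_mixture(1, 14, 400, 9)
  expect_equal(unname(e_step(d, single)[, 1]), rep(1, 25))
  twin <- weibull_mixture(c(0.3, 0.7), c(14, 14), c(400, 400), c(9, 9),
                          sort_components = FALSE)
  r <- e_step(d, twin)
  expect_equal(unname(r[, 1]), rep(0.3, 25), tolerance = 1e-12)
  # rows sum to one across random models too
  r2 <- e_step(d, necrodes_model())
  expect_equal(unname(rowSums(r2)), rep(1, 25), tolerance = 1e-12)
})

test_that("M-step recovers single-component truth from unit weights", {
  d <- sample_dataset(simulation_design(
    components = data.frame(weight = 1, shape = 14, scale = 400, t0 = 10,
                            mean_length = 18, sd_length = 0.8),
    temperatures = c(15, 20, 25), n = 1000, seed = 99))
  est <- m_step_component(d, rep(1, 1000), t0_bounds = c(-15, 14.5))
  expect_lt(abs(est$shape - 14) / 14, 0.15)
  expect_lt(abs(est$scale - 400) / 400, 0.03)
  expect_lt(abs(est$t0 - 10), 0.5)
  # achieved objective dominates the truth's objective (argmax definition)
  truth_obj <- thermomix:::.component_objective(d, rep(1, 1000), 14, 400, 10)
  expect_gte(est$objective, truth_obj - 1e-6)
})

test_that("M-step weighted MLE dominates a dense grid search", {
  d <- development_data(dev_time = c(38, 42, 35, 47, 40),
                        temp = c(18, 20, 22, 16, 19))
  r <- c(1, 0.8, 1, 0.6, 0.9)
  est <- m_step_component(d, r, t0_bounds = c(-14, 15.5))
  grid_best <- -Inf
  for (kap in seq(1, 40, by = 0.5)) {
    for (lam in seq(250, 600, by = 5)) {
      for (t0 in seq(-14, 15.5, by = 0.25)) {
        obj <- thermomix:::.component_objective(d, r, kap, lam, t0)
        if (obj > grid_best) grid_best <- obj
      }
    }
  }
  expect_gte(est$objective, grid_best)
})

test_that("M-step validates responsibilities and bounds", {
  d <- exact_law_data()
  expect_error(m_step_component(d, rep(0, nrow(d)), c(-10, 14)),
               "positive sum")
  expect_error(m_step_component(d, rep(1, nrow(d)), c(-10, 20)),
               "below the minimum rearing temperature")
  expect_error(m_step_component(d, rep(1, 2), c(-10, 14)),
               "one entry per record")
})

test_that("EM recovers the two-component generating parameters", {
  design <- species_preset("necrodes_littoralis", n = 2000, seed = 11)
  d <- sample_dataset(design)
  fit <- em_fit(d, fit_config(n_components = 2, n_restarts = 3, seed = 11))
  truth <- design_mixture(design)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$components$weight - truth$components$weight)), 0.05)
  for (l in 1:2) {
    expect_lt(abs(fit$components$shape[l] - truth$components$shape[l]) /
                truth$components$shape[l], 0.20)
    expect_lt(abs(fit$components$scale[l] - truth$components$scale[l]) /
                truth$components$scale[l], 0.03)
    expect_lt(abs(fit$components$t0[l] - truth$components$t0[l]), 0.7)
  }
})

test_that("single-component EM equals the direct weighted MLE", {
  d <- sample_dataset(random_design(5, n = 300))
  fit <- em_fit(d, fit_config(n_components = 1, n_restarts = 1, seed = 5))
  direct <- m_step_component(d, rep(1, nrow(d)),
                             t0_bounds = c(min(d$temp) - 30,
                                           min(d$temp) - 0.5))
  expect_equal(fit$components$shape, direct$shape, tolerance = 1e-6)
  expect_equal(fit$components$scale, direct$scale, tolerance = 1e-6)
  expect_equal(fit$components$t0, direct$t0, tolerance = 1e-4)
  expect_equal(fit$components$weight, 1)
})

test_that("EM log-likelihood trajectories are non-decreasing", {
  for (seed in 1:5) {
    d <- sample_dataset(random_design(seed, n = 150))
    fit <- em_fit(d, fit_config(n_components = 2, n_restarts = 1,
                                max_iter = 60, tol = 1e-7, seed = seed))
    for (traj in Filter(Negate(is.null), attr(fit, "trajectories")))
      expect_true(all(diff(traj) >= -1e-9))
  }
})

test_that("EM is equivariant to record order", {
  d <- sample_dataset(random_design(8, n = 200))
  cfg <- fit_config(n_components = 2, n_restarts = 1, tol = 1e-7, seed = 8)
  fit1 <- em_fit(d, cfg)
  perm <- sample(nrow(d))
  d2 <- development_data(d$dev_time[perm], d$temp[perm], d$sex[perm],
                         d$length[perm])
  fit2 <- em_fit(d2, cfg)
  expect_equal(fit1$components$shape, fit2$components$shape, tolerance = 1e-4)
  expect_equal(fit1$components$scale, fit2$components$scale, tolerance = 1e-4)
  expect_equal(fit1$loglik, fit2$loglik, tolerance = 1e-6)
})

test_that("components come back sorted by expected K", {
  m <- weibull_mixture(c(0.3, 0.7), c(5, 14), c(600, 400), c(10, 10))
  ek <- m$components$scale * gamma(1 + 1 / m$components$shape)
  expect_true(all(diff(ek) > 0))
  expect_equal(m$components$em_label, c(2L, 1L))
})

test_that("BIC arithmetic and nesting behave as expected", {
  expect_equal(bic_mixture(-1234.5, 2, 954), -2 * -1234.5 + 7 * log(954))
  d <- sample_dataset(simulation_design(
    components = data.frame(weight = 1, shape = 12, scale = 420, t0 = 9,
                            mean_length = 18, sd_length = 0.8),
    temperatures = c(14, 18, 22, 26), n = 600, seed = 31))
  cfg <- fit_config(n_restarts = 2, tol = 1e-7, seed = 31)
  m <- select_n_components(d, cfg, max_components = 2)
  tab <- attr(m, "bic_table")
  # one true population: the 2-component loglik can only be higher (nesting),
  # but BIC must prefer the single component
  expect_equal(nrow(m$components), 1L)
  expect_equal(which.min(tab$bic), 1L)
})

test_that("BIC selects two components on clearly mixed data", {
  d <- sample_dataset(species_preset("necrodes_littoralis", n = 2000,
                                     seed = 3))
  m <- select_n_components(d, fit_config(n_restarts = 2, tol = 1e-7,
                                         seed = 3), max_components = 2)
  expect_equal(nrow(m$components), 2L)
})
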