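test_that("published mixture parameters reproduce the printed k-intervals", {
  # combined-population intervals: mixture CDF inverted at 2.5% / 97.5%
  iv_n <- k_interval(necrodes_model(), 0.95, "combined")
  expect_equal(round(iv_n$lower), 315)
  expect_equal(round(iv_n$upper), 461)
  iv_c <- k_interval(creophilus_model(), 0.95, "combined")
  expect_equal(round(iv_c$lower), 339)
  expect_equal(round(iv_c$upper), 600)
  # regular (dominant) component alone
  m <- creophilus_model()
  reg <- which(m$components$shape == 14.03)
  iv_r <- k_interval(m, 0.95, paste0("component:", reg))
  expect_equal(round(iv_r$lower), 341)
  expect_equal(round(iv_r$upper), 486)
})

test_that("mixture quantile inversion is consistent with the forward CDF", {
  m <- necrodes_model()
  for (p in c(0.01, 0.025, 0.5, 0.975, 0.99)) {
    q <- mixture_quantile(p, m)
    expect_equal(mixture_cdf(q, m), p, tolerance = 1e-6)
  }
  # interval probability mass equals the level
  for (level in c(0.5, 0.9, 0.95)) {
    iv <- k_interval(m, level)
    expect_equal(mixture_cdf(iv$upper, m) - mixture_cdf(iv$lower, m), level,
                 tolerance = 1e-6)
  }
})

test_that("k-interval validates level and scope", {
  m <- necrodes_model()
  expect_error(k_interval(m, 1.2), "level")
  expect_error(k_interval(m, 0.95, "component:9"), "invalid component")
  expect_error(k_interval(m, 0.95, "both"), "unknown scope")
})

test_that("simulated realizations fall in the 95% interval at the nominal rate", {
  m <- necrodes_model()
  iv <- k_interval(m, 0.95)
  set.seed(20260919)
  cc <- m$components
  comp <- sample.int(2, 10000, replace = TRUE, prob = cc$weight)
  k <- rweibull(10000, cc$shape[comp], cc$scale[comp])
  expect_equal(mean(k >= iv$lower & k <= iv$upper), 0.95, tolerance = 0.01)
})

test_that("age intervals divide component k-quantiles by the temperature excess", {
  m <- creophilus_model()
  reg <- which(m$components$shape == 14.03)
  # at 21.25 C the excess over the regular component's 11.25 C threshold is 10
  iv <- age_interval(m, 21.25, 0.95, paste0("component:", reg))
  kq <- weibull_quantile(c(0.025, 0.975), 14.03, 442.74)
  expect_equal(iv$lower, kq[1] / 10, tolerance = 1e-9)
  expect_equal(iv$upper, kq[2] / 10, tolerance = 1e-9)
  expect_equal(round(c(iv$lower, iv$upper), 1), c(34.1, 48.6))
})

test_that("combined and component age intervals agree for one component", {
  m <- weibull_mixture(1, 14, 400, 10)
  a <- age_interval(m, 20, 0.95, "combined")
  b <- age_interval(m, 20, 0.95, "component:1")
  expect_equal(a$lower, b$lower, tolerance = 1e-6)
  expect_equal(a$upper, b$upper, tolerance = 1e-6)
})

test_that("age intervals shrink with temperature and respect thresholds", {
  m <- necrodes_model()
  temps <- c(14, 18, 24, 30)
  ivs <- lapply(temps, function(tt) age_interval(m, tt, 0.95))
  lowers <- vapply(ivs, `[[`, numeric(1), "lower")
  uppers <- vapply(ivs, `[[`, numeric(1), "upper")
  expect_true(all(diff(lowers) < 0))
  expect_true(all(diff(uppers) < 0))
  expect_error(age_interval(m, 10.21, 0.95), "below developmental threshold")
})

test_that("combined age intervals are calibrated in the development-time domain", {
  m <- necrodes_model()
  iv <- age_interval(m, 18, 0.95, "combined")
  cc <- m$components
  cdf_d <- function(d)
    sum(cc$weight * pweibull(d * (18 - cc$t0), cc$shape, cc$scale))
  expect_equal(cdf_d(iv$upper) - cdf_d(iv$lower), 0.95, tolerance = 1e-5)
})

test_that("interval tables enumerate levels and scopes consistently", {
  m <- necrodes_model()
  levels <- c(0.5, 0.8, 0.9, 0.95, 0.99)
  tab <- interval_table(m, levels)
  expect_equal(nrow(tab), 15L)  # 5 levels x (combined + 2 components)
  row95 <- tab[tab$level == 0.95 & tab$scope == "combined", ]
  iv95 <- k_interval(m, 0.95, "combined")
  expect_equal(row95$lower, iv95$lower)
  expect_equal(row95$upper, iv95$upper)
  # widths strictly increase with level within each scope
  for (s in unique(tab$scope)) {
    w <- with(tab[tab$scope == s, ], upper - lower)
    expect_true(all(diff(w[order(levels)]) > 0))
  }
  # combined rows annotate every component threshold
  expect_true(all(grepl(";", tab$t0_annotation)))
  expect_error(interval_table(m, numeric(0)), "non-empty")
})

test_that("bootstrap CI for E[K] contains the plug-in mean and narrows with n", {
  cfg <- fit_config(n_components = 2, n_restarts = 1, tol = 1e-5,
                    max_iter = 100, seed = 17)
  d_small <- sample_dataset(species_preset("necrodes_littoralis", n = 400,
                                           seed = 17))
  ci_small <- mean_k_ci(d_small, cfg, level = 0.95, n_boot = 30, seed = 17)
  expect_gte(attr(ci_small, "mean_k_hat"), ci_small$lower)
  expect_lte(attr(ci_small, "mean_k_hat"), ci_small$upper)
  d_large <- sample_dataset(species_preset("necrodes_littoralis", n = 1600,
                                           seed = 18))
  ci_large <- mean_k_ci(d_large, cfg, level = 0.95, n_boot = 30, seed = 18)
  w_small <- ci_small$upper - ci_small$lower
  w_large <- ci_large$upper - ci_large$lower
  # quadrupling n should roughly halve the width (1/sqrt(n) scaling)
  expect_lt(w_large / w_small, 0.8)
  # degenerate-but-defined smoke contract
  ci2 <- mean_k_ci(d_small, cfg, level = 0.5, n_boot = 2, seed = 19)
  expect_s3_class(ci2, "thermal_interval")
})
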