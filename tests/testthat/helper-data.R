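# shared fixture builders; everything is generated in code

# noise-free data obeying k = D (T - t0) exactly, one or more reps per temp
exact_law_data <- function(k = 400, t0 = 10, temps = c(15, 20, 25), reps = 1L) {
  tt <- rep(temps, each = reps)
  development_data(dev_time = k / (tt - t0), temp = tt)
}

# the six printed example rows from a C. maxillosus rearing experiment
table7_data <- function() {
  development_data(dev_time = c(109.79, 141.13, 66.25, 87.12, 62.08, 70.29),
                   temp = c(15.0, 15.0, 15.0, 17.5, 17.5, 17.5))
}

# published two-component mixture fits used as known models in tests
necrodes_model <- function() {
  weibull_mixture(weight = c(0.41, 0.59), shape = c(14.57, 13.67),
                  scale = c(394.44, 423.95), t0 = c(9.52, 10.21))
}

creophilus_model <- function() {
  weibull_mixture(weight = c(0.87, 0.13), shape = c(14.03, 6.72),
                  scale = c(442.74, 556.66), t0 = c(11.25, 11.15))
}

# random but well-posed two-component design for property-style loops
random_design <- function(seed, n = 120L) {
  set.seed(seed)
  w1 <- stats::runif(1, 0.25, 0.75)
  simulation_design(
    components = data.frame(
      weight = c(w1, 1 - w1),
      shape = stats::runif(2, 4, 20),
      scale = stats::runif(2, 250, 550),
      t0 = stats::runif(2, 7, 11),
      mean_length = c(18, 17), sd_length = 0.8),
    temperatures = c(14, 16, 18, 20, 24, 28),
    n = n, seed = seed)
}
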