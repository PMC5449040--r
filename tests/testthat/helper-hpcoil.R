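# Shared fixtures: everything is generated in code, nothing is stored.

default_grid <- seq(0.1, 200, length.out = 9)

# A random 2- or 3-state ensemble model on bounded parameter ranges.
# p0 = 10 MPa gives the numeric differentiation oracle room for a centred
# step without hitting the p >= 0 boundary.
random_ensemble <- function(n_states = sample(2:3, 1), p0 = 10) {
  states <- lapply(seq_len(n_states), function(k) {
    thermo_state(paste0("s", k),
                 shift = runif(1, 7, 10),
                 G0 = runif(1, -3000, 3000),
                 V0 = runif(1, -80, 80),
                 beta0 = runif(1, -0.5, 0.5))
  })
  ensemble_model(states, p0 = p0)
}

# A gently pressure-sensitive ensemble: parameter bounds chosen so the
# local quadratic stays within o(dp^2) of the full curve over p0 +/- 10 MPa
# (third-order remainder ~ ddelta * (V/RT)^3 / 8 * dp^3 well under 1e-4 ppm).
mild_ensemble <- function(n_states = sample(2:3, 1), p0 = 0.1) {
  states <- lapply(seq_len(n_states), function(k) {
    thermo_state(paste0("s", k),
                 shift = runif(1, 7, 9),
                 G0 = runif(1, -2000, 2000),
                 V0 = runif(1, -20, 20),
                 beta0 = runif(1, -0.1, 0.1))
  })
  ensemble_model(states, p0 = p0)
}

# Richardson-extrapolated central differences: truncation O(h^4), used as
# the independent oracle for taylor_coefficients().
central_diff1 <- function(f, x, h) {
  d <- function(h) (f(x + h) - f(x - h)) / (2 * h)
  (4 * d(h / 2) - d(h)) / 3
}
central_diff2 <- function(f, x, h) {
  d <- function(h) (f(x + h) - 2 * f(x) + f(x - h)) / h^2
  (4 * d(h / 2) - d(h)) / 3
}

# Brute-force ensemble average in the straightforward order of operations,
# independent of the vectorized implementation path.
brute_force_shift <- function(model, p) {
  RT <- 8.31446 * model$temperature
  dp <- p - model$p0
  w <- vapply(model$states, function(s) {
    exp(-(s$G0 + s$V0 * dp + 0.5 * s$beta0 * dp^2) / RT)
  }, numeric(1))
  sum(vapply(model$states, `[[`, numeric(1), "shift") * w) / sum(w)
}

expect_sigdigits <- function(actual, expected, digits = 10) {
  expect_lt(abs(actual - expected),
            10^(-digits) * max(abs(expected), 1e-300) * 10)
}
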