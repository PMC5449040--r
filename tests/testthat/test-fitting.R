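ref <- load_reference()

test_that("noiseless round trips recover every reference entry exactly", {
  grid <- default_grid
  for (i in seq_len(nrow(ref))) {
    co <- pressure_coefficients(ref$delta0[i], ref$B1[i], ref$B2[i])
    fit <- fit_quadratic(pressure_series(grid, predict_shift(co, grid)))
    expect_sigdigits(fit$coefficients$delta0, ref$delta0[i])
    expect_sigdigits(fit$coefficients$B1, ref$B1[i])
    expect_sigdigits(fit$coefficients$B2, ref$B2[i])
    expect_lt(fit$rms, 1e-10)
  }
})

test_that("three points interpolate exactly with undefined errors", {
  s <- pressure_series(c(0.1, 100, 200), c(0, 1, 1.5))
  fit <- fit_quadratic(s)
  expect_identical(fit$dof, 0L)
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-10)
  expect_true(is.na(fit$coefficients$B1_err))
  expect_true(is.na(fit$coefficients$delta0_err))
  expect_error(pressure_series(c(0.1, 100), c(0, 1)), "need >= 3 pressures")
  expect_error(pressure_series(c(0.1, 100, 100), c(0, 1, 1)),
               "strictly increasing")
  expect_error(pressure_series(c(0.1, 100, 1500), c(0, 1, 2)),
               "\\[0, 1000\\]")
})

test_that("the fit is equivariant under shift and pressure scaling", {
  set.seed(21)
  p <- default_grid
  y <- predict_shift(pressure_coefficients(120, 3, -2), p) + rnorm(9, 0, 0.01)
  f0 <- fit_quadratic(pressure_series(p, y))
  # adding a constant moves only delta0
  f1 <- fit_quadratic(pressure_series(p, y + 5))
  expect_equal(f1$coefficients$delta0, f0$coefficients$delta0 + 5)
  expect_equal(f1$coefficients$B1, f0$coefficients$B1)
  expect_equal(f1$coefficients$B2, f0$coefficients$B2)
  # halving all pressure offsets doubles B1 and quadruples B2
  f2 <- fit_quadratic(pressure_series(0.1 + (p - 0.1) / 2, y), p0 = 0.1)
  expect_equal(f2$coefficients$B1, 2 * f0$coefficients$B1)
  expect_equal(f2$coefficients$B2, 4 * f0$coefficients$B2)
})

test_that("inverse-variance weights reproduce the weighted solution", {
  set.seed(22)
  p <- default_grid
  y <- predict_shift(pressure_coefficients(8.4, 0.5, -0.4), p) +
    rnorm(9, 0, 0.005)
  w <- c(rep(4, 5), rep(1, 4))
  fit <- fit_quadratic(pressure_series(p, y, weights = w))
  x <- (p - 0.1) / 1000
  oracle <- stats::lm(y ~ x + I(x^2), weights = w)
  expect_equal(fit$coefficients$B1, unname(coef(oracle)[2]))
  expect_equal(fit$coefficients$B1_err,
               unname(sqrt(diag(vcov(oracle)))[2]))
})

test_that("Monte-Carlo: B1 estimator is unbiased and its SE honest", {
  set.seed(23)
  truth <- pressure_coefficients(109.22, 3.79, -2.16)
  sigma <- 0.01
  p <- default_grid
  mu <- predict_shift(truth, p)
  n_rep <- 1000
  b1 <- se1 <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    fit <- fit_quadratic(pressure_series(p, mu + rnorm(9, 0, sigma)))
    b1[r] <- fit$coefficients$B1
    se1[r] <- fit$coefficients$B1_err
  }
  # bias well under the Monte-Carlo standard error of the mean
  expect_lt(abs(mean(b1) - 3.79), 4 * sd(b1) / sqrt(n_rep))
  # reported SE tracks the empirical spread within 15%
  expect_lt(abs(mean(se1) - sd(b1)) / sd(b1), 0.15)
})

test_that("confidence intervals cover at the nominal rate", {
  # 33-point series so the residual variance estimate has enough dof for
  # the normal-theory +/- 1.96 SE interval to be calibrated
  set.seed(24)
  truth <- pressure_coefficients(120.0, 3.0, -2.5)
  p <- seq(0.1, 200, length.out = 33)
  mu <- predict_shift(truth, p)
  n_rep <- 1000
  covered <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    fit <- fit_quadratic(pressure_series(p, mu + rnorm(33, 0, 0.01)))
    co <- fit$coefficients
    covered[r] <- abs(co$delta0 - 120.0) <= 1.96 * co$delta0_err
  }
  expect_gte(mean(covered), 0.92)
  expect_lte(mean(covered), 0.98)
})

test_that("two-state fit recovers thermodynamic parameters", {
  truth <- ensemble_model(list(thermo_state("A", 8),
                               thermo_state("B", 10, G0 = 2000, V0 = -50)))
  for (seed in 1:5) {
    cfg <- simulation_config(pressure_grid = seq(0.1, 200, length.out = 16),
                             seed = seed)
    fit <- fit_two_state(simulate_two_state(truth, cfg, "N15"))
    expect_false(fit$quadratic_sufficient)
    b <- fit$model$states[[2]]
    expect_lt(abs(b$V0 - (-50)) / 50, 0.20)
    expect_lt(abs(fit$model$states[[1]]$shift - 8), 0.2)
  }
})

test_that("two-state fit flags non-identifiable inputs", {
  # noiseless single-state data: degenerate, quadratic is sufficient
  flat <- pressure_series(default_grid, rep(8.5, 9))
  expect_true(fit_two_state(flat)$quadratic_sufficient)
  # exactly quadratic data (noiseless): flagged too
  gly <- pressure_coefficients(109.22, 3.79, -2.16)
  quad <- pressure_series(default_grid, predict_shift(gly, default_grid))
  expect_true(fit_two_state(quad)$quadratic_sufficient)
  # and with noise at the experimental level
  cfg <- simulation_config(seed = 7)
  noisy <- simulate_series(gly, cfg, "N15")
  expect_true(fit_two_state(noisy)$quadratic_sufficient)
  expect_error(fit_two_state(pressure_series(c(1, 2, 3), c(1, 2, 3))),
               "need >= 5 points")
})

test_that("series csv io round-trips and rejects bad headers", {
  s <- pressure_series(default_grid,
                       predict_shift(pressure_coefficients(8.4, 0.5, -0.4),
                                     default_grid), nucleus = "H1N")
  path <- withr::local_tempfile(fileext = ".csv")
  write_pressure_series(s, path)
  back <- read_pressure_series(path, nucleus = "H1N")
  expect_equal(back$pressures, s$pressures)
  expect_equal(back$shifts, s$shifts)
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2"), bad)
  expect_error(read_pressure_series(bad), "pressure_MPa")
})
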