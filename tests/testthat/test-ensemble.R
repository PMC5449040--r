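test_that("state populations follow the closed forms", {
  # identical free energies, no pressure sensitivity: uniform at any p
  m <- ensemble_model(list(thermo_state("a", 8), thermo_state("b", 9)))
  for (p in c(0.1, 100, 200)) {
    expect_equal(unname(state_populations(m, p)), c(0.5, 0.5))
  }
  # dG = RT ln 9 puts 90/10 at p0
  RT <- 8.31446 * 283
  m2 <- ensemble_model(list(thermo_state("a", 8),
                            thermo_state("b", 9, G0 = RT * log(9))))
  expect_equal(unname(state_populations(m2, 0.1)), c(0.9, 0.1))
  # negative dV: the high-pressure state grows strictly with p
  m3 <- ensemble_model(list(thermo_state("a", 8),
                            thermo_state("b", 9, G0 = 3000, V0 = -40)))
  pops <- state_populations(m3, seq(0.1, 200, length.out = 30), drop = FALSE)
  expect_true(all(diff(pops["b", ]) > 0))
})

test_that("populations are a simplex and gauge-invariant", {
  set.seed(11)
  for (i in 1:25) {
    m <- random_ensemble()
    p <- runif(1, 0, 200)
    pops <- state_populations(m, p)
    expect_equal(sum(pops), 1, tolerance = 1e-12)
    expect_true(all(pops >= 0))
    # adding a constant to every G0 changes nothing
    shifted <- ensemble_model(lapply(m$states, function(s) {
      thermo_state(s$label, s$shift, s$G0 + 12345, s$V0, s$beta0)
    }), temperature = m$temperature, p0 = m$p0)
    expect_equal(state_populations(shifted, p), pops, tolerance = 1e-12)
  }
})

test_that("huge exponents are handled overflow-safely or rejected clearly", {
  m <- ensemble_model(list(thermo_state("a", 8, G0 = -5e6),
                           thermo_state("b", 9, G0 = 5e6)))
  pops <- state_populations(m, 0.1)
  expect_equal(unname(pops), c(1, 0))
  bad <- ensemble_model(list(
    thermo_state("a", 8, beta0 = .Machine$double.xmax),
    thermo_state("b", 9)))
  expect_error(state_populations(bad, 200), "non-finite.*'a'")
})

test_that("ensemble shift is the population-weighted mean", {
  m <- ensemble_model(list(thermo_state("a", 8), thermo_state("b", 9)))
  expect_equal(ensemble_shift(m, 0.1), 8.5)
  # a 50 kJ/mol penalty makes the other state invisible
  m2 <- ensemble_model(list(thermo_state("a", 8),
                            thermo_state("b", 9, G0 = 5e4)))
  expect_lt(abs(ensemble_shift(m2, 0.1) - 8), 1e-6)
  # bounded by the state shifts, and equal to brute-force summation
  set.seed(12)
  for (i in 1:25) {
    m <- random_ensemble()
    p <- runif(1, 0, 200)
    val <- ensemble_shift(m, p)
    shifts <- vapply(m$states, `[[`, numeric(1), "shift")
    expect_gte(val, min(shifts))
    expect_lte(val, max(shifts))
    expect_equal(val, brute_force_shift(m, p), tolerance = 1e-13)
  }
})

test_that("ensemble shift is monotone when all dV share a sign and beta = 0", {
  set.seed(13)
  for (i in 1:10) {
    m <- ensemble_model(list(
      thermo_state("a", runif(1, 7, 8)),
      thermo_state("b", runif(1, 9, 10), G0 = runif(1, -2000, 2000),
                   V0 = -runif(1, 10, 80))))
    y <- ensemble_shift(m, seq(0.1, 200, length.out = 50))
    expect_true(all(diff(y) > 0) || all(diff(y) < 0))
  }
})

test_that("taylor_coefficients matches the numeric oracle and closed forms", {
  # single effective state: no pressure response
  m0 <- ensemble_model(list(thermo_state("a", 8.5, V0 = -30),
                            thermo_state("b", 8.5, V0 = 40)))
  tc0 <- taylor_coefficients(m0)
  expect_equal(tc0$B1, 0)
  expect_equal(tc0$B2, 0)
  expect_equal(tc0$delta0, 8.5)

  # equal-population two-state closed form:
  # B1[/MPa] = -ddelta * f(1-f) * dV / RT, f = 1/2
  RT <- 8.31446 * 283
  m1 <- ensemble_model(list(thermo_state("a", 8),
                            thermo_state("b", 9, V0 = -41.4)))
  expect_equal(taylor_coefficients(m1)$B1, 1 * 0.25 * 41.4 / RT * 1e3)

  # property: agreement with Richardson central differences, 100 models
  set.seed(14)
  for (i in 1:100) {
    m <- random_ensemble()
    tc <- taylor_coefficients(m)
    f <- function(p) ensemble_shift(m, p)
    b1_num <- central_diff1(f, m$p0, 0.5) * 1e3
    b2_num <- 0.5 * central_diff2(f, m$p0, 0.5) * 1e6
    expect_equal(tc$B1, b1_num, tolerance = 1e-6)
    expect_equal(tc$B2, b2_num, tolerance = 1e-6)
    expect_equal(tc$delta0, f(m$p0))
  }
})

test_that("the local quadratic tracks the ensemble to o(dp^2) near p0", {
  set.seed(15)
  for (i in 1:20) {
    m <- mild_ensemble(p0 = 0.1)
    tc <- taylor_coefficients(m)
    p <- seq(0.1, 10.1, length.out = 21)
    dev <- abs(predict_shift(tc, p) - ensemble_shift(m, p))
    expect_lt(max(dev), 1e-4)
  }
})

test_that("model validation rejects malformed ensembles", {
  expect_error(ensemble_model(list(thermo_state("a", 8))), ">= 2")
  expect_error(ensemble_model(list(thermo_state("a", 8),
                                   thermo_state("a", 9))), "unique")
  expect_error(ensemble_model(list(thermo_state("a", 8),
                                   thermo_state("b", 9)),
                              temperature = -1), "temperature")
  expect_error(thermo_state("a", Inf), "finite")
})

test_that("key-value serialization round-trips a model exactly", {
  set.seed(16)
  m <- random_ensemble(3)
  path <- withr::local_tempfile(fileext = ".dcf")
  write_ensemble_model(m, path)
  back <- read_ensemble_model(path)
  expect_equal(back, m)
  expect_error(read_ensemble_model(
    write_reference(load_reference(), withr::local_tempfile(), "dcf")),
    "not an ensemble_model")
})
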