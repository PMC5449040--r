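## Multistate Boltzmann ensemble with pressure-dependent free energies.
##
## Each state i carries a shift expectation <delta_i> and a free energy
##   G_i(p) = G_i^0 + V_i^0 dp + (1/2) beta_i^0 dp^2,   dp = p - p0 in MPa,
## with V in mL/mol and beta in mL/(mol MPa); since 1 mL MPa = 1 J the
## exponent G_i(p)/RT is dimensionless without conversion factors.

.gas_constant <- 8.31446  # J/(mol K)

#' Define one conformational state
#'
#' @param label unique state name.
#' @param shift expectation value of the observed chemical shift in this
#'   state, ppm.
#' @param G0 free energy at (p0, T0) relative to an arbitrary reference,
#'   J/mol.
#' @param V0 partial molar volume difference at (p0, T0), mL/mol.
#' @param beta0 compressibility factor at (p0, T0), mL/(mol MPa).
#' @return a `thermo_state` list.
#' @seealso [ensemble_model()]
#' @export
thermo_state <- function(label, shift, G0 = 0, V0 = 0, beta0 = 0) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label),
            is.numeric(shift), length(shift) == 1L, is.finite(shift),
            is.numeric(G0), is.finite(G0),
            is.numeric(V0), is.finite(V0),
            is.numeric(beta0), is.finite(beta0))
  structure(list(label = label, shift = as.numeric(shift), G0 = as.numeric(G0),
                 V0 = as.numeric(V0), beta0 = as.numeric(beta0)),
            class = "thermo_state")
}

#' Build a multistate ensemble model
#'
#' The observed (fast-exchange) shift is the population-weighted average of
#' the state shifts, with Boltzmann populations
#' \deqn{p_i'(p) = \exp\!\big(-(G_i^0 + V_i^0\Delta p +
#'   \tfrac12\beta_i^0\Delta p^2)/RT\big)\big/Z,}
#' \eqn{\Delta p = p - p_0} in MPa and \eqn{Z} the sum over states.
#'
#' @param states list of [thermo_state()] objects, at least two, with unique
#'   labels.
#' @param temperature absolute temperature in K (default 283, the
#'   experimental temperature of the reference data).
#' @param p0 reference pressure in MPa (default atmospheric, 0.1).
#' @return an `ensemble_model`.
#' @examples
#' m <- ensemble_model(list(thermo_state("closed", 8.0),
#'                          thermo_state("open", 9.0, G0 = 2000, V0 = -50)))
#' ensemble_shift(m, c(0.1, 100, 200))
#' @export
ensemble_model <- function(states, temperature = 283, p0 = 0.1) {
  if (!is.list(states) || length(states) < 2L ||
      !all(vapply(states, inherits, TRUE, "thermo_state"))) {
    stop("states must be a list of >= 2 thermo_state objects", call. = FALSE)
  }
  labels <- vapply(states, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("state labels must be unique", call. = FALSE)
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            is.finite(temperature), temperature > 0,
            is.numeric(p0), length(p0) == 1L, is.finite(p0), p0 >= 0)
  structure(list(states = states, temperature = as.numeric(temperature),
                 p0 = as.numeric(p0), R = .gas_constant),
            class = "ensemble_model")
}

## Per-state fields as vectors.
.state_field <- function(model, field) {
  vapply(model$states, `[[`, numeric(1), field)
}

#' State populations at given pressures
#'
#' Boltzmann populations of every state, normalized so each column sums to
#' one.  The computation is overflow-safe: the largest exponent is
#' subtracted before exponentiating, which changes nothing analytically
#' (populations are invariant under adding a constant to all free energies).
#'
#' @param model an [ensemble_model()].
#' @param p pressure(s) in MPa.
#' @return a matrix with one row per state (rownames = labels) and one
#'   column per pressure; drop to a named vector for scalar `p` with
#'   `drop = TRUE`.
#' @param drop if `TRUE` (default) and `p` is scalar, return a named vector.
#' @export
state_populations <- function(model, p, drop = TRUE) {
  stopifnot(inherits(model, "ensemble_model"), is.numeric(p))
  if (any(!is.finite(p)) || any(p < 0)) {
    stop("pressures must be finite and non-negative (MPa)", call. = FALSE)
  }
  G0 <- .state_field(model, "G0")
  V0 <- .state_field(model, "V0")
  b0 <- .state_field(model, "beta0")
  RT <- model$R * model$temperature
  labels <- vapply(model$states, `[[`, "", "label")
  dp <- p - model$p0
  # states x pressures matrix of exponents -G(p)/RT
  ex <- -(outer(G0, rep(1, length(p))) + outer(V0, dp) + 0.5 * outer(b0, dp^2)) / RT
  bad <- which(!is.finite(ex), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("non-finite Boltzmann exponent for state '", labels[bad[1, 1]],
         "'", call. = FALSE)
  }
  ex <- sweep(ex, 2, apply(ex, 2, max))
  w <- exp(ex)
  pop <- sweep(w, 2, colSums(w), "/")
  rownames(pop) <- labels
  if (drop && length(p) == 1L) pop[, 1] else pop
}

#' Ensemble-averaged chemical shift
#'
#' Population-weighted mean of the state shifts at each pressure — the
#' observable under fast exchange.  Always lies within the range of the
#' state shifts.
#'
#' @inheritParams state_populations
#' @return shift(s) in ppm, same length as `p`.
#' @export
ensemble_shift <- function(model, p) {
  pop <- state_populations(model, p, drop = FALSE)
  drop(crossprod(pop, .state_field(model, "shift")))[seq_along(p)]
}

#' Taylor coefficients of the ensemble shift at p0
#'
#' Analytic first and second pressure derivatives of [ensemble_shift()]
#' evaluated at the reference pressure, repackaged as the quadratic-model
#' coefficients.  Writing \eqn{\langle\cdot\rangle} for the population
#' average at \eqn{p_0},
#' \deqn{B_1^{(\mathrm{MPa})} = -\mathrm{Cov}(\delta, V)/RT,}
#' \deqn{2 B_2^{(\mathrm{MPa})} =
#'   \big\langle(\delta-\langle\delta\rangle)(V-\langle V\rangle)^2
#'   \big\rangle / (RT)^2 - \mathrm{Cov}(\delta, \beta)/RT,}
#' then converted to the tabulated per-GPa / per-GPa^2 units
#' (\eqn{\times 10^3} and \eqn{\times 10^6}).
#'
#' @param model an [ensemble_model()].
#' @return a [pressure_coefficients()] object (`delta0` is the ensemble
#'   shift at `p0`).
#' @export
taylor_coefficients <- function(model) {
  stopifnot(inherits(model, "ensemble_model"))
  w <- state_populations(model, model$p0, drop = FALSE)[, 1]
  d <- .state_field(model, "shift")
  V <- .state_field(model, "V0")
  b <- .state_field(model, "beta0")
  RT <- model$R * model$temperature

  Ed <- sum(w * d)
  EV <- sum(w * V)
  cov_dV <- sum(w * d * V) - Ed * EV
  cov_db <- sum(w * d * b) - Ed * sum(w * b)
  m3 <- sum(w * (d - Ed) * (V - EV)^2)

  b1_mpa <- -cov_dV / RT
  b2_mpa <- 0.5 * (m3 / RT^2 - cov_db / RT)
  pressure_coefficients(delta0 = Ed, B1 = b1_mpa * 1e3, B2 = b2_mpa * 1e6,
                        p0 = model$p0)
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("Ensemble model: %d states, T = %g K, p0 = %g MPa\n",
              length(x$states), x$temperature, x$p0))
  df <- data.frame(
    label = vapply(x$states, `[[`, "", "label"),
    shift_ppm = .state_field(x, "shift"),
    G0_J_mol = .state_field(x, "G0"),
    V0_mL_mol = .state_field(x, "V0"),
    beta0_mL_mol_MPa = .state_field(x, "beta0")
  )
  print(df, row.names = FALSE)
  invisible(x)
}

## ---- key-value serialization ---------------------------------------------

#' Write / read an ensemble model as structured key-value text
#'
#' One DCF record per state plus a leading header record carrying the
#' temperature and reference pressure; numeric values at full precision so
#' the round trip is exact.
#'
#' @param model an [ensemble_model()].
#' @param path file path.
#' @return `write_ensemble_model()`: `path`, invisibly;
#'   `read_ensemble_model()`: the model.
#' @export
write_ensemble_model <- function(model, path) {
  stopifnot(inherits(model, "ensemble_model"))
  f15 <- function(v) format(v, digits = 15)
  head <- cbind(Type = "ensemble_model", Temperature = f15(model$temperature),
                P0 = f15(model$p0))
  states <- do.call(rbind, lapply(model$states, function(s) {
    cbind(Label = s$label, Shift = f15(s$shift), G0 = f15(s$G0),
          V0 = f15(s$V0), Beta0 = f15(s$beta0))
  }))
  con <- file(path, "w")
  on.exit(close(con))
  write.dcf(head, con)
  write.dcf(states, con)
  invisible(path)
}

#' @rdname write_ensemble_model
#' @export
read_ensemble_model <- function(path) {
  m <- read.dcf(path, fields = c("Type", "Temperature", "P0", "Label",
                                 "Shift", "G0", "V0", "Beta0"))
  hd <- which(!is.na(m[, "Type"]) & m[, "Type"] == "ensemble_model")
  if (length(hd) != 1L) stop("not an ensemble_model file: ", path, call. = FALSE)
  rows <- which(!is.na(m[, "Label"]))
  states <- lapply(rows, function(i) {
    thermo_state(unname(m[i, "Label"]), as.numeric(m[i, "Shift"]),
                 G0 = as.numeric(m[i, "G0"]), V0 = as.numeric(m[i, "V0"]),
                 beta0 = as.numeric(m[i, "Beta0"]))
  })
  ensemble_model(states, temperature = as.numeric(m[hd, "Temperature"]),
                 p0 = as.numeric(m[hd, "P0"]))
}
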