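## Quadratic pressure-shift model and the fast-exchange criterion.

#' Pressure-coefficient triple
#'
#' The object of the second-order Taylor expansion of a chemical shift in
#' pressure about the reference pressure `p0`:
#' \deqn{\delta(p) = \delta_0 + B_1 \Delta p + B_2 \Delta p^2,\qquad
#'       \Delta p = (p - p_0)/1000 \ \mathrm{GPa}.}
#'
#' @param delta0 shift at `p0`, ppm.
#' @param B1 first-order coefficient, ppm/GPa.
#' @param B2 second-order coefficient, ppm/GPa^2.
#' @param delta0_err,B1_err,B2_err optional standard errors (same units).
#' @param p0 reference pressure in MPa; defaults to atmospheric (0.1).
#' @return an object of class `pressure_coefficients`.
#' @seealso [predict_shift()], [fit_quadratic()], [as_coefficients()]
#' @export
pressure_coefficients <- function(delta0, B1, B2, delta0_err = NA_real_,
                                  B1_err = NA_real_, B2_err = NA_real_,
                                  p0 = 0.1) {
  stopifnot(is.numeric(delta0), is.numeric(B1), is.numeric(B2),
            length(delta0) == 1L, length(B1) == 1L, length(B2) == 1L,
            is.finite(delta0), is.finite(B1), is.finite(B2))
  if (!is.numeric(p0) || length(p0) != 1L || !is.finite(p0) || p0 < 0) {
    stop("p0 must be a single non-negative pressure in MPa", call. = FALSE)
  }
  errs <- c(delta0_err, B1_err, B2_err)
  if (any(!is.na(errs) & errs < 0)) {
    stop("standard errors must be non-negative", call. = FALSE)
  }
  structure(list(delta0 = as.numeric(delta0), B1 = as.numeric(B1),
                 B2 = as.numeric(B2), delta0_err = as.numeric(delta0_err),
                 B1_err = as.numeric(B1_err), B2_err = as.numeric(B2_err),
                 p0 = as.numeric(p0)),
            class = "pressure_coefficients")
}

#' Convert a reference entry to pressure coefficients
#'
#' @param entry an `rc_entry` from [get_entry()].
#' @param p0 reference pressure in MPa.
#' @return a `pressure_coefficients` object carrying the entry's values and
#'   standard errors (the tabulated \eqn{\delta_0} reading error is 0.01 ppm
#'   for \eqn{^{15}}N and 0.001 ppm for \eqn{^1}H).
#' @export
as_coefficients <- function(entry, p0 = 0.1) {
  stopifnot(inherits(entry, "rc_entry"))
  pressure_coefficients(entry$delta0, entry$B1, entry$B2,
                        delta0_err = if (entry$nucleus == "N15") 0.01 else 0.001,
                        B1_err = entry$B1_err, B2_err = entry$B2_err, p0 = p0)
}

#' Predict a chemical shift from pressure coefficients
#'
#' Evaluates the quadratic model at pressures `p` (MPa).  The pressure
#' offset from `p0` is converted to GPa by exact division by 1000, matching
#' the units in which B1 and B2 are tabulated.
#'
#' @param coeffs a `pressure_coefficients` object.
#' @param p pressure(s) in MPa, each \eqn{\ge 0}.
#' @return predicted shift(s) in ppm, same length as `p`.
#' @examples
#' gly <- pressure_coefficients(109.22, 3.79, -2.16)
#' predict_shift(gly, c(0.1, 200))
#' @export
predict_shift <- function(coeffs, p) {
  stopifnot(inherits(coeffs, "pressure_coefficients"), is.numeric(p))
  if (any(!is.finite(p)) || any(p < 0)) {
    stop("pressures must be finite and non-negative (MPa)", call. = FALSE)
  }
  dp <- (p - coeffs$p0) / 1000
  coeffs$delta0 + coeffs$B1 * dp + coeffs$B2 * dp^2
}

#' @export
print.pressure_coefficients <- function(x, ...) {
  fe <- function(v, e) {
    if (is.na(e)) format(v) else sprintf("%s +/- %s", format(v), format(e))
  }
  cat(sprintf("Pressure coefficients (p0 = %g MPa):\n", x$p0))
  cat("  delta0:", fe(x$delta0, x$delta0_err), "ppm\n")
  cat("  B1:    ", fe(x$B1, x$B1_err), "ppm/GPa\n")
  cat("  B2:    ", fe(x$B2, x$B2_err), "ppm/GPa^2\n")
  invisible(x)
}

#' Fast-exchange criterion
#'
#' Two conformational states contribute a single population-averaged
#' resonance only when interconversion is fast on the chemical-shift
#' timescale, i.e. when \eqn{|\Delta\omega_{ij}\,\tau_{ij}| \ll 1}.  This
#' helper evaluates that product and compares it against a concrete
#' threshold (default 0.1, one reading of "much less than one").
#'
#' @param delta_omega shift difference between the states, rad/s.
#' @param tau exchange correlation time, s (\eqn{\ge 0}).
#' @param threshold dimensionless cutoff below which exchange is declared
#'   fast.
#' @return an `exchange_check` list: `delta_omega`, `tau`, `product`
#'   (\eqn{|\Delta\omega\,\tau|}) and logical `fast`.
#' @examples
#' check_fast_exchange(100, 1e-5)$fast  # TRUE
#' @export
check_fast_exchange <- function(delta_omega, tau, threshold = 0.1) {
  stopifnot(is.numeric(delta_omega), is.numeric(tau), length(tau) == length(delta_omega))
  if (any(tau < 0)) stop("tau must be non-negative", call. = FALSE)
  if (!is.numeric(threshold) || threshold <= 0) {
    stop("threshold must be positive", call. = FALSE)
  }
  product <- abs(delta_omega * tau)
  structure(list(delta_omega = delta_omega, tau = tau, product = product,
                 threshold = threshold, fast = product < threshold),
            class = "exchange_check")
}

#' @export
print.exchange_check <- function(x, ...) {
  cat(sprintf("|domega * tau| = %s (threshold %g): %s exchange\n",
              paste(format(x$product), collapse = ", "), x$threshold,
              paste(ifelse(x$fast, "fast", "NOT fast"), collapse = ", ")))
  invisible(x)
}
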