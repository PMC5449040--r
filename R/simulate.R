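## Seeded synthetic-data generator emulating a 0.1-200 MPa HSQC titration.
##
## The generator is the package's stated experimental world: a 9-point
## evenly spaced pressure grid (the source tables do not print their grid;
## 9 points over 0.1-200 MPa mirrors typical high-pressure NMR titrations),
## with i.i.d. Gaussian shift-reading noise at the tabulated uncertainties
## (0.01 ppm for 15N, 0.001 ppm for amide 1H).

#' Simulation configuration
#'
#' @param pressure_grid pressures in MPa, strictly increasing (default 9
#'   evenly spaced points over 0.1--200 MPa).
#' @param noise_sd_H1 Gaussian noise sd for amide \eqn{^1}H shifts, ppm
#'   (default 0.001, the tabulated \eqn{\delta_0} reading error).
#' @param noise_sd_N15 Gaussian noise sd for \eqn{^{15}}N shifts, ppm
#'   (default 0.01).
#' @param seed optional integer seed; when set, every simulation call is
#'   reproducible and leaves the global RNG stream untouched.
#' @param replicates number of replicate series where applicable.
#' @return a `simulation_config`.
#' @export
simulation_config <- function(pressure_grid = seq(0.1, 200, length.out = 9),
                              noise_sd_H1 = 0.001, noise_sd_N15 = 0.01,
                              seed = NULL, replicates = 1L) {
  stopifnot(is.numeric(pressure_grid), length(pressure_grid) >= 3L,
            all(is.finite(pressure_grid)), all(diff(pressure_grid) > 0),
            is.numeric(noise_sd_H1), noise_sd_H1 >= 0,
            is.numeric(noise_sd_N15), noise_sd_N15 >= 0,
            is.numeric(replicates), replicates >= 1L)
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    seed <- as.integer(seed)
  }
  structure(list(pressure_grid = as.numeric(pressure_grid),
                 noise_sd_H1 = as.numeric(noise_sd_H1),
                 noise_sd_N15 = as.numeric(noise_sd_N15),
                 seed = seed, replicates = as.integer(replicates)),
            class = "simulation_config")
}

## Evaluate fn with a private RNG stream when seed is set.
.with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

.noise_sd <- function(config, nucleus) {
  switch(nucleus, N15 = config$noise_sd_N15, H1N = config$noise_sd_H1,
         stop("nucleus must be N15 or H1N", call. = FALSE))
}

#' Simulate a pressure series from quadratic coefficients
#'
#' Evaluates [predict_shift()] on the configured grid and adds i.i.d.
#' Gaussian noise at the nucleus-appropriate standard deviation
#' (zero noise allowed).
#'
#' @param coeffs a [pressure_coefficients()] object (e.g. from
#'   [as_coefficients()]).
#' @param config a [simulation_config()].
#' @param nucleus `"N15"` or `"H1N"`; selects the noise level.
#' @return a [pressure_series()].
#' @examples
#' ref <- load_reference()
#' s <- simulate_series(as_coefficients(get_entry(ref, "Ala", "N15")),
#'                      simulation_config(seed = 7), "N15")
#' @export
simulate_series <- function(coeffs, config = simulation_config(),
                            nucleus = c("N15", "H1N")) {
  stopifnot(inherits(coeffs, "pressure_coefficients"),
            inherits(config, "simulation_config"))
  nucleus <- match.arg(nucleus)
  sd <- .noise_sd(config, nucleus)
  grid <- config$pressure_grid
  truth <- predict_shift(coeffs, grid)
  shifts <- .with_seed(config$seed, function() {
    truth + stats::rnorm(length(grid), 0, sd)
  })
  pressure_series(grid, shifts, nucleus = nucleus)
}

#' Simulate the full reference panel as peak tracks
#'
#' One track per library entry -- the 22 \eqn{^{15}}N entries followed by
#' the 19 amide \eqn{^1}H entries, residue ids 1..41 -- each generated from
#' that entry's own coefficients plus nucleus-level noise.  Running
#' [correct_tracks()] on the noiseless panel is the pipeline's
#' self-correction null: every \eqn{\Delta B} is zero and nothing is
#' flagged.
#'
#' @param config a [simulation_config()].
#' @param reference an `rc_reference` (default: bundled library).
#' @return list of 41 [peak_track()] objects.
#' @export
simulate_reference_panel <- function(config = simulation_config(),
                                     reference = load_reference()) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(reference, "rc_reference"))
  ord <- order(match(reference$nucleus, .rc_nuclei))
  ref <- as.data.frame(reference)[ord, ]
  grid <- config$pressure_grid
  .with_seed(config$seed, function() {
    lapply(seq_len(nrow(ref)), function(i) {
      row <- ref[i, ]
      coeffs <- pressure_coefficients(row$delta0, row$B1, row$B2)
      sd <- .noise_sd(config, row$nucleus)
      shifts <- predict_shift(coeffs, grid) + stats::rnorm(length(grid), 0, sd)
      peak_track(i, row$residue, row$nucleus,
                 pressure_series(grid, shifts, nucleus = row$nucleus),
                 variant = row$variant)
    })
  })
}

#' Simulate a pressure series from an ensemble model
#'
#' [ensemble_shift()] on the configured grid plus Gaussian noise; the input
#' for two-state parameter-recovery studies with [fit_two_state()].
#'
#' @param model an [ensemble_model()].
#' @param config a [simulation_config()].
#' @param nucleus noise-level selector (default `"N15"`).
#' @return a [pressure_series()].
#' @export
simulate_two_state <- function(model, config = simulation_config(),
                               nucleus = c("N15", "H1N")) {
  stopifnot(inherits(model, "ensemble_model"),
            inherits(config, "simulation_config"))
  nucleus <- match.arg(nucleus)
  sd <- .noise_sd(config, nucleus)
  grid <- config$pressure_grid
  truth <- ensemble_shift(model, grid)
  shifts <- .with_seed(config$seed, function() {
    truth + stats::rnorm(length(grid), 0, sd)
  })
  pressure_series(grid, shifts, nucleus = nucleus)
}
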