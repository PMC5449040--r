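## Random-coil correction of protein pressure tracks.
##
## The pressure response of a disordered chain is "trivial": it reflects
## hydrogen-bond compression, not structure.  Subtracting the model-peptide
## coefficients from per-residue protein fits exposes the residues whose
## pressure response exceeds that baseline.

#' Construct a peak track
#'
#' One residue's measured shift-versus-pressure series in a protein.
#'
#' @param residue_id sequence position (integer).
#' @param residue_type three-letter amino-acid code.
#' @param nucleus `"N15"` or `"H1N"`.
#' @param series a [pressure_series()].
#' @param variant optional reference variant override (His pH form, Pro
#'   isomer); `NULL` uses the library defaults.
#' @return a `peak_track`.
#' @export
peak_track <- function(residue_id, residue_type, nucleus, series,
                       variant = NULL) {
  stopifnot(length(residue_id) == 1L, is.finite(residue_id),
            residue_id == round(residue_id),
            is.character(residue_type), length(residue_type) == 1L,
            inherits(series, "pressure_series"))
  if (!residue_type %in% .rc_residues) {
    stop("residue_type must be a canonical three-letter code, got: ",
         residue_type, call. = FALSE)
  }
  nucleus <- match.arg(nucleus, .rc_nuclei)
  structure(list(residue_id = as.integer(residue_id),
                 residue_type = residue_type, nucleus = nucleus,
                 series = series, variant = variant),
            class = "peak_track")
}

#' Correct peak tracks against the random-coil reference
#'
#' For every track: fit the quadratic pressure model, subtract the matching
#' random-coil \eqn{B_1}/\eqn{B_2}, and score the differences
#' \deqn{z_k = |\Delta B_k| \big/ \sqrt{SE_{obs}^2 + SE_{ref}^2}}
#' (standard errors combined in quadrature, assuming independence).  A track
#' is flagged when \eqn{z_1} exceeds `threshold`; \eqn{B_2} differences are
#' reported with their own score but do not drive the flag by default (the
#' tabulated \eqn{B_2} errors are several-fold larger).  Differences in
#' \eqn{\delta_0} are never flagged: absolute random-coil shifts depend on
#' sequence context, only the pressure response is corrected.  Tracks whose
#' residue/nucleus/variant combination is absent from the reference are
#' reported in the `skipped` attribute, never dropped silently.
#'
#' @param tracks list of [peak_track()] objects (may be empty).
#' @param reference an `rc_reference`; defaults to the bundled library.
#' @param threshold flagging threshold on \eqn{z_1} (default 2.0 — roughly a
#'   two-sided 5% level; this significance rule is this package's own
#'   convention, not part of the measured data).
#' @param threshold_B2 optional threshold on \eqn{z_2}; `Inf` (default)
#'   disables flagging on the second-order coefficient.
#' @param p0 reference pressure in MPa.
#' @return a `correction_results` data frame ordered by `residue_id` with
#'   columns `residue_id`, `residue_type`, `nucleus`, observed and reference
#'   `B1`/`B2`, `dB1`, `dB2`, `z1`, `z2`, `flagged`; skipped tracks (with
#'   reasons) in `attr(, "skipped")`.
#' @examples
#' ref <- load_reference()
#' p <- seq(0.1, 200, length.out = 9)
#' tr <- peak_track(12, "Ala", "N15",
#'                  pressure_series(p, predict_shift(
#'                    as_coefficients(get_entry(ref, "Ala", "N15")), p)))
#' correct_tracks(list(tr))
#' @export
correct_tracks <- function(tracks, reference = load_reference(),
                           threshold = 2.0, threshold_B2 = Inf, p0 = 0.1) {
  stopifnot(is.list(tracks), inherits(reference, "rc_reference"))
  rows <- list()
  skipped <- list()
  for (tr in tracks) {
    stopifnot(inherits(tr, "peak_track"))
    entry <- tryCatch(
      get_entry(reference, tr$residue_type, tr$nucleus, variant = tr$variant),
      error = function(e) e)
    if (inherits(entry, "error")) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        residue_id = tr$residue_id, residue_type = tr$residue_type,
        nucleus = tr$nucleus, reason = conditionMessage(entry))
      next
    }
    fit <- fit_quadratic(tr$series, p0 = p0)
    obs <- fit$coefficients
    dB1 <- obs$B1 - entry$B1
    dB2 <- obs$B2 - entry$B2
    comb <- function(se_obs, se_ref) {
      v <- c(se_obs^2, se_ref^2)
      if (all(is.na(v))) NA_real_ else sqrt(sum(v, na.rm = TRUE))
    }
    z1 <- abs(dB1) / comb(obs$B1_err, entry$B1_err)
    z2 <- abs(dB2) / comb(obs$B2_err, entry$B2_err)
    rows[[length(rows) + 1L]] <- data.frame(
      residue_id = tr$residue_id, residue_type = tr$residue_type,
      nucleus = tr$nucleus, variant = entry$variant,
      obs_B1 = obs$B1, obs_B2 = obs$B2, ref_B1 = entry$B1, ref_B2 = entry$B2,
      dB1 = dB1, dB2 = dB2, z1 = z1, z2 = z2,
      flagged = isTRUE(z1 > threshold) || isTRUE(z2 > threshold_B2))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(residue_id = integer(), residue_type = character(),
               nucleus = character(), variant = character(),
               obs_B1 = numeric(), obs_B2 = numeric(), ref_B1 = numeric(),
               ref_B2 = numeric(), dB1 = numeric(), dB2 = numeric(),
               z1 = numeric(), z2 = numeric(), flagged = logical())
  out <- out[order(out$residue_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(residue_id = integer(), residue_type = character(),
               nucleus = character(), reason = character())
  attr(out, "threshold") <- threshold
  class(out) <- c("correction_results", "data.frame")
  out
}

#' @export
print.correction_results <- function(x, ...) {
  cat(sprintf("Random-coil correction: %d tracks, %d flagged (z1 > %g), %d skipped\n",
              nrow(x), sum(x$flagged), attr(x, "threshold"),
              nrow(attr(x, "skipped"))))
  print(as.data.frame(x), row.names = FALSE, digits = 4, ...)
  sk <- attr(x, "skipped")
  if (nrow(sk)) {
    cat("Skipped:\n")
    print(sk, row.names = FALSE)
  }
  invisible(x)
}

#' Pointwise random-coil residual of a track
#'
#' Observed shift minus the reference prediction at each measured pressure.
#' A purely random-coil residue leaves residuals at the noise level (plus a
#' constant offset if its \eqn{\delta_0} differs from the model-peptide
#' value: only the pressure response is corrected).
#'
#' @param track a [peak_track()].
#' @param entry the matching `rc_entry` (see [get_entry()]).
#' @param p0 reference pressure in MPa.
#' @return a [pressure_series()] of residuals (ppm) on the track's grid.
#' @export
residual_curve <- function(track, entry, p0 = 0.1) {
  stopifnot(inherits(track, "peak_track"), inherits(entry, "rc_entry"))
  if (entry$nucleus != track$nucleus) {
    stop("nucleus mismatch between track (", track$nucleus,
         ") and reference entry (", entry$nucleus, ")", call. = FALSE)
  }
  pred <- predict_shift(as_coefficients(entry, p0 = p0), track$series$pressures)
  pressure_series(track$series$pressures, track$series$shifts - pred,
                  nucleus = track$nucleus)
}

#' Read peak tracks from comma-delimited text
#'
#' Expects columns `residue_id,residue_type,nucleus,pressure_MPa,shift_ppm`;
#' one track per distinct (`residue_id`, `nucleus`) pair, points sorted by
#' pressure.  An optional `variant` column overrides the His/Pro reference
#' defaults.
#'
#' @param path csv file path.
#' @return a list of [peak_track()] objects ordered by residue_id.
#' @export
read_peak_tracks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("residue_id", "residue_type", "nucleus", "pressure_MPa", "shift_ppm")
  if (!all(need %in% names(df))) {
    stop("tracks file must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  key <- interaction(df$residue_id, df$nucleus, drop = TRUE)
  tracks <- lapply(split(df, key), function(d) {
    d <- d[order(d$pressure_MPa), ]
    v <- if ("variant" %in% names(d)) d$variant[1] else NULL
    if (!is.null(v) && (is.na(v) || !nzchar(v))) v <- NULL
    peak_track(d$residue_id[1], d$residue_type[1], d$nucleus[1],
               pressure_series(d$pressure_MPa, d$shift_ppm,
                               nucleus = d$nucleus[1]),
               variant = v)
  })
  tracks <- unname(tracks)
  tracks[order(vapply(tracks, `[[`, 0L, "residue_id"))]
}

#' Write peak tracks as comma-delimited text
#'
#' @param tracks list of [peak_track()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peak_tracks <- function(tracks, path) {
  df <- do.call(rbind, lapply(tracks, function(tr) {
    data.frame(residue_id = tr$residue_id, residue_type = tr$residue_type,
               nucleus = tr$nucleus,
               variant = if (is.null(tr$variant)) "" else tr$variant,
               pressure_MPa = tr$series$pressures,
               shift_ppm = tr$series$shifts)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write correction results
#'
#' Comma-delimited main table plus, for `format = "dcf"`, a structured
#' key-value report (one record per track).
#'
#' @param results a `correction_results` from [correct_tracks()].
#' @param path output path.
#' @param format `"csv"` or `"dcf"`.
#' @return `path`, invisibly.
#' @export
write_correction_results <- function(results, path, format = c("csv", "dcf")) {
  stopifnot(inherits(results, "correction_results"))
  format <- match.arg(format)
  df <- as.data.frame(results)
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  } else {
    m <- vapply(df, function(col) {
      if (is.numeric(col)) vapply(col, function(v)
        if (is.na(v)) NA_character_ else format(v, digits = 15), "")
      else as.character(col)
    }, character(nrow(df)))
    if (is.null(dim(m))) m <- matrix(m, nrow = nrow(df),
                                     dimnames = list(NULL, names(df)))
    write.dcf(m, path)
  }
  invisible(path)
}
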