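## Embedded reference library of random-coil amide pressure coefficients.
##
## The data are the printed per-residue tables of backbone 15N and amide 1H
## pressure responses of Ac-Gly-Gly-X-Ala-NH2 model peptides (0.1-200 MPa,
## 283 K, pH 6.7): delta0 at atmospheric pressure, first/second order
## pressure coefficients B1 (ppm/GPa) and B2 (ppm/GPa^2) with their fit
## standard deviations, and the one-bond 1J(HN) coupling where measured.

#' @importFrom stats setNames
NULL

.rc_residues <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly",
                  "His", "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser",
                  "Thr", "Trp", "Tyr", "Val")
.rc_variants <- c("standard", "pH4.0", "pH8.5", "cis", "trans")
.rc_nuclei   <- c("N15", "H1N")

#' Load the random-coil pressure-coefficient reference
#'
#' Reads the coefficient library bundled with the package (or a user-supplied
#' file in the same structured key-value format) and validates it: 22
#' \eqn{^{15}}N entries (His at pH 4.0 and pH 8.5, Pro as cis and trans
#' isomers) and 19 amide \eqn{^1}H entries (no Pro, His at pH 4.0 only);
#' every \eqn{B_1 > 0} and every \eqn{B_2 < 0}; \eqn{\delta_0} and
#' \eqn{^1J(HN)} inside the measured ranges.  Any violation is a hard error
#' naming the broken invariant, so a corrupted file can never be used
#' silently.
#'
#' @param path path to a reference file in DCF (one key-value record per
#'   entry) format.  Defaults to the file shipped with the package.
#' @return an object of class `rc_reference`: a data frame with columns
#'   `residue`, `variant`, `nucleus`, `delta0` (ppm), `B1` (ppm/GPa),
#'   `B1_err`, `B2` (ppm/GPa^2), `B2_err`, `oneJ_HN` (Hz; `NA` where not
#'   measured).
#' @seealso [get_entry()], [table_mean()], [write_reference()],
#'   [read_reference_csv()]
#' @examples
#' ref <- load_reference()
#' get_entry(ref, "Gly", "N15")$B1
#' @export
load_reference <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "random_coil_reference.dcf",
                        package = "hpcoil", mustWork = TRUE)
  }
  m <- read.dcf(path, fields = c("Residue", "Variant", "Nucleus", "Delta0",
                                 "B1", "B1Err", "B2", "B2Err", "OneJHN"))
  ref <- data.frame(
    residue = as.character(m[, "Residue"]),
    variant = as.character(m[, "Variant"]),
    nucleus = as.character(m[, "Nucleus"]),
    delta0  = as.numeric(m[, "Delta0"]),
    B1      = as.numeric(m[, "B1"]),
    B1_err  = as.numeric(m[, "B1Err"]),
    B2      = as.numeric(m[, "B2"]),
    B2_err  = as.numeric(m[, "B2Err"]),
    oneJ_HN = as.numeric(m[, "OneJHN"]),
    stringsAsFactors = FALSE
  )
  class(ref) <- c("rc_reference", "data.frame")
  validate_reference(ref)
  ref
}

#' Validate a reference library
#'
#' Checks every structural invariant of the coefficient tables; called
#' automatically by [load_reference()] and [read_reference_csv()].
#'
#' @param ref an `rc_reference` object (or data frame with its columns).
#' @return `ref`, invisibly, if valid; otherwise an error naming the first
#'   violated invariant.
#' @export
validate_reference <- function(ref) {
  fail <- function(what) {
    stop("reference library invalid: ", what, call. = FALSE)
  }
  needed <- c("residue", "variant", "nucleus", "delta0", "B1", "B1_err",
              "B2", "B2_err", "oneJ_HN")
  if (!all(needed %in% names(ref))) {
    fail(paste("missing columns:",
               paste(setdiff(needed, names(ref)), collapse = ", ")))
  }
  if (!all(ref$residue %in% .rc_residues)) {
    fail(paste("unknown residue code(s):",
               paste(unique(setdiff(ref$residue, .rc_residues)), collapse = ", ")))
  }
  if (!all(ref$variant %in% .rc_variants)) fail("unknown variant label")
  if (!all(ref$nucleus %in% .rc_nuclei)) fail("unknown nucleus label")
  if (anyDuplicated(ref[c("residue", "variant", "nucleus")])) {
    fail("duplicate residue/variant/nucleus entry")
  }

  n15 <- ref[ref$nucleus == "N15", ]
  h1n <- ref[ref$nucleus == "H1N", ]
  if (nrow(n15) != 22L) fail(sprintf("expected 22 N15 entries, found %d", nrow(n15)))
  if (nrow(h1n) != 19L) fail(sprintf("expected 19 H1N entries, found %d", nrow(h1n)))
  if (!setequal(n15$variant[n15$residue == "His"], c("pH4.0", "pH8.5"))) {
    fail("N15 His must appear exactly as pH4.0 and pH8.5")
  }
  if (!setequal(n15$variant[n15$residue == "Pro"], c("cis", "trans"))) {
    fail("N15 Pro must appear exactly as cis and trans")
  }
  if ("Pro" %in% h1n$residue) fail("H1N table must not contain Pro")
  if (!identical(h1n$variant[h1n$residue == "His"], "pH4.0")) {
    fail("H1N His must appear only at pH4.0")
  }

  if (anyNA(ref$delta0) || anyNA(ref$B1) || anyNA(ref$B2)) {
    fail("delta0, B1 and B2 must all be present")
  }
  if (any(ref$B1 <= 0)) fail("every B1 must be positive")
  if (any(ref$B2 >= 0)) fail("every B2 must be negative")
  j <- ref$oneJ_HN[!is.na(ref$oneJ_HN)]
  if (any(j < -99.5 | j > -92.7)) fail("oneJ_HN outside [-99.5, -92.7] Hz")
  d0n <- n15$delta0
  if (any(d0n < 109 | d0n > 136)) fail("N15 delta0 outside [109, 136] ppm")
  d0h <- h1n$delta0
  if (any(d0h < 8.0 | d0h > 8.6)) fail("H1N delta0 outside [8.0, 8.6] ppm")
  invisible(ref)
}

#' Look up one reference entry
#'
#' Returns the unique library row for a residue and nucleus.  When `variant`
#' is omitted, His defaults to its pH 4.0 form and Pro to the trans isomer
#' (the forms observable by 1H-detected HSQC and relevant to trans-dominant
#' proteins); both defaults can be overridden.  Combinations the tables do
#' not contain (e.g. Pro \eqn{^1}H, His pH 8.5 \eqn{^1}H) raise an explicit
#' "not in reference" error rather than returning anything.
#'
#' @param ref an `rc_reference`, e.g. from [load_reference()].
#' @param residue three-letter amino-acid code (e.g. `"Gly"`).
#' @param nucleus `"N15"` or `"H1N"`.
#' @param variant optional: one of `"standard"`, `"pH4.0"`, `"pH8.5"`,
#'   `"cis"`, `"trans"`.
#' @return a one-row `rc_reference` entry as a list with the library columns.
#' @examples
#' ref <- load_reference()
#' get_entry(ref, "His", "N15")$delta0  # pH 4.0 form by default
#' @export
get_entry <- function(ref, residue, nucleus = c("N15", "H1N"), variant = NULL) {
  stopifnot(inherits(ref, "rc_reference"))
  nucleus <- match.arg(nucleus)
  if (!is.character(residue) || length(residue) != 1L ||
      !(residue %in% .rc_residues)) {
    stop("unknown residue code: ", paste(residue, collapse = ", "), call. = FALSE)
  }
  if (is.null(variant)) {
    variant <- switch(residue, His = "pH4.0", Pro = "trans", "standard")
  } else {
    variant <- match.arg(variant, .rc_variants)
  }
  hit <- ref$residue == residue & ref$nucleus == nucleus & ref$variant == variant
  if (sum(hit) != 1L) {
    stop(sprintf("not in reference: %s/%s (variant %s)", residue, nucleus,
                 variant), call. = FALSE)
  }
  entry <- as.list(ref[hit, , drop = FALSE])
  class(entry) <- "rc_entry"
  entry
}

#' Column means of the reference tables
#'
#' Arithmetic mean of \eqn{\delta_0} (`order = 0`), \eqn{B_1} (`order = 1`)
#' or \eqn{B_2} (`order = 2`) over *all* entries of one nucleus -- 22 rows
#' for \eqn{^{15}}N (both His pH forms, both Pro isomers) and 19 for
#' \eqn{^1}H.  That membership convention reproduces the published mean
#' coefficients at two-decimal rounding.  No rounding is applied here.
#'
#' @inheritParams get_entry
#' @param order 0, 1 or 2, selecting the coefficient order.
#' @return the mean, with a `units` attribute (`"ppm"`, `"ppm/GPa"` or
#'   `"ppm/GPa^2"`).
#' @examples
#' round(table_mean(load_reference(), "N15", 1), 2)  # 2.91
#' @export
table_mean <- function(ref, nucleus = c("N15", "H1N"), order = 1) {
  stopifnot(inherits(ref, "rc_reference"))
  nucleus <- match.arg(nucleus)
  if (!order %in% 0:2) stop("order must be 0, 1 or 2", call. = FALSE)
  col <- c("delta0", "B1", "B2")[order + 1L]
  out <- mean(ref[[col]][ref$nucleus == nucleus])
  attr(out, "units") <- c("ppm", "ppm/GPa", "ppm/GPa^2")[order + 1L]
  out
}

#' Range of the stored one-bond couplings
#'
#' Max minus min of all \eqn{^1J(HN)} values in the library, in Hz (the
#' residue-dependent variation is close to 7 Hz).
#'
#' @inheritParams get_entry
#' @return the range in Hz (a positive number).
#' @export
oneJ_range <- function(ref) {
  stopifnot(inherits(ref, "rc_reference"))
  j <- ref$oneJ_HN[!is.na(ref$oneJ_HN)]
  max(j) - min(j)
}

## ---- import / export ------------------------------------------------------

.rc_csv_header <- c("residue", "variant", "nucleus", "delta0_ppm",
                    "B1_ppm_per_GPa", "B1_err", "B2_ppm_per_GPa2", "B2_err",
                    "oneJ_HN_Hz")

#' Export a reference library
#'
#' Writes the library either as comma-delimited text (header
#' `residue,variant,nucleus,delta0_ppm,B1_ppm_per_GPa,B1_err,
#' B2_ppm_per_GPa2,B2_err,oneJ_HN_Hz`), as the structured key-value (DCF)
#' format that [load_reference()] reads, or as JSON.  Numeric fields are
#' written at full precision so that export followed by import reproduces
#' every field exactly.
#'
#' @inheritParams get_entry
#' @param path output file path.
#' @param format `"csv"`, `"dcf"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_reference <- function(ref, path, format = c("csv", "dcf", "json")) {
  stopifnot(inherits(ref, "rc_reference"))
  format <- match.arg(format)
  df <- as.data.frame(ref)
  if (format == "csv") {
    out <- setNames(df, .rc_csv_header)
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  } else if (format == "dcf") {
    m <- vapply(df, function(col) {
      if (is.numeric(col)) {
        vapply(col, function(v) if (is.na(v)) NA_character_ else format(v, digits = 15), "")
      } else as.character(col)
    }, character(nrow(df)))
    colnames(m) <- c("Residue", "Variant", "Nucleus", "Delta0", "B1", "B1Err",
                     "B2", "B2Err", "OneJHN")
    write.dcf(m, path)
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", na = "null",
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Import a reference library from comma-delimited text
#'
#' Reads a file written by [write_reference(format = "csv")][write_reference]
#' and validates it like [load_reference()].
#'
#' @param path csv file path.
#' @return an `rc_reference`.
#' @export
read_reference_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), .rc_csv_header)) {
    stop("unexpected reference csv header; expected: ",
         paste(.rc_csv_header, collapse = ","), call. = FALSE)
  }
  names(df) <- c("residue", "variant", "nucleus", "delta0", "B1", "B1_err",
                 "B2", "B2_err", "oneJ_HN")
  for (col in c("delta0", "B1", "B1_err", "B2", "B2_err", "oneJ_HN")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  class(df) <- c("rc_reference", "data.frame")
  validate_reference(df)
  df
}

#' @export
print.rc_reference <- function(x, ...) {
  cat(sprintf("Random-coil pressure-coefficient reference: %d entries (%d N15, %d H1N)\n",
              nrow(x), sum(x$nucleus == "N15"), sum(x$nucleus == "H1N")))
  print(as.data.frame(x), row.names = FALSE, ...)
  invisible(x)
}

#' @export
print.rc_entry <- function(x, ...) {
  cat(sprintf("%s (%s) %s: delta0 = %s ppm, B1 = %s +/- %s ppm/GPa, B2 = %s +/- %s ppm/GPa^2",
              x$residue, x$variant, x$nucleus, format(x$delta0), format(x$B1),
              format(x$B1_err), format(x$B2), format(x$B2_err)))
  if (!is.na(x$oneJ_HN)) cat(sprintf(", 1J(HN) = %s Hz", format(x$oneJ_HN)))
  cat("\n")
  invisible(x)
}
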