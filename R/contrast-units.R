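#' Convert linear RMS contrast to decibels
#'
#' Contrast is expressed throughout the package in decibel units,
#' `dB = 20 * log10(c)`, where `c` is linear root-mean-square contrast.
#' Physical stimuli have `c` in (0, 1] and therefore non-positive dB values;
#' model-internal quantities (gains, weights) may exceed 0 dB.
#'
#' @param c Numeric vector of linear RMS contrasts, all strictly positive.
#' @return Numeric vector of contrasts in dB.
#' @seealso [db_to_rms()] for the inverse.
#' @export
#' @examples
#' rms_to_db(c(1, 0.1, 0.45))
rms_to_db <- function(c) {
  if (!is.numeric(c) || any(!is.finite(c)) || any(c <= 0)) {
    rlang::abort("`c` must be finite and strictly positive linear contrast.")
  }
  20 * log10(c)
}

#' Convert decibel contrast to linear RMS contrast
#'
#' @param x Numeric vector of contrasts in dB (finite).
#' @return Numeric vector of linear RMS contrasts, `10^(x/20)`.
#' @export
#' @examples
#' db_to_rms(c(0, -12, -36))
db_to_rms <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    rlang::abort("`x` must be finite dB contrast.")
  }
  10^(x / 20)
}

#' Convert an interocular contrast ratio to dB
#'
#' The balance-point axis used by the binocular combination task is the
#' interocular contrast ratio left/right expressed in dB,
#' `20 * log10(c_left / c_right)`. A value of 0 dB means the two eyes receive
#' equal contrast; at the fitted balance point a positive value means the
#' left eye required the higher contrast for the two eyes to contribute
#' equally (i.e. right-eye sensory dominance).
#'
#' @param r Numeric vector of contrast ratios (left/right), strictly positive.
#' @return Ratio in dB.
#' @seealso [db_to_ratio()], [ratio_to_log10()] for the raw log10 accessor.
#' @export
#' @examples
#' ratio_to_db(c(1, 4, 1 / 2))
ratio_to_db <- function(r) {
  if (!is.numeric(r) || any(!is.finite(r)) || any(r <= 0)) {
    rlang::abort("`r` must be a finite, strictly positive contrast ratio.")
  }
  20 * log10(r)
}

#' @rdname ratio_to_db
#' @param x Ratio in dB.
#' @export
db_to_ratio <- function(x) {
  10^(x / 20)
}

#' @rdname ratio_to_db
#' @export
ratio_to_log10 <- function(r) {
  if (!is.numeric(r) || any(!is.finite(r)) || any(r <= 0)) {
    rlang::abort("`r` must be a finite, strictly positive contrast ratio.")
  }
  log10(r)
}

#' Convert a log2 disparity threshold to arc seconds
#'
#' Stereoacuity is analysed on a log2 axis; `log2_to_arcsec()` maps back to
#' linear disparity in arc seconds, optionally rounding to the nearest
#' integer arc second (half away from zero) as printed in clinical tables.
#'
#' @param x Numeric vector, log2 of disparity in arc seconds.
#' @param rounded If `TRUE`, round to integer arc seconds.
#' @return Disparity in arc seconds.
#' @export
#' @examples
#' log2_to_arcsec(5.0, rounded = TRUE) # 32 arc sec
#' log2_to_arcsec(7.1, rounded = TRUE) # 137 arc sec
log2_to_arcsec <- function(x, rounded = FALSE) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    rlang::abort("`x` must be finite log2 arc seconds.")
  }
  out <- 2^x
  if (isTRUE(rounded)) {
    # round half away from zero (not banker's rounding)
    out <- sign(out) * floor(abs(out) + 0.5)
  }
  out
}

#' @rdname log2_to_arcsec
#' @param arcsec Disparity in arc seconds, strictly positive.
#' @export
arcsec_to_log2 <- function(arcsec) {
  if (!is.numeric(arcsec) || any(!is.finite(arcsec)) || any(arcsec <= 0)) {
    rlang::abort("`arcsec` must be finite and strictly positive.")
  }
  log2(arcsec)
}
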