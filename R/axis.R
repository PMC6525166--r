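#' Construct a wavenumber axis
#'
#' Builds the Raman-shift grid on which all spectra in a study live. The
#' default span (350--2300 cm^-1) matches a line-focus spectrograph operating
#' at 785 nm excitation; the default 2 cm^-1 step gives 976 channels.
#'
#' @param start First wavenumber (cm^-1).
#' @param stop Last wavenumber (cm^-1); must exceed `start`.
#' @param step Channel spacing (cm^-1); must be positive.
#'
#' @return A strictly increasing numeric vector of wavenumbers (cm^-1).
#' @examples
#' wn <- wavenumber_axis()
#' length(wn)
#' @export
wavenumber_axis <- function(start = 350, stop = 2300, step = 2) {
  stopifnot(is.numeric(start), is.numeric(stop), is.numeric(step))
  if (step <= 0) stop("`step` must be positive", call. = FALSE)
  if (stop <= start) stop("`stop` must exceed `start`", call. = FALSE)
  seq(start, stop, by = step)
}

#' Validate a wavenumber axis
#'
#' @param wavenumbers Numeric vector of wavenumbers.
#' @return The axis, invisibly, after checking it is finite and strictly
#'   increasing.
#' @keywords internal
validate_axis <- function(wavenumbers) {
  if (!is.numeric(wavenumbers) || length(wavenumbers) < 2) {
    stop("a wavenumber axis needs at least two numeric values", call. = FALSE)
  }
  if (any(!is.finite(wavenumbers))) {
    stop("wavenumber axis contains non-finite values", call. = FALSE)
  }
  if (any(diff(wavenumbers) <= 0)) {
    stop("wavenumber axis must be strictly increasing", call. = FALSE)
  }
  invisible(wavenumbers)
}

#' Default lateral positions along the laser line
#'
#' The line-focus geometry acquires many spatially separated spectra along a
#' single illumination line; the default is 220 positions spread over 1.8 mm
#' (about 8.18 um spacing).
#'
#' @param n Number of lateral positions.
#' @param length_mm Physical line length in mm.
#' @return Numeric vector of positions in mm, starting at 0.
#' @examples
#' head(line_positions())
#' @export
line_positions <- function(n = 220, length_mm = 1.8) {
  stopifnot(n >= 1, length_mm > 0)
  seq(0, length_mm, length.out = n)
}
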