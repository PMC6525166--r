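#' Detector-noise specification
#'
#' The generator's noise model is scaled-Poisson shot noise plus additive
#' Gaussian read noise, with an optional slowly varying baseline. With the
#' defaults (shot gain 1e4 counts at unit intensity, read sd 0.002) the
#' signal-to-noise ratio at a unit-height band is about 40 dB, typical of a
#' well-exposed CCD Raman spectrum.
#'
#' @param shot_gain Counts corresponding to unit intensity; Poisson counts
#'   are drawn at `lambda = intensity * shot_gain` and rescaled. `NULL`
#'   disables shot noise.
#' @param read_sd Standard deviation of additive Gaussian read noise, in
#'   intensity units; 0 disables it.
#' @param baseline_amp Amplitude of a slowly varying (half-period cosine)
#'   baseline in intensity units; 0 (default) disables it.
#' @return A `noise_spec` list.
#' @examples
#' noise_spec()
#' @export
noise_spec <- function(shot_gain = 1e4, read_sd = 2e-3, baseline_amp = 0) {
  if (!is.null(shot_gain) && (!is.finite(shot_gain) || shot_gain <= 0)) {
    stop("`shot_gain` must be positive or NULL", call. = FALSE)
  }
  if (read_sd < 0 || baseline_amp < 0) {
    stop("`read_sd` and `baseline_amp` must be >= 0", call. = FALSE)
  }
  structure(list(shot_gain = shot_gain, read_sd = read_sd,
                 baseline_amp = baseline_amp),
            class = "noise_spec")
}

#' Hyperspectral line-scan constructor
#'
#' @param intensities Array (time x position x channel).
#' @param times Acquisition times (min), strictly increasing.
#' @param positions Lateral positions (mm) along the laser line.
#' @param wavenumbers Wavenumber axis (cm^-1).
#' @param temperature Isothermal hold temperature (degC).
#' @return A `hyper_linescan` object.
#' @export
hyper_linescan <- function(intensities, times, positions, wavenumbers,
                           temperature = NA_real_) {
  stopifnot(is.array(intensities), length(dim(intensities)) == 3)
  validate_axis(wavenumbers)
  if (dim(intensities)[1] != length(times) ||
      dim(intensities)[2] != length(positions) ||
      dim(intensities)[3] != length(wavenumbers)) {
    stop("intensity array dimensions must match times x positions x wavenumbers",
         call. = FALSE)
  }
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(intensities))) {
    stop("intensities must be finite", call. = FALSE)
  }
  structure(list(intensities = intensities, times = as.numeric(times),
                 positions = as.numeric(positions),
                 wavenumbers = as.numeric(wavenumbers),
                 temperature = temperature),
            class = "hyper_linescan")
}

#' @export
print.hyper_linescan <- function(x, ...) {
  d <- dim(x$intensities)
  cat("<hyper_linescan> ", d[1], " times x ", d[2], " positions x ", d[3],
      " channels", sep = "")
  if (is.finite(x$temperature)) cat(" @ ", x$temperature, " degC", sep = "")
  cat("\n")
  invisible(x)
}

#' Tidy a line scan into a long tibble
#'
#' Large: one row per (time, position, channel). Useful for plotting subsets.
#'
#' @param x A `hyper_linescan`.
#' @param ... Unused.
#' @return Tibble with `time`, `position`, `wavenumber`, `intensity`.
#' @export
tidy.hyper_linescan <- function(x, ...) {
  d <- dim(x$intensities)
  tibble::tibble(
    time = rep(x$times, times = d[2] * d[3]),
    position = rep(rep(x$positions, each = d[1]), times = d[3]),
    wavenumber = rep(x$wavenumbers, each = d[1] * d[2]),
    intensity = as.vector(x$intensities)
  )
}

#' Synthesize a hyperspectral line scan from a concentration field
#'
#' Applies the bilinear model `I(t, x, nu) = gain * sum_j C(t, x, j) S_j(nu)`
#' and then the detector-noise model of [noise_spec()]. The draw is fully
#' reproducible: the same seed, field, library and noise spec give a
#' bit-identical cube, and the global RNG state is left untouched.
#'
#' @param field A `conc_field` (ground-truth fractions).
#' @param library A `spectral_library` whose components match the field's
#'   (all rows must be known).
#' @param noise A [noise_spec()]; use `noise_spec(NULL, 0)` for a noiseless
#'   cube.
#' @param seed Integer seed for the noise draw.
#' @param gain Global intensity gain applied to the clean signal.
#' @param temperature Stored in the scan metadata (degC).
#' @return A `hyper_linescan`.
#' @examples
#' sch <- kinetic_scheme(c("A", "B"), rates = 0.1)
#' fld <- simulate_kinetics(sch, 0:10, line_positions(4))
#' lib <- make_component_spectra(
#'   list(A = band_table(800, 12, 1), B = band_table(1200, 12, 1)),
#'   wavenumber_axis(600, 1400, 4)
#' )
#' scan <- synthesize_linescan(fld, lib, seed = 1)
#' @export
synthesize_linescan <- function(field, library, noise = noise_spec(), seed = 1,
                                gain = 1, temperature = NA_real_) {
  stopifnot(inherits(field, "conc_field"), inherits(library, "spectral_library"),
            inherits(noise, "noise_spec"))
  comps <- attr(field, "components")
  if (!identical(comps, library$labels)) {
    stop("component mismatch between field (", paste(comps, collapse = ", "),
         ") and library (", paste(library$labels, collapse = ", "), ")",
         call. = FALSE)
  }
  if (any(!library$known)) {
    stop("synthesis needs a fully known library", call. = FALSE)
  }
  d <- dim(field)
  n_chan <- ncol(library$spectra)
  # unfold (time*position) x component, mix, refold
  cmat <- matrix(as.vector(unclass(field)), nrow = d[1] * d[2], ncol = d[3])
  clean <- gain * (cmat %*% library$spectra)

  if (noise$baseline_amp > 0) {
    bl <- noise$baseline_amp *
      (0.5 + 0.5 * cos(pi * seq(0, 1, length.out = n_chan)))
    clean <- sweep(clean, 2, bl, "+")
  }

  out <- clean
  withr::with_seed(as.integer(seed), {
    if (!is.null(noise$shot_gain)) {
      lam <- pmax(clean, 0) * noise$shot_gain
      out <- matrix(stats::rpois(length(lam), lam), nrow = nrow(lam)) /
        noise$shot_gain
    }
    if (noise$read_sd > 0) {
      out <- out + matrix(stats::rnorm(length(out), sd = noise$read_sd),
                          nrow = nrow(out))
    }
  })

  cube <- array(out, dim = c(d[1], d[2], n_chan))
  hyper_linescan(cube, attr(field, "times"), attr(field, "positions"),
                 library$wavenumbers, temperature = temperature)
}
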