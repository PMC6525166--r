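#' Per-position signal-to-noise ratio at one time point
#'
#' The line-focus geometry yields hundreds of spectra per time point, of
#' uneven quality (particle edges, glass, defects). Profile resolution uses
#' only the single lateral point with the best spectrum, ranked by
#' SNR = (peak signal in a band window) / (robust noise estimate from a
#' signal-free window). The noise estimate is the scaled median absolute
#' deviation of first differences in the noise window, which is insensitive
#' to flat offsets and slow baselines.
#'
#' @param scan A `hyper_linescan`.
#' @param t Time index (1-based).
#' @param signal_window Wavenumber range (cm^-1) scanned for the peak signal;
#'   default: all but the top decile of the axis.
#' @param noise_window Signal-free wavenumber range used for the noise
#'   estimate; default: the top decile of the axis. Must not overlap
#'   `signal_window`.
#' @return Numeric vector of finite, non-negative SNR values, one per
#'   position (zero where there is no signal).
#' @examples
#' sim <- simulate_scenario(default_scenario("TP4"), seed = 42)
#' snr <- snr_per_position(sim$scan, t = 1)
#' which.max(snr)
#' @export
snr_per_position <- function(scan, t, signal_window = NULL, noise_window = NULL) {
  stopifnot(inherits(scan, "hyper_linescan"))
  if (length(t) != 1 || t < 1 || t > length(scan$times)) {
    stop("invalid time index", call. = FALSE)
  }
  w <- scan$wavenumbers
  split_at <- min(w) + 0.9 * (max(w) - min(w))
  if (is.null(signal_window)) signal_window <- c(min(w), split_at)
  if (is.null(noise_window)) noise_window <- c(split_at, max(w))
  if (max(min(signal_window), min(noise_window)) <
      min(max(signal_window), max(noise_window))) {
    stop("signal and noise windows overlap", call. = FALSE)
  }
  sig_idx <- which(w >= min(signal_window) & w <= max(signal_window))
  noi_idx <- which(w >= min(noise_window) & w <= max(noise_window))
  if (length(sig_idx) == 0) stop("signal window contains no channels", call. = FALSE)
  if (length(noi_idx) < 3) stop("noise window needs at least 3 channels", call. = FALSE)

  spectra <- scan$intensities[t, , , drop = FALSE]
  dim(spectra) <- dim(scan$intensities)[2:3]
  signal <- apply(spectra[, sig_idx, drop = FALSE], 1, max)
  noise <- apply(spectra[, noi_idx, drop = FALSE], 1, function(s) {
    stats::mad(diff(s)) / sqrt(2)
  })
  snr <- ifelse(signal <= 0, 0, signal / pmax(noise, .Machine$double.eps))
  pmax(snr, 0)
}

#' Select the highest-SNR lateral position
#'
#' @param snr Numeric vector of per-position SNR values.
#' @return 1-based index of the maximum; ties are broken toward the lowest
#'   index.
#' @examples
#' select_best_position(c(1, 3, 2))
#' select_best_position(c(2, 2))
#' @export
select_best_position <- function(snr) {
  if (length(snr) == 0) stop("empty SNR vector", call. = FALSE)
  if (all(is.na(snr))) stop("SNR vector is all-NaN", call. = FALSE)
  which.max(snr)
}

#' Extract the analysis trace at one lateral position
#'
#' @param scan A `hyper_linescan`.
#' @param position 1-based position index.
#' @return Matrix (times x channels): the M_line slice used for curve
#'   resolution.
#' @export
extract_trace <- function(scan, position) {
  stopifnot(inherits(scan, "hyper_linescan"))
  if (position < 1 || position > length(scan$positions)) {
    stop("invalid position index", call. = FALSE)
  }
  tr <- scan$intensities[, position, , drop = FALSE]
  dim(tr) <- dim(scan$intensities)[c(1, 3)]
  tr
}

#' Stable-form residual map
#'
#' Subtracts the best non-negative combination of the stable-form spectra
#' from every spectrum of the scan and maps the size of what is left. The
#' residual isolates the dynamics of species *not* in the stable library —
#' the metastable intermediates — which rise and fall while the stable forms
#' dominate at the start and end of a dehydration run.
#'
#' Each spectrum `d` is fitted by NNLS against the stable library `A`
#' (simultaneous fit of all stable forms); the residual spectrum is
#' `r = d - A x_hat` and the residual intensity is `||r||` (Euclidean norm)
#' or, optionally, the integrated absolute intensity `sum |r|`.
#'
#' @param scan A `hyper_linescan`.
#' @param stable A `spectral_library` of known (stable) forms on the scan's
#'   axis.
#' @param measure `"norm"` (default) or `"integral"`.
#' @param keep_spectra Keep the full residual spectra array (time x position
#'   x channel)? Default `TRUE`.
#' @return A `residual_map`: list with `intensity` (times x positions
#'   matrix), optional `spectra` array, and axis metadata.
#' @examples
#' sim <- simulate_scenario(default_scenario("TP4"), seed = 42, noise = FALSE)
#' stable <- subset_library(sim$library, sim$scenario$stable)
#' small <- sim$scan
#' rm <- residual_map(
#'   hyper_linescan(small$intensities[, 1:4, , drop = FALSE], small$times,
#'                  small$positions[1:4], small$wavenumbers),
#'   stable
#' )
#' @export
residual_map <- function(scan, stable, measure = c("norm", "integral"),
                         keep_spectra = TRUE) {
  stopifnot(inherits(scan, "hyper_linescan"), inherits(stable, "spectral_library"))
  measure <- match.arg(measure)
  if (nrow(stable$spectra) == 0) stop("stable library is empty", call. = FALSE)
  if (any(!stable$known)) {
    stop("stable library must contain only known rows", call. = FALSE)
  }
  if (!isTRUE(all.equal(scan$wavenumbers, stable$wavenumbers))) {
    stop("scan and stable library are on different wavenumber axes", call. = FALSE)
  }
  A <- t(stable$spectra)
  d <- dim(scan$intensities)
  intensity <- matrix(0, d[1], d[2])
  spectra <- if (keep_spectra) array(0, dim = d) else NULL
  for (ti in seq_len(d[1])) {
    for (xi in seq_len(d[2])) {
      b <- scan$intensities[ti, xi, ]
      r <- if (all(b == 0)) b else b - as.vector(A %*% nnls_solve(A, b))
      intensity[ti, xi] <- if (measure == "norm") sqrt(sum(r^2)) else sum(abs(r))
      if (keep_spectra) spectra[ti, xi, ] <- r
    }
  }
  structure(list(intensity = intensity, spectra = spectra,
                 times = scan$times, positions = scan$positions,
                 wavenumbers = scan$wavenumbers, measure = measure),
            class = "residual_map")
}

#' @export
print.residual_map <- function(x, ...) {
  cat("<residual_map> ", nrow(x$intensity), " times x ", ncol(x$intensity),
      " positions (", x$measure, ")\n", sep = "")
  invisible(x)
}

#' Tidy a residual map
#'
#' @param x A `residual_map`.
#' @param ... Unused.
#' @return Tibble with `time`, `position`, `residual`.
#' @export
tidy.residual_map <- function(x, ...) {
  tibble::tibble(
    time = rep(x$times, times = ncol(x$intensity)),
    position = rep(x$positions, each = nrow(x$intensity)),
    residual = as.vector(x$intensity)
  )
}
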