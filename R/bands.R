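#' Pseudo-Voigt line profile
#'
#' Unit-height pseudo-Voigt band: a linear mix of a Gaussian and a Lorentzian
#' that share the same centre and full width at half maximum, the standard
#' approximation for Raman band shapes.
#'
#' @param x Wavenumbers (cm^-1) at which to evaluate.
#' @param center Band centre (cm^-1).
#' @param fwhm Full width at half maximum (cm^-1), > 0.
#' @param shape Lorentzian fraction in \[0, 1\]; 0 is pure Gaussian, 1 pure
#'   Lorentzian.
#' @return Numeric vector of intensities with maximum 1 at `center`.
#' @examples
#' pseudo_voigt(1680:1700, center = 1690, fwhm = 10, shape = 0.3)
#' @export
pseudo_voigt <- function(x, center, fwhm, shape = 0) {
  stopifnot(fwhm > 0, shape >= 0, shape <= 1)
  u <- (x - center) / fwhm
  g <- exp(-4 * log(2) * u^2)
  l <- 1 / (1 + 4 * u^2)
  (1 - shape) * g + shape * l
}

#' Build a band table
#'
#' A band table is a tibble with one row per Raman band of a solid-state
#' form: centre (cm^-1), FWHM (cm^-1), amplitude (arbitrary intensity) and a
#' pseudo-Voigt shape fraction.
#'
#' @param center,fwhm,amplitude,shape Numeric vectors, recycled to a common
#'   length. `shape` is the Lorentzian fraction (default 0 = Gaussian).
#' @return A tibble with columns `center`, `fwhm`, `amplitude`, `shape`.
#' @examples
#' band_table(center = c(555, 1660), fwhm = 10, amplitude = c(0.7, 1))
#' @export
band_table <- function(center = numeric(), fwhm = numeric(),
                       amplitude = numeric(), shape = 0) {
  tb <- tibble::tibble(
    center = as.numeric(center),
    fwhm = as.numeric(fwhm),
    amplitude = as.numeric(amplitude),
    shape = as.numeric(shape)
  )
  validate_band_table(tb)
  tb
}

validate_band_table <- function(tb, label = NULL, wavenumbers = NULL) {
  who <- if (is.null(label)) "band table" else paste0("band table for '", label, "'")
  need <- c("center", "fwhm", "amplitude", "shape")
  if (!all(need %in% names(tb))) {
    stop(who, " must have columns center, fwhm, amplitude, shape", call. = FALSE)
  }
  if (nrow(tb) == 0) return(invisible(tb))
  if (any(tb$fwhm <= 0)) stop(who, ": all band widths must be > 0", call. = FALSE)
  if (any(tb$amplitude < 0)) stop(who, ": band amplitudes must be >= 0", call. = FALSE)
  if (any(tb$shape < 0 | tb$shape > 1)) {
    stop(who, ": shape (Lorentzian fraction) must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(wavenumbers)) {
    out <- tb$center < min(wavenumbers) | tb$center > max(wavenumbers)
    if (any(out)) {
      stop(who, ": band at ", paste(tb$center[out], collapse = ", "),
           " cm^-1 lies outside the wavenumber axis (",
           min(wavenumbers), "-", max(wavenumbers), " cm^-1)", call. = FALSE)
    }
  }
  invisible(tb)
}

#' Synthesize a spectral library from band tables
#'
#' Renders one component spectrum per band table by summing pseudo-Voigt
#' bands on a shared wavenumber axis, then normalizing each spectrum to unit
#' maximum. All spectra are marked as "known" (reference) forms; use
#' [mark_unknown()] to blank the rows that a curve-resolution run is meant to
#' recover.
#'
#' @param band_tables Named list of band tables (see [band_table()]), one per
#'   component; names become component labels.
#' @param wavenumbers Wavenumber axis from [wavenumber_axis()].
#' @return A `spectral_library` object (components x channels intensity
#'   matrix, labels, known-mask, wavenumbers).
#' @examples
#' lib <- make_component_spectra(tp4_band_tables(), wavenumber_axis())
#' lib
#' @export
make_component_spectra <- function(band_tables, wavenumbers = wavenumber_axis()) {
  validate_axis(wavenumbers)
  if (!is.list(band_tables) || length(band_tables) == 0) {
    stop("`band_tables` must be a non-empty named list of band tables", call. = FALSE)
  }
  labels <- names(band_tables)
  if (is.null(labels) || any(labels == "")) {
    stop("every band table must be named after its component", call. = FALSE)
  }
  spectra <- matrix(0, nrow = length(band_tables), ncol = length(wavenumbers),
                    dimnames = list(labels, NULL))
  for (i in seq_along(band_tables)) {
    tb <- band_tables[[i]]
    validate_band_table(tb, label = labels[i], wavenumbers = wavenumbers)
    if (nrow(tb) == 0) next
    s <- rep(0, length(wavenumbers))
    for (b in seq_len(nrow(tb))) {
      s <- s + tb$amplitude[b] *
        pseudo_voigt(wavenumbers, tb$center[b], tb$fwhm[b], tb$shape[b])
    }
    if (max(s) > 0) s <- s / max(s)
    spectra[i, ] <- s
  }
  new_spectral_library(spectra, wavenumbers, known = rep(TRUE, length(labels)))
}

#' Spectral library constructor
#'
#' @param spectra Components x channels matrix with component row names.
#' @param wavenumbers Shared wavenumber axis.
#' @param known Logical per component: `TRUE` rows are fixed reference
#'   spectra, `FALSE` rows are unknowns to be resolved (their contents are
#'   ignored and stored as `NA`).
#' @return A `spectral_library`.
#' @keywords internal
new_spectral_library <- function(spectra, wavenumbers, known) {
  stopifnot(is.matrix(spectra), !is.null(rownames(spectra)))
  validate_axis(wavenumbers)
  if (ncol(spectra) != length(wavenumbers)) {
    stop("spectra matrix and wavenumber axis disagree on channel count", call. = FALSE)
  }
  known <- as.logical(known)
  stopifnot(length(known) == nrow(spectra))
  if (any(known) && any(!is.finite(spectra[known, , drop = FALSE]))) {
    stop("known library rows must be finite", call. = FALSE)
  }
  if (any(known) && any(spectra[known, , drop = FALSE] < 0)) {
    stop("known library rows must be non-negative", call. = FALSE)
  }
  spectra[!known, ] <- NA_real_
  structure(
    list(spectra = spectra, wavenumbers = wavenumbers,
         labels = rownames(spectra), known = known),
    class = "spectral_library"
  )
}

#' Mark library components as unknown
#'
#' Blanks the listed components (rows become `NA`) so MCR-ALS resolves them
#' while the remaining rows are held fixed — the partially known library used
#' when hunting for metastable intermediates with only the stable hydrate and
#' anhydrate on file.
#'
#' @param library A `spectral_library`.
#' @param unknown Character vector of component labels to blank.
#' @return The modified `spectral_library`.
#' @examples
#' lib <- make_component_spectra(tp4_band_tables(), wavenumber_axis())
#' mark_unknown(lib, c("TP MS1", "TP MS2"))
#' @export
mark_unknown <- function(library, unknown) {
  stopifnot(inherits(library, "spectral_library"))
  miss <- setdiff(unknown, library$labels)
  if (length(miss)) {
    stop("unknown component label(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  known <- library$known & !(library$labels %in% unknown)
  new_spectral_library(library$spectra, library$wavenumbers, known)
}

#' Subset a spectral library
#'
#' @param library A `spectral_library`.
#' @param labels Component labels to keep, in the order given.
#' @return A `spectral_library` with only those components.
#' @export
subset_library <- function(library, labels) {
  stopifnot(inherits(library, "spectral_library"))
  miss <- setdiff(labels, library$labels)
  if (length(miss)) {
    stop("unknown component label(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  idx <- match(labels, library$labels)
  new_spectral_library(library$spectra[idx, , drop = FALSE],
                       library$wavenumbers, library$known[idx])
}

#' @export
print.spectral_library <- function(x, ...) {
  cat("<spectral_library> ", nrow(x$spectra), " components x ",
      ncol(x$spectra), " channels (",
      min(x$wavenumbers), "-", max(x$wavenumbers), " cm^-1)\n", sep = "")
  flag <- ifelse(x$known, "known", "unknown")
  cat(paste0("  ", format(x$labels), "  [", flag, "]"), sep = "\n")
  invisible(x)
}

#' Tidy a spectral library into a long tibble
#'
#' @param x A `spectral_library`.
#' @param ... Unused.
#' @return Tibble with columns `component`, `known`, `wavenumber`,
#'   `intensity` (NA for unknown rows).
#' @export
tidy.spectral_library <- function(x, ...) {
  tibble::tibble(
    component = rep(x$labels, each = length(x$wavenumbers)),
    known = rep(x$known, each = length(x$wavenumbers)),
    wavenumber = rep(x$wavenumbers, times = length(x$labels)),
    intensity = as.vector(t(x$spectra))
  )
}
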