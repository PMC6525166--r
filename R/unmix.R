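#' Unmix a full line scan against a resolved library
#'
#' Fits every spectrum of the scan independently by NNLS against the resolved
#' component spectra, giving per-component concentration values over
#' (time, position) — the chemical concentration maps. With `closure = TRUE`
#' each pixel's coefficients are normalized to fractions summing to 1; pixels
#' whose total raw coefficient falls below `empty_floor_frac` times the
#' median total are flagged empty (background/glass) and their fractions set
#' to `NA`.
#'
#' @param scan A `hyper_linescan`.
#' @param library A fully known (resolved) `spectral_library` on the scan's
#'   axis.
#' @param closure Normalize each pixel to fractions (default `TRUE`).
#' @param empty_floor_frac Empty-pixel floor as a fraction of the median
#'   total coefficient (default 1e-3).
#' @return A `chemical_map`: `values` (time x position x component; fractions
#'   if `closure`, raw coefficients otherwise), `raw` (coefficients), `empty`
#'   (logical time x position), axes and labels.
#' @examples
#' sim <- simulate_scenario(default_scenario("TP4"), seed = 42, noise = FALSE)
#' sub <- hyper_linescan(sim$scan$intensities[, 1:5, , drop = FALSE],
#'                       sim$scan$times, sim$scan$positions[1:5],
#'                       sim$scan$wavenumbers)
#' cm <- unmix_scan(sub, sim$library)
#' @export
unmix_scan <- function(scan, library, closure = TRUE, empty_floor_frac = 1e-3) {
  stopifnot(inherits(scan, "hyper_linescan"), inherits(library, "spectral_library"))
  if (any(!library$known)) {
    stop("unmixing needs a fully resolved (known) library", call. = FALSE)
  }
  if (!isTRUE(all.equal(scan$wavenumbers, library$wavenumbers))) {
    stop("scan and library are on different wavenumber axes", call. = FALSE)
  }
  d <- dim(scan$intensities)
  k <- nrow(library$spectra)
  B <- matrix(scan$intensities, nrow = d[1] * d[2], ncol = d[3])
  coef <- solve_rows_nnls(t(library$spectra), B, nonneg = TRUE)
  colnames(coef) <- library$labels

  totals <- rowSums(coef)
  floor_val <- empty_floor_frac * stats::median(totals)
  empty <- totals < floor_val

  values <- coef
  if (closure) {
    values <- coef / ifelse(totals > 0, totals, 1)
    values[empty, ] <- NA_real_
  }

  structure(list(
    values = array(values, dim = c(d[1], d[2], k)),
    raw = array(coef, dim = c(d[1], d[2], k)),
    empty = matrix(empty, d[1], d[2]),
    closure = closure,
    times = scan$times, positions = scan$positions,
    components = library$labels
  ), class = "chemical_map")
}

#' @export
print.chemical_map <- function(x, ...) {
  d <- dim(x$values)
  cat("<chemical_map> ", d[1], " times x ", d[2], " positions x ", d[3],
      " components (", if (x$closure) "closed fractions" else "raw coefficients",
      "); ", sum(x$empty), " empty pixels\n", sep = "")
  invisible(x)
}

#' Tidy a chemical map
#'
#' @param x A `chemical_map`.
#' @param ... Unused.
#' @return Tibble with `time`, `position`, `component`, `value`, `empty`.
#' @export
tidy.chemical_map <- function(x, ...) {
  d <- dim(x$values)
  tibble::tibble(
    time = rep(x$times, times = d[2] * d[3]),
    position = rep(rep(x$positions, each = d[1]), times = d[3]),
    component = rep(x$components, each = d[1] * d[2]),
    value = as.vector(x$values),
    empty = rep(as.vector(x$empty), times = d[3])
  )
}

#' Per-time concentration profiles from a chemical map
#'
#' @param map A `chemical_map`.
#' @param from `"mean"` (default): mean over non-empty line positions per
#'   time; `"position"`: the profile at one lateral position.
#' @param position 1-based position index when `from = "position"`.
#' @return Tibble with `time`, `component`, `fraction`.
#' @export
concentration_profiles <- function(map, from = c("mean", "position"),
                                   position = NULL) {
  stopifnot(inherits(map, "chemical_map"))
  from <- match.arg(from)
  d <- dim(map$values)
  if (from == "position") {
    if (is.null(position) || position < 1 || position > d[2]) {
      stop("valid `position` index required", call. = FALSE)
    }
    prof <- map$values[, position, , drop = FALSE]
    dim(prof) <- d[c(1, 3)]
  } else {
    prof <- apply(map$values, c(1, 3), mean, na.rm = TRUE)
  }
  tibble::tibble(
    time = rep(map$times, times = d[3]),
    component = rep(map$components, each = d[1]),
    fraction = as.vector(prof)
  )
}

#' Metastable-only area-plot series
#'
#' The stacked area plots that track just the transient intermediates: the
#' full library (stable forms included) is used for the unmixing, so stable
#' contributions are accounted for, and only the metastable series are
#' emitted.
#'
#' @param map A `chemical_map` from a full-library [unmix_scan()], or a
#'   ground-truth `conc_field`.
#' @param metastable Character vector of metastable component labels (a
#'   subset of the map's components).
#' @return Tibble with `time`, `component`, `fraction` (per-time mean over
#'   the line), components restricted to `metastable`.
#' @export
metastable_area_plot <- function(map, metastable) {
  comps <- if (inherits(map, "conc_field")) attr(map, "components") else map$components
  miss <- setdiff(metastable, comps)
  if (length(miss)) {
    stop("unknown metastable label(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  prof <- if (inherits(map, "conc_field")) {
    d <- dim(map)
    tibble::tibble(
      time = rep(attr(map, "times"), times = d[3]),
      component = rep(comps, each = d[1]),
      fraction = as.vector(apply(unclass(map), c(1, 3), mean))
    )
  } else {
    concentration_profiles(map, from = "mean")
  }
  dplyr::filter(prof, .data$component %in% metastable)
}

#' Synthesize a multi-particle area scene
#'
#' Builds a 2-D Raman map cube: rectangular particle patches on empty glass,
#' each patch carrying a fixed composition over the library components.
#' Emulates a powder-mapping experiment where several particles of different
#' solid-state forms sit in the field of view.
#'
#' @param library A fully known `spectral_library`.
#' @param patches Tibble with columns `x0`, `x1`, `y0`, `y1` (um) and one
#'   composition column per component label (fractions, rows need not sum
#'   to 1).
#' @param extent_um Length-2 vector: map extents in um (x, y).
#' @param step_um Grid step in um.
#' @param noise A [noise_spec()].
#' @param seed Integer seed for the noise draw.
#' @return An `area_scan`: list with `intensities` (nx x ny x channel),
#'   `x_um`, `y_um`, `wavenumbers`, plus the ground-truth fraction array
#'   `truth` (nx x ny x component).
#' @export
simulate_area_scene <- function(library, patches, extent_um = c(1170, 2109),
                                step_um = 8, noise = noise_spec(), seed = 1) {
  stopifnot(inherits(library, "spectral_library"), all(library$known))
  nx <- floor(extent_um[1] / step_um) + 1
  ny <- floor(extent_um[2] / step_um) + 1
  x_um <- (seq_len(nx) - 1) * step_um
  y_um <- (seq_len(ny) - 1) * step_um
  k <- nrow(library$spectra)
  comp_cols <- intersect(library$labels, names(patches))
  if (length(comp_cols) == 0) {
    stop("`patches` has no composition columns matching the library labels",
         call. = FALSE)
  }
  frac <- array(0, dim = c(nx, ny, k))
  for (p in seq_len(nrow(patches))) {
    xi <- which(x_um >= patches$x0[p] & x_um <= patches$x1[p])
    yi <- which(y_um >= patches$y0[p] & y_um <= patches$y1[p])
    for (lab in comp_cols) {
      j <- match(lab, library$labels)
      frac[xi, yi, j] <- patches[[lab]][p]
    }
  }
  clean <- matrix(frac, nrow = nx * ny, ncol = k) %*% library$spectra
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
  structure(list(
    intensities = array(out, dim = c(nx, ny, ncol(library$spectra))),
    x_um = x_um, y_um = y_um, wavenumbers = library$wavenumbers,
    truth = frac, components = library$labels
  ), class = "area_scan")
}

#' Unmix a 2-D area map
#'
#' Per-pixel NNLS of an area-mapping cube against a resolved library, with
#' optional rectangular region-of-interest cropping.
#'
#' @param scene An `area_scan` (or a list with `intensities` nx x ny x
#'   channel, `x_um`, `y_um`, `wavenumbers`).
#' @param library A fully known `spectral_library` on the scene's axis.
#' @param closure Normalize pixels to fractions (default `FALSE`: raw
#'   coefficient maps).
#' @param roi Optional ROI `c(xmin, xmax, ymin, ymax)` in um.
#' @param empty_floor_frac Empty-pixel floor (see [unmix_scan()]).
#' @return An `area_map`: `values` (nx x ny x component), `empty`, `x_um`,
#'   `y_um`, `components`, `closure`.
#' @export
unmix_area_map <- function(scene, library, closure = FALSE, roi = NULL,
                           empty_floor_frac = 1e-3) {
  stopifnot(inherits(library, "spectral_library"))
  if (is.null(scene$x_um) || is.null(scene$y_um)) {
    stop("area scene is missing its grid metadata (x_um/y_um)", call. = FALSE)
  }
  if (any(!library$known)) {
    stop("unmixing needs a fully resolved (known) library", call. = FALSE)
  }
  if (!isTRUE(all.equal(scene$wavenumbers, library$wavenumbers))) {
    stop("scene and library are on different wavenumber axes", call. = FALSE)
  }
  x_um <- scene$x_um; y_um <- scene$y_um
  cube <- scene$intensities
  if (!is.null(roi)) {
    xi <- which(x_um >= roi[1] & x_um <= roi[2])
    yi <- which(y_um >= roi[3] & y_um <= roi[4])
    if (length(xi) == 0 || length(yi) == 0) stop("empty ROI", call. = FALSE)
    cube <- cube[xi, yi, , drop = FALSE]
    x_um <- x_um[xi]; y_um <- y_um[yi]
  }
  d <- dim(cube)
  k <- nrow(library$spectra)
  B <- matrix(cube, nrow = d[1] * d[2], ncol = d[3])
  coef <- solve_rows_nnls(t(library$spectra), B, nonneg = TRUE)
  totals <- rowSums(coef)
  empty <- totals < empty_floor_frac * stats::median(totals)
  values <- coef
  if (closure) {
    values <- coef / ifelse(totals > 0, totals, 1)
    values[empty, ] <- NA_real_
  }
  structure(list(
    values = array(values, dim = c(d[1], d[2], k)),
    empty = matrix(empty, d[1], d[2]),
    x_um = x_um, y_um = y_um,
    components = library$labels, closure = closure
  ), class = "area_map")
}

#' @export
print.area_map <- function(x, ...) {
  d <- dim(x$values)
  cat("<area_map> ", d[1], " x ", d[2], " pixels x ", d[3], " components\n",
      sep = "")
  invisible(x)
}

#' Tidy an area map
#'
#' @param x An `area_map`.
#' @param ... Unused.
#' @return Tibble with `x_um`, `y_um`, `component`, `value`, `empty`.
#' @export
tidy.area_map <- function(x, ...) {
  d <- dim(x$values)
  tibble::tibble(
    x_um = rep(x$x_um, times = d[2] * d[3]),
    y_um = rep(rep(x$y_um, each = d[1]), times = d[3]),
    component = rep(x$components, each = d[1] * d[2]),
    value = as.vector(x$values),
    empty = rep(as.vector(x$empty), times = d[3])
  )
}
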