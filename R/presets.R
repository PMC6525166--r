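#' Band tables for the four theophylline solid-state forms
#'
#' Emulates the four forms traversed during isothermal dehydration of
#' theophylline monohydrate: the monohydrate (TP MH), two metastable
#' intermediates (TP MS1, TP MS2) and the stable anhydrate (TP AH II). All
#' forms share a common ring/backbone band set; the discriminating features
#' follow the positions reported for this system: the anhydrate's carbonyl
#' doublet at 1690 and 1730 cm^-1, and MS1/MS2 differing near 1150, 1230 and
#' 1750 cm^-1 (imidazole/pyrimidine ring deformations).
#'
#' @return Named list of band tables in transformation order
#'   (MH, MS1, MS2, AH II).
#' @examples
#' names(tp4_band_tables())
#' @export
tp4_band_tables <- function() {
  backbone <- band_table(
    center    = c(440, 555, 665, 930, 1315, 1425, 1610),
    fwhm      = c(12, 10, 10, 12, 14, 16, 12),
    amplitude = c(0.25, 0.70, 0.60, 0.30, 0.50, 0.35, 0.55),
    shape     = 0.3
  )
  list(
    "TP MH" = dplyr::bind_rows(backbone, band_table(
      center    = c(595, 1190, 1660),
      fwhm      = c(10, 12, 14),
      amplitude = c(0.40, 0.30, 1.00),
      shape     = 0.3
    )),
    "TP MS1" = dplyr::bind_rows(backbone, band_table(
      center    = c(620, 1145, 1225, 1668),
      fwhm      = c(10, 10, 10, 14),
      amplitude = c(0.35, 0.50, 0.45, 1.00),
      shape     = 0.3
    )),
    "TP MS2" = dplyr::bind_rows(backbone, band_table(
      center    = c(635, 1160, 1242, 1672, 1750),
      fwhm      = c(10, 10, 10, 14, 12),
      amplitude = c(0.35, 0.50, 0.45, 1.00, 0.35),
      shape     = 0.3
    )),
    "TP AH II" = dplyr::bind_rows(backbone, band_table(
      center    = c(705, 1690, 1730),
      fwhm      = c(10, 12, 12),
      amplitude = c(0.40, 1.00, 0.80),
      shape     = 0.3
    ))
  )
}

#' Band tables for the four nitrofurantoin solid-state forms
#'
#' Emulates the dehydration cascade of nitrofurantoin monohydrate II: the two
#' monohydrates (NF MH II, NF MH I) differ in the C=N linkage band near
#' 1615 cm^-1; the two anhydrous polymorphs (NF AH alpha, NF AH beta) differ
#' across 950--1000, 1200--1300, 1310--1400 and 1550--1650 cm^-1.
#'
#' @return Named list of band tables in transformation order
#'   (MH II, MH I, AH alpha, AH beta).
#' @examples
#' names(nf4_band_tables())
#' @export
nf4_band_tables <- function() {
  backbone <- band_table(
    center    = c(460, 600, 880, 1050, 1160, 1470, 1710),
    fwhm      = c(12, 10, 12, 12, 12, 14, 14),
    amplitude = c(0.30, 0.40, 0.35, 0.40, 0.40, 0.50, 0.40),
    shape     = 0.3
  )
  list(
    "NF MH II" = dplyr::bind_rows(backbone, band_table(
      center    = c(975, 1250, 1340, 1615),
      fwhm      = c(12, 12, 12, 12),
      amplitude = c(0.30, 0.40, 0.50, 1.00),
      shape     = 0.3
    )),
    "NF MH I" = dplyr::bind_rows(backbone, band_table(
      center    = c(805, 975, 1250, 1340, 1627),
      fwhm      = c(10, 12, 12, 12, 12),
      amplitude = c(0.25, 0.30, 0.40, 0.50, 1.00),
      shape     = 0.3
    )),
    "NF AH alpha" = dplyr::bind_rows(backbone, band_table(
      center    = c(960, 1255, 1352, 1580),
      fwhm      = c(10, 12, 12, 12),
      amplitude = c(0.70, 0.60, 0.55, 0.90),
      shape     = 0.3
    )),
    "NF AH beta" = dplyr::bind_rows(backbone, band_table(
      center    = c(992, 1285, 1390, 1640),
      fwhm      = c(10, 12, 12, 12),
      amplitude = c(0.70, 0.60, 0.55, 0.90),
      shape     = 0.3
    ))
  )
}

#' Default dehydration scenarios
#'
#' A scenario bundles everything the synthetic generator needs to emulate one
#' isothermal line-focus experiment: the wavenumber axis, band tables, the
#' sequential kinetic scheme with defect heterogeneity, the time grid, the
#' line geometry, and the detector-noise settings. `"TP4"` emulates
#' theophylline monohydrate dehydrating at 50 degC over 90 min
#' (MH -> MS1 -> MS2 -> AH II); `"NF4"` emulates nitrofurantoin monohydrate II
#' at 120 degC (MH II -> MH I -> AH alpha -> AH beta).
#'
#' Stable forms (the first and last of the cascade) are flagged so that the
#' residual-map and MCR stages know which library rows are reference spectra.
#'
#' @param name `"TP4"` or `"NF4"`.
#' @return A `scenario` list: `name`, `axis`, `bands`, `scheme`, `defects`,
#'   `times`, `temperature`, `positions`, `noise`, `stable` (labels),
#'   `metastable` (labels).
#' @examples
#' sc <- default_scenario("TP4")
#' sc$scheme$components
#' @export
default_scenario <- function(name = c("TP4", "NF4")) {
  name <- match.arg(name)
  if (name == "TP4") {
    bands <- tp4_band_tables()
    scheme <- kinetic_scheme(
      components = names(bands),
      rates = c(0.08, 0.05, 0.03)
    )
    temperature <- 50
  } else {
    bands <- nf4_band_tables()
    scheme <- kinetic_scheme(
      components = names(bands),
      rates = c(0.10, 0.055, 0.035)
    )
    temperature <- 120
  }
  comps <- scheme$components
  structure(list(
    name = name,
    axis = list(start = 350, stop = 2300, step = 2),
    bands = bands,
    scheme = scheme,
    defects = tibble::tibble(
      start_mm = c(0.45, 1.20),
      end_mm = c(0.60, 1.35),
      multiplier = c(2.0, 1.6)
    ),
    times = seq(0, 90, by = 2),
    temperature = temperature,
    positions = list(n = 220, length_mm = 1.8),
    noise = noise_spec(),
    stable = comps[c(1, length(comps))],
    metastable = comps[-c(1, length(comps))]
  ), class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat("<scenario> ", x$name, ": ", paste(x$scheme$components, collapse = " -> "),
      "\n  ", length(x$times), " time points over ", max(x$times), " min at ",
      x$temperature, " degC; ", x$positions$n, " positions over ",
      x$positions$length_mm, " mm\n", sep = "")
  invisible(x)
}

#' Simulate a full scenario
#'
#' Runs the generator end to end: renders the component library from band
#' tables, integrates the kinetic scheme over the line, and synthesizes the
#' noisy hyperspectral cube. The ground truth (concentration field and
#' library) is returned alongside the scan so recovery can be scored.
#'
#' @param scenario A scenario from [default_scenario()] (or an equivalent
#'   list).
#' @param seed Integer seed controlling the detector noise.
#' @param noise Logical; `FALSE` generates a noiseless cube (the bilinear
#'   model exactly).
#' @return List with elements `scan` (a `hyper_linescan`), `truth_field`
#'   (`conc_field`), `library` (ground-truth `spectral_library`), and
#'   `scenario`.
#' @examples
#' sim <- simulate_scenario(default_scenario("TP4"), seed = 42)
#' dim(sim$scan$intensities)
#' @export
simulate_scenario <- function(scenario, seed = 42, noise = TRUE) {
  axis <- wavenumber_axis(scenario$axis$start, scenario$axis$stop, scenario$axis$step)
  lib <- make_component_spectra(scenario$bands, axis)
  positions <- line_positions(scenario$positions$n, scenario$positions$length_mm)
  mult <- defect_multipliers(positions, scenario$defects)
  field <- simulate_kinetics(scenario$scheme, scenario$times, positions,
                             multipliers = mult)
  nz <- if (isTRUE(noise)) scenario$noise else noise_spec(shot_gain = NULL, read_sd = 0)
  scan <- synthesize_linescan(field, lib, noise = nz, seed = seed,
                              temperature = scenario$temperature)
  list(scan = scan, truth_field = field, library = lib, scenario = scenario)
}
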