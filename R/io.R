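#' Write / read a single spectrum as two-column CSV
#'
#' @param wavenumbers,intensity Numeric vectors of equal length.
#' @param path File path.
#' @return `read_spectrum_csv` returns a tibble with `wavenumber`,
#'   `intensity`; the writer returns `path` invisibly.
#' @export
write_spectrum_csv <- function(wavenumbers, intensity, path) {
  stopifnot(length(wavenumbers) == length(intensity))
  utils::write.csv(data.frame(wavenumber = wavenumbers, intensity = intensity),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}

#' Write a spectral library to CSV
#'
#' Layout: a header row of component labels (first column `wavenumber`), a
#' mask row (`known`/`unknown`), then one row per channel. Unknown columns
#' hold `NA` — the rows MCR-ALS is asked to resolve.
#'
#' @param library A `spectral_library`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_library_csv <- function(library, path) {
  stopifnot(inherits(library, "spectral_library"))
  con <- file(path, "w")
  on.exit(close(con))
  esc <- function(x) paste0('"', x, '"')
  writeLines(paste(c(esc("wavenumber"), esc(library$labels)), collapse = ","), con)
  writeLines(paste(c(esc("mask"),
                     esc(ifelse(library$known, "known", "unknown"))),
                   collapse = ","), con)
  body <- cbind(library$wavenumbers, t(library$spectra))
  utils::write.table(body, con, sep = ",", col.names = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a spectral library from CSV
#'
#' @param path File written by [write_library_csv()] (or hand-built in the
#'   same layout).
#' @return A `spectral_library`.
#' @export
read_library_csv <- function(path) {
  header <- strsplit(readLines(path, n = 2), ",")
  labels <- gsub('^"|"$', "", header[[1]][-1])
  mask <- gsub('^"|"$', "", header[[2]][-1])
  if (!all(mask %in% c("known", "unknown"))) {
    stop("mask row must contain only 'known'/'unknown'", call. = FALSE)
  }
  body <- utils::read.csv(path, skip = 2, header = FALSE)
  wavenumbers <- body[[1]]
  spectra <- t(as.matrix(body[, -1, drop = FALSE]))
  rownames(spectra) <- labels
  known <- mask == "known"
  if (any(is.na(spectra[known, ]))) {
    stop("NaN cells are only permitted in unknown columns", call. = FALSE)
  }
  new_spectral_library(spectra, wavenumbers, known)
}

#' Export one time point of a scan as a positions x channels CSV
#'
#' @param scan A `hyper_linescan`.
#' @param t Time index.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
export_time_csv <- function(scan, t, path) {
  stopifnot(inherits(scan, "hyper_linescan"), t >= 1, t <= length(scan$times))
  m <- scan$intensities[t, , , drop = FALSE]
  dim(m) <- dim(scan$intensities)[2:3]
  utils::write.table(m, path, sep = ",", col.names = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a line-scan dataset archive
#'
#' A dataset archive is a directory of plain-text arrays: `times.csv`,
#' `positions.csv`, `wavenumbers.csv`, one `intensities_t<NNN>.csv` per time
#' point (rows = positions, columns = channels), optional ground truth
#' (`truth_C.csv` long format and `truth_S.csv` library layout), and a
#' `manifest.json` with shapes, seed and a config hash.
#'
#' @param scan A `hyper_linescan`.
#' @param dir Output directory (created if missing).
#' @param truth_field Optional ground-truth `conc_field`.
#' @param truth_library Optional ground-truth `spectral_library`.
#' @param config Optional list serialized into the manifest (hashed for
#'   provenance).
#' @param seed Seed recorded in the manifest.
#' @return `dir`, invisibly.
#' @export
write_linescan_archive <- function(scan, dir, truth_field = NULL,
                                   truth_library = NULL, config = NULL,
                                   seed = NA_integer_) {
  stopifnot(inherits(scan, "hyper_linescan"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory ", dir, call. = FALSE)
  w <- function(x, f) utils::write.table(x, file.path(dir, f), sep = ",",
                                         col.names = FALSE, row.names = FALSE)
  w(scan$times, "times.csv")
  w(scan$positions, "positions.csv")
  w(scan$wavenumbers, "wavenumbers.csv")
  for (t in seq_along(scan$times)) {
    export_time_csv(scan, t, file.path(dir, sprintf("intensities_t%03d.csv", t)))
  }
  if (!is.null(truth_field)) {
    utils::write.csv(tidy(truth_field), file.path(dir, "truth_C.csv"),
                     row.names = FALSE)
  }
  if (!is.null(truth_library)) {
    write_library_csv(truth_library, file.path(dir, "truth_S.csv"))
  }
  manifest <- list(
    n_times = length(scan$times), n_positions = length(scan$positions),
    n_channels = length(scan$wavenumbers),
    temperature = scan$temperature, seed = seed,
    config = config,
    config_hash = if (!is.null(config)) rlang::hash(config) else NULL
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a line-scan dataset archive
#'
#' @param dir Directory written by [write_linescan_archive()].
#' @return List with `scan` (`hyper_linescan`), `truth_field` (or `NULL`),
#'   `truth_library` (or `NULL`), `manifest`.
#' @export
read_linescan_archive <- function(dir) {
  r <- function(f) as.numeric(utils::read.table(file.path(dir, f), sep = ",")[[1]])
  times <- r("times.csv")
  positions <- r("positions.csv")
  wavenumbers <- r("wavenumbers.csv")
  cube <- array(0, dim = c(length(times), length(positions), length(wavenumbers)))
  for (t in seq_along(times)) {
    m <- as.matrix(utils::read.table(
      file.path(dir, sprintf("intensities_t%03d.csv", t)), sep = ","))
    cube[t, , ] <- m
  }
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  temp <- if (is.null(manifest$temperature)) NA_real_ else manifest$temperature
  scan <- hyper_linescan(cube, times, positions, wavenumbers, temperature = temp)

  truth_field <- NULL
  if (file.exists(file.path(dir, "truth_C.csv"))) {
    tc <- utils::read.csv(file.path(dir, "truth_C.csv"))
    comps <- unique(tc$component)
    arr <- array(tc$fraction,
                 dim = c(length(times), length(positions), length(comps)))
    truth_field <- new_conc_field(arr, times, positions, comps)
  }
  truth_library <- NULL
  if (file.exists(file.path(dir, "truth_S.csv"))) {
    truth_library <- read_library_csv(file.path(dir, "truth_S.csv"))
  }
  list(scan = scan, truth_field = truth_field, truth_library = truth_library,
       manifest = manifest)
}

#' Serialize / deserialize a scenario as JSON
#'
#' The JSON carries the axis, per-component band tables, the kinetic scheme,
#' defect intervals, time grid, geometry and noise settings — everything
#' needed to regenerate a dataset bit-identically under the same seed.
#'
#' @param scenario A `scenario` (see [default_scenario()]).
#' @param path File path.
#' @return `scenario_from_json` returns a `scenario`; the writer returns
#'   `path` invisibly.
#' @export
scenario_to_json <- function(scenario, path) {
  payload <- list(
    name = scenario$name,
    axis = scenario$axis,
    bands = lapply(scenario$bands, as.data.frame),
    scheme = list(components = scenario$scheme$components,
                  rates = scenario$scheme$rates,
                  induction = scenario$scheme$induction),
    defects = as.data.frame(scenario$defects),
    times = scenario$times,
    temperature = scenario$temperature,
    positions = scenario$positions,
    noise = unclass(scenario$noise),
    stable = scenario$stable,
    metastable = scenario$metastable
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname scenario_to_json
#' @export
scenario_from_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("axis", "bands", "scheme", "times", "positions", "noise")
  miss <- setdiff(need, names(p))
  if (length(miss)) {
    stop("scenario JSON is missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  scheme <- kinetic_scheme(p$scheme$components, p$scheme$rates,
                           if (is.null(p$scheme$induction))
                             rep(1, length(p$scheme$rates))
                           else p$scheme$induction)
  bands <- lapply(p$bands, function(b) {
    tb <- tibble::as_tibble(b)
    if (is.null(tb$shape)) tb$shape <- 0
    validate_band_table(tb)
    tb
  })
  ns <- p$noise
  structure(list(
    name = if (is.null(p$name)) "custom" else p$name,
    axis = p$axis,
    bands = bands,
    scheme = scheme,
    defects = if (is.null(p$defects)) NULL else tibble::as_tibble(p$defects),
    times = p$times,
    temperature = if (is.null(p$temperature)) NA_real_ else p$temperature,
    positions = p$positions,
    noise = noise_spec(shot_gain = ns$shot_gain,
                       read_sd = if (is.null(ns$read_sd)) 0 else ns$read_sd,
                       baseline_amp = if (is.null(ns$baseline_amp)) 0
                                      else ns$baseline_amp),
    stable = p$stable,
    metastable = p$metastable
  ), class = "scenario")
}
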