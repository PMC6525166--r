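#' Simulate a scenario and archive the dataset
#'
#' Generator stage of the pipeline: builds the dataset for a scenario and
#' writes the archive (cube, ground truth, resolved config and its hash) to
#' `out_dir`.
#'
#' @param scenario A `scenario` object, a preset name (`"TP4"`/`"NF4"`), or a
#'   path to a scenario JSON.
#' @param out_dir Output directory.
#' @param seed Integer seed for the noise draw.
#' @param noise Generate detector noise (default `TRUE`).
#' @param quiet Suppress progress messages.
#' @return Invisibly, the simulation list from [simulate_scenario()] with
#'   `$dir` added.
#' @export
run_simulate <- function(scenario = "TP4", out_dir, seed = 42, noise = TRUE,
                         quiet = FALSE) {
  scenario <- resolve_scenario(scenario)
  sim <- simulate_scenario(scenario, seed = seed, noise = noise)
  cfg_path <- file.path(out_dir, "scenario.json")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scenario_to_json(scenario, cfg_path)
  write_linescan_archive(
    sim$scan, out_dir,
    truth_field = sim$truth_field, truth_library = sim$library,
    config = jsonlite::read_json(cfg_path), seed = seed
  )
  if (!quiet) {
    message("simulated scenario ", scenario$name, ": ",
            length(sim$scan$times), " x ", length(sim$scan$positions), " x ",
            length(sim$scan$wavenumbers), " cube (seed ", seed, ") -> ", out_dir)
  }
  sim$dir <- out_dir
  invisible(sim)
}

resolve_scenario <- function(scenario) {
  if (inherits(scenario, "scenario")) return(scenario)
  if (is.character(scenario) && length(scenario) == 1) {
    if (scenario %in% c("TP4", "NF4")) return(default_scenario(scenario))
    if (file.exists(scenario)) return(scenario_from_json(scenario))
  }
  stop("`scenario` must be a scenario object, 'TP4', 'NF4', or a JSON path",
       call. = FALSE)
}

#' Resolve unknown spectra from an archived dataset
#'
#' Analysis stage: picks the highest-SNR lateral point, estimates the number
#' of components by lack of fit, and runs library-constrained MCR-ALS with
#' the stable-form spectra fixed. Writes the resolved library, concentration
#' profiles, LoF table and provenance JSON (plus figures) to `out_dir`.
#'
#' @param data A directory written by [run_simulate()], or the list it
#'   returns.
#' @param stable A `spectral_library` of stable forms, a path to a library
#'   CSV, or `NULL` to take the stable forms recorded in the archive's ground
#'   truth.
#' @param out_dir Output directory; `NULL` skips writing.
#' @param k_max Largest rank tried by [estimate_rank()].
#' @param tol,max_iter Passed to [mcr_als()].
#' @param snr_time Time index at which per-position SNR is ranked (default 1,
#'   the first acquisition, where the particle is intact).
#' @param signal_window,noise_window Passed to [snr_per_position()].
#' @param write_figures Save diagnostic PNGs (default `TRUE` when `out_dir`
#'   is given).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list: `fit` (`mcr_fit`), `rank` (`rank_selection`),
#'   `library` (the partially known input library), `resolved`
#'   (fully known `spectral_library`), `best_position`, `trace`.
#' @export
run_resolve <- function(data, stable = NULL, out_dir = NULL, k_max = 6,
                        tol = 1e-6, max_iter = 200, snr_time = 1,
                        signal_window = NULL, noise_window = NULL,
                        write_figures = !is.null(out_dir), quiet = FALSE) {
  ds <- if (is.character(data)) read_linescan_archive(data) else data
  scan <- ds$scan

  if (is.null(stable)) {
    lib_full <- if (!is.null(ds$truth_library)) ds$truth_library else ds$library
    stable_labels <- ds$manifest$config$stable %||% ds$scenario$stable
    if (is.null(lib_full) || is.null(stable_labels)) {
      stop("no stable library given and none recoverable from the archive",
           call. = FALSE)
    }
    stable <- subset_library(lib_full, unlist(stable_labels))
  } else if (is.character(stable)) {
    stable <- read_library_csv(stable)
  }

  snr <- snr_per_position(scan, snr_time, signal_window, noise_window)
  best <- select_best_position(snr)
  trace <- extract_trace(scan, best)

  rank <- estimate_rank(trace, k_max = k_max)
  n_unknown <- rank$k - nrow(stable$spectra)
  if (n_unknown < 0) {
    stop("rank selection (k = ", rank$k, ") is smaller than the stable library (",
         nrow(stable$spectra), " forms); nothing to resolve", call. = FALSE)
  }
  labels <- c(stable$labels, if (n_unknown > 0) paste0("resolved ", seq_len(n_unknown)))
  S0 <- rbind(stable$spectra,
              matrix(NA_real_, n_unknown, ncol(stable$spectra)))
  rownames(S0) <- labels
  # order components stable-first; unknown rows flagged for resolution
  lib <- new_spectral_library(S0, stable$wavenumbers,
                              known = c(rep(TRUE, nrow(stable$spectra)),
                                        rep(FALSE, n_unknown)))
  fit <- mcr_als(trace, lib, tol = tol, max_iter = max_iter)
  resolved <- resolved_library(fit)

  if (!quiet) {
    message("resolved ", n_unknown, " unknown component(s) at position ", best,
            ": LoF ", signif(fit$lof, 4), "% in ", fit$iterations,
            " iterations; averaged relative residual ",
            signif(fit$avg_rel_residual, 4), "%")
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_library_csv(resolved, file.path(out_dir, "resolved_library.csv"))
    conc <- tidy(fit, "concentrations")
    conc$time <- scan$times[conc$observation]
    utils::write.csv(conc, file.path(out_dir, "concentration_profiles.csv"),
                     row.names = FALSE)
    utils::write.csv(tidy(rank), file.path(out_dir, "lof_table.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(
      best_position = best, selected_k = rank$k,
      lof = fit$lof, avg_rel_residual = fit$avg_rel_residual,
      iterations = fit$iterations, converged = fit$converged,
      config_hash = ds$manifest$config_hash %||% NA,
      seed = ds$manifest$seed %||% NA
    ), file.path(out_dir, "resolve_provenance.json"), auto_unbox = TRUE,
    digits = NA)
    if (write_figures) {
      save_quiet(autoplot(fit, "concentrations"),
                 file.path(out_dir, "concentration_profiles.png"))
      save_quiet(autoplot(fit, "spectra"),
                 file.path(out_dir, "resolved_spectra.png"))
    }
  }

  invisible(list(fit = fit, rank = rank, library = lib, resolved = resolved,
                 best_position = best, trace = trace, snr = snr))
}

#' Map a full line scan with a resolved library
#'
#' Mapping stage: per-pixel NNLS over the whole line, per-component chemical
#' maps, line-mean concentration profiles, and the metastable-only stacked
#' area series. CSV twins are written for every figure.
#'
#' @param data A directory written by [run_simulate()], or the list it
#'   returns.
#' @param resolved A fully known `spectral_library` or a path to its CSV
#'   (e.g. from [run_resolve()]).
#' @param metastable Labels treated as metastable for the area series;
#'   default: every resolved component whose label is not in the archive's
#'   stable list (if known), else none.
#' @param out_dir Output directory; `NULL` skips writing.
#' @param closure Closure-normalize the map (default `TRUE`).
#' @param write_figures Save PNGs (default `TRUE` when `out_dir` is given).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list: `map` (`chemical_map`), `profiles` (tibble),
#'   `area_series` (tibble or `NULL`).
#' @export
run_map <- function(data, resolved, metastable = NULL, out_dir = NULL,
                    closure = TRUE, write_figures = !is.null(out_dir),
                    quiet = FALSE) {
  ds <- if (is.character(data)) read_linescan_archive(data) else data
  scan <- ds$scan
  if (is.character(resolved)) resolved <- read_library_csv(resolved)
  if (!inherits(resolved, "spectral_library")) {
    stop("`resolved` must be a spectral_library or a library CSV path",
         call. = FALSE)
  }

  map <- unmix_scan(scan, resolved, closure = closure)
  profiles <- concentration_profiles(map, from = "mean")
  if (is.null(metastable)) {
    stable_labels <- unlist(ds$manifest$config$stable %||% ds$scenario$stable)
    if (!is.null(stable_labels)) {
      metastable <- setdiff(resolved$labels, stable_labels)
    }
  }
  area_series <- if (length(metastable)) {
    metastable_area_plot(map, metastable)
  } else NULL

  if (!quiet) {
    message("mapped ", length(scan$times), " x ", length(scan$positions),
            " pixels against ", nrow(resolved$spectra), " components (",
            sum(map$empty), " empty)")
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tidy(map), file.path(out_dir, "chemical_map.csv"),
                     row.names = FALSE)
    utils::write.csv(profiles, file.path(out_dir, "line_profiles.csv"),
                     row.names = FALSE)
    if (!is.null(area_series)) {
      utils::write.csv(area_series, file.path(out_dir, "metastable_area.csv"),
                       row.names = FALSE)
    }
    if (write_figures) {
      save_quiet(autoplot(map), file.path(out_dir, "chemical_map.png"))
      if (!is.null(area_series)) {
        save_quiet(plot_area_series(area_series),
                   file.path(out_dir, "metastable_area.png"))
      }
    }
  }

  invisible(list(map = map, profiles = profiles, area_series = area_series))
}

#' Read a chemical-map CSV back into a tibble
#'
#' Round-trip companion of the CSV written by [run_map()].
#'
#' @param path CSV path.
#' @return Tibble with `time`, `position`, `component`, `value`, `empty`.
#' @export
read_chemical_map_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}

save_quiet <- function(plot, path, width = 7, height = 5) {
  suppressMessages(ggplot2::ggsave(path, plot, width = width, height = height,
                                   dpi = 120))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
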