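test_that("nnls_solve handles identity systems and clamps infeasible signs", {
  expect_equal(unname(nnls_solve(diag(2), c(0.2, 0.8))), c(0.2, 0.8))
  expect_equal(unname(nnls_solve(diag(2), c(-1, 2))), c(0, 2))
  A <- cbind(good = c(1, 1), bad = c(0, 0))
  expect_error(nnls_solve(A, c(1, 1)), "bad")
})

test_that("nnls_solve agrees with the active-set enumeration oracle", {
  withr::with_seed(99, {
    for (rep in 1:200) {
      A <- matrix(rnorm(18), 6, 3)
      b <- rnorm(6)
      got <- unname(nnls_solve(A, b))
      want <- nnls_oracle(A, b)
      expect_lt(max(abs(got - want)), 1e-8)
      # optimality sanity check: at least as good as clipped unconstrained LS
      ls_clip <- pmax(qr.solve(A, b), 0)
      expect_lte(sum((A %*% got - b)^2), sum((A %*% ls_clip - b)^2) + 1e-12)
    }
  })
})

test_that("a noiseless single-component scan unmixes to a pure map", {
  sch <- kinetic_scheme(c("A", "B"), rates = 0)
  fld <- simulate_kinetics(sch, times = 0:2, positions = 1:4)
  lib <- make_component_spectra(
    list(A = band_table(800, 20, 1), B = band_table(1200, 20, 1)),
    wavenumber_axis(600, 1400, 4))
  scan <- synthesize_linescan(fld, lib, noise = noise_spec(NULL, 0), seed = 1)
  cm <- unmix_scan(scan, lib)
  expect_true(all(abs(cm$values[, , 1] - 1) < 1e-10))
  expect_true(all(cm$values[, , 2] < 1e-10))
})

test_that("noiseless unmixing inverts the bilinear model to machine accuracy", {
  sim <- simulate_scenario(tiny_tp4(), seed = 1, noise = FALSE)
  cm <- unmix_scan(sim$scan, sim$library)
  expect_lt(max(abs(cm$values - unclass(sim$truth_field))), 1e-6)
})

test_that("masking non-discriminating channels barely degrades recovery", {
  sim <- simulate_scenario(tiny_tp4(), seed = 6, noise = TRUE)
  err_full <- {
    cm <- unmix_scan(sim$scan, sim$library)
    mean(abs(cm$values - unclass(sim$truth_field)), na.rm = TRUE)
  }
  # drop 1850-2300 1/cm: no preset band lies there
  keep <- sim$scan$wavenumbers < 1850
  sub_scan <- hyper_linescan(sim$scan$intensities[, , keep, drop = FALSE],
                             sim$scan$times, sim$scan$positions,
                             sim$scan$wavenumbers[keep])
  sub_lib <- ramanmcr:::new_spectral_library(
    sim$library$spectra[, keep], sim$scan$wavenumbers[keep],
    known = sim$library$known)
  err_masked <- {
    cm <- unmix_scan(sub_scan, sub_lib)
    mean(abs(cm$values - unclass(sim$truth_field)), na.rm = TRUE)
  }
  expect_lt(err_masked, 10 * err_full)
})

test_that("with closure off, coefficients scale linearly with global gain", {
  sch <- kinetic_scheme(c("A", "B"), rates = 0.1)
  fld <- simulate_kinetics(sch, times = seq(0, 20, 5), positions = 1:3)
  lib <- make_component_spectra(
    list(A = band_table(800, 20, 1), B = band_table(1200, 20, 1)),
    wavenumber_axis(600, 1400, 4))
  s1 <- synthesize_linescan(fld, lib, noise = noise_spec(NULL, 0), gain = 1)
  s3 <- synthesize_linescan(fld, lib, noise = noise_spec(NULL, 0), gain = 3)
  m1 <- unmix_scan(s1, lib, closure = FALSE)
  m3 <- unmix_scan(s3, lib, closure = FALSE)
  expect_equal(m3$raw, 3 * m1$raw, tolerance = 1e-8)
  # and closure removes the gain dependence
  c1 <- unmix_scan(s1, lib, closure = TRUE)
  c3 <- unmix_scan(s3, lib, closure = TRUE)
  expect_equal(c3$values, c1$values, tolerance = 1e-8)
})

test_that("unmixing is pixel-separable under position permutation", {
  sim <- simulate_scenario(tiny_tp4(), seed = 7, noise = TRUE)
  cm <- unmix_scan(sim$scan, sim$library)
  perm <- rev(seq_along(sim$scan$positions))
  pscan <- hyper_linescan(sim$scan$intensities[, perm, , drop = FALSE],
                          sim$scan$times, sim$scan$positions, sim$scan$wavenumbers)
  pcm <- unmix_scan(pscan, sim$library)
  expect_equal(pcm$values, cm$values[, perm, , drop = FALSE], tolerance = 1e-12)
})

test_that("metastable area series behave per the generator ground truth", {
  sim <- simulate_scenario(tiny_tp4(), seed = 1, noise = FALSE)
  cm <- unmix_scan(sim$scan, sim$library)
  meta <- sim$scenario$metastable
  series <- metastable_area_plot(cm, meta)
  expect_setequal(unique(series$component), meta)
  for (lab in meta) {
    expect_true(is_unimodal(series$fraction[series$component == lab], tol = 1e-8))
  }
  # closure before restriction: all four series sum to 1 at every time
  full <- concentration_profiles(cm, from = "mean")
  sums <- tapply(full$fraction, full$time, sum)
  expect_lt(max(abs(sums - 1)), 1e-8)
  expect_error(metastable_area_plot(cm, "never seen"), "never seen")

  # a run that never forms metastables has all-zero series
  sch0 <- kinetic_scheme(sim$scenario$scheme$components, rates = c(0, 0, 0))
  fld0 <- simulate_kinetics(sch0, times = 0:3, positions = 1:3)
  expect_true(all(metastable_area_plot(fld0, meta)$fraction == 0))
})

test_that("area scenes unmix patch by patch with correct grid arithmetic", {
  wn <- wavenumber_axis(600, 1400, 20)
  lib <- make_component_spectra(
    list(AH = band_table(800, 25, 1), MS = band_table(1200, 25, 1)), wn)
  patches <- tibble::tibble(
    x0 = c(50, 600), x1 = c(350, 900), y0 = c(100, 1100), y1 = c(500, 1700),
    AH = c(1, 0.9), MS = c(0, 0.1)
  )
  clean <- simulate_area_scene(lib, patches, extent_um = c(1170, 2109),
                               step_um = 8, noise = noise_spec(NULL, 0), seed = 11)
  expect_equal(dim(clean$intensities)[1:2],
               c(floor(1170 / 8) + 1, floor(2109 / 8) + 1))
  amc <- unmix_area_map(clean, lib, closure = FALSE)
  tdc <- tidy(amc)
  pure <- tdc[tdc$component == "MS" &
                tdc$x_um >= 50 & tdc$x_um <= 350 &
                tdc$y_um >= 100 & tdc$y_um <= 500, ]
  expect_lt(max(pure$value), 1e-10)  # MS absent from the pure-anhydrate patch

  scene <- simulate_area_scene(lib, patches, extent_um = c(1170, 2109),
                               step_um = 8, noise = noise_spec(), seed = 11)
  am <- unmix_area_map(scene, lib, closure = TRUE)
  td <- tidy(am)
  mixed <- td[td$component == "MS" & !td$empty &
                td$x_um >= 600 & td$x_um <= 900 & td$y_um >= 1100 & td$y_um <= 1700, ]
  expect_lt(abs(mean(mixed$value) - 0.1), 0.02)  # residual metastable found
  # glass background is flagged empty
  expect_true(am$empty[1, 1])

  roi <- unmix_area_map(scene, lib, roi = c(600, 900, 1100, 1700))
  expect_true(all(roi$x_um >= 600 & roi$x_um <= 900))
  scene_bad <- scene
  scene_bad$x_um <- NULL
  expect_error(unmix_area_map(scene_bad, lib), "grid metadata")
})
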