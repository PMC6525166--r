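zero_scan <- function(n_t = 2, n_x = 5, wn = wavenumber_axis(600, 1400, 4)) {
  hyper_linescan(array(0, dim = c(n_t, n_x, length(wn))),
                 times = seq_len(n_t) - 1, positions = seq_len(n_x), wn)
}

test_that("all-zero spectra give zero SNR everywhere", {
  scan <- zero_scan()
  snr <- snr_per_position(scan, 1, signal_window = c(600, 1200),
                          noise_window = c(1300, 1400))
  expect_equal(snr, rep(0, 5))
})

test_that("a noiseless band at one position maximizes SNR there", {
  wn <- wavenumber_axis(600, 1400, 4)
  cube <- array(0, dim = c(1, 5, length(wn)))
  withr::with_seed(1, {
    for (x in c(1, 2, 4, 5)) cube[1, x, ] <- abs(rnorm(length(wn), sd = 0.01))
  })
  cube[1, 3, ] <- pseudo_voigt(wn, 900, 20)
  scan <- hyper_linescan(cube, 0, 1:5, wn)
  snr <- snr_per_position(scan, 1, signal_window = c(600, 1200),
                          noise_window = c(1300, 1400))
  expect_equal(which.max(snr), 3)
})

test_that("with fixed additive noise, SNR ranking equals amplitude ranking", {
  wn <- wavenumber_axis(600, 1400, 4)
  amps <- c(0.5, 2, 1.2, 3, 0.8)
  cube <- array(0, dim = c(1, 5, length(wn)))
  withr::with_seed(42, {
    noise <- matrix(rnorm(5 * length(wn), sd = 0.01), 5)
  })
  for (x in 1:5) cube[1, x, ] <- amps[x] * pseudo_voigt(wn, 900, 20) + noise[x, ]
  scan <- hyper_linescan(cube, 0, 1:5, wn)
  snr <- snr_per_position(scan, 1, signal_window = c(600, 1200),
                          noise_window = c(1300, 1400))
  expect_equal(order(snr), order(amps))
})

test_that("overlapping windows and bad indices are rejected", {
  scan <- zero_scan()
  expect_error(snr_per_position(scan, 1, signal_window = c(600, 1350),
                                noise_window = c(1300, 1400)), "overlap")
  expect_error(snr_per_position(scan, 99), "time index")
})

test_that("select_best_position takes the argmax with lowest-index ties", {
  expect_equal(select_best_position(c(1, 3, 2)), 2)
  expect_equal(select_best_position(c(2, 2)), 1)
  expect_error(select_best_position(c(NA_real_, NA_real_)), "NaN")
  expect_error(select_best_position(numeric(0)), "empty")
})

test_that("best position on a synthetic scan equals the brute-force argmax", {
  sim <- simulate_scenario(tiny_tp4(), seed = 3)
  snr <- snr_per_position(sim$scan, 1)
  best <- select_best_position(snr)
  brute <- 1
  for (i in seq_along(snr)) if (snr[i] > snr[brute]) brute <- i
  expect_equal(best, brute)
})

test_that("residual intensity is zero for stable spectra and ||m|| for orthogonal additions", {
  wn <- wavenumber_axis(600, 1400, 4)
  stable <- make_component_spectra(
    list(S1 = band_table(800, 20, 1), S2 = band_table(1200, 20, 1)), wn)
  s1 <- stable$spectra["S1", ]
  # orthogonalize a third band against the stable span
  m0 <- pseudo_voigt(wn, 1000, 15)
  B <- t(stable$spectra)
  m <- m0 - B %*% solve(crossprod(B), crossprod(B, m0))
  cube <- array(0, dim = c(1, 3, length(wn)))
  cube[1, 1, ] <- s1
  cube[1, 2, ] <- s1 + m
  cube[1, 3, ] <- 0
  scan <- hyper_linescan(cube, 0, 1:3, wn)
  rm <- residual_map(scan, stable)
  expect_lt(rm$intensity[1, 1], 1e-10)
  expect_equal(rm$intensity[1, 2], sqrt(sum(m^2)), tolerance = 1e-6)
  expect_equal(rm$intensity[1, 3], 0)
  # residual spectrum of the orthogonal case is m itself
  expect_equal(rm$spectra[1, 2, ], as.vector(m), tolerance = 1e-6)
})

test_that("residual intensity is invariant to rescaling stable spectra", {
  wn <- wavenumber_axis(600, 1400, 4)
  stable <- make_component_spectra(
    list(S1 = band_table(800, 20, 1), S2 = band_table(1200, 20, 1)), wn)
  scaled <- stable
  scaled$spectra[1, ] <- 3.7 * scaled$spectra[1, ]
  scaled$spectra[2, ] <- 0.2 * scaled$spectra[2, ]
  cube <- array(0, dim = c(2, 2, length(wn)))
  withr::with_seed(5, {
    for (t in 1:2) for (x in 1:2) {
      cube[t, x, ] <- runif(1) * stable$spectra[1, ] +
        runif(1) * stable$spectra[2, ] + abs(rnorm(length(wn), sd = 0.02))
    }
  })
  scan <- hyper_linescan(cube, 0:1, 1:2, wn)
  r1 <- residual_map(scan, stable, keep_spectra = FALSE)
  r2 <- residual_map(scan, scaled, keep_spectra = FALSE)
  expect_equal(r1$intensity, r2$intensity, tolerance = 1e-8)
})

test_that("a noiseless stable-only scan leaves no residual", {
  sc <- tiny_tp4()
  # freeze the kinetics at the two stable forms only: jump straight MH -> AH
  sc$scheme <- kinetic_scheme(sc$scheme$components,
                              rates = c(0.1, 1e6, 1e6))
  sim <- simulate_scenario(sc, seed = 1, noise = FALSE)
  stable <- subset_library(sim$library, sc$stable)
  rm <- residual_map(sim$scan, stable, keep_spectra = FALSE)
  expect_lt(max(rm$intensity), 1e-6)
})

test_that("metastable transients make the residual trace rise and fall", {
  sim <- simulate_scenario(tiny_tp4(), seed = 1, noise = FALSE)
  stable <- subset_library(sim$library, sim$scenario$stable)
  rm <- residual_map(sim$scan, stable, keep_spectra = FALSE)
  for (x in c(1, 20, 40)) {
    prof <- rm$intensity[, x]
    expect_true(is_unimodal(prof, tol = 1e-9 * max(prof)))
    expect_gt(max(prof), 10 * prof[1])
  }
  other_axis <- make_component_spectra(tp4_band_tables(), wavenumber_axis(350, 2300, 2))
  expect_error(residual_map(sim$scan, subset_library(other_axis, "TP MH")),
               "axes")
})
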