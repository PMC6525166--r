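test_that("lack_of_fit evaluates its formula on known cases", {
  D <- matrix(c(1, 0, 0, 1), 2)
  expect_equal(lack_of_fit(D, D, diag(2)), 0)
  expect_equal(lack_of_fit(D, matrix(0, 2, 2), matrix(0, 2, 2)), 100)
  CS <- matrix(c(1, 0, 0, 0), 2, byrow = TRUE)
  expect_equal(lack_of_fit(D, CS, diag(2)), 100 * sqrt(1 / 2), tolerance = 1e-12)
  expect_error(lack_of_fit(matrix(0, 2, 2), D, diag(2)), "all-zero")
})

test_that("estimate_rank recovers exact low ranks and rejects degenerate input", {
  withr::with_seed(11, {
    D1 <- outer(runif(12), runif(30))
    r1 <- estimate_rank(D1, k_max = 5)
    expect_equal(r1$k, 1)
    expect_lt(r1$table$lof[1], 1e-6)

    D3 <- matrix(runif(36), 12, 3) %*% matrix(runif(90), 3, 30)
    r3 <- estimate_rank(D3, k_max = 6)
    expect_equal(r3$k, 3)
    expect_lt(r3$table$lof[3], 1e-8)
  })
  expect_error(estimate_rank(matrix(0, 3, 3), 2), "all-zero")
  expect_error(estimate_rank(diag(3), 9), "k_max")
})

test_that("initialize_unknowns returns known spectra untouched when nothing is unknown", {
  lib <- make_component_spectra(
    list(A = band_table(800, 20, 1), B = band_table(1200, 20, 1)),
    wavenumber_axis(600, 1400, 4))
  D <- matrix(runif(2 * length(lib$wavenumbers)), 2)
  expect_identical(initialize_unknowns(D, lib), lib$spectra)
})

test_that("a pure observation seeds its unknown component almost exactly", {
  wn <- wavenumber_axis(600, 1400, 4)
  lib3 <- make_component_spectra(
    list(A = band_table(800, 20, 1), B = band_table(1200, 20, 1),
         U = band_table(c(950, 1050), c(15, 18), c(1, 0.6))), wn)
  truth_u <- lib3$spectra["U", ]
  part <- mark_unknown(lib3, "U")
  C <- rbind(c(1, 0, 0), c(0.5, 0.5, 0), c(0.2, 0.3, 0.5), c(0, 0, 1))
  D <- C %*% lib3$spectra
  S0 <- initialize_unknowns(D, part)
  expect_gte(cos_sim(S0["U", ], truth_u), 0.999)
  expect_identical(S0["A", ], part$spectra["A", ])
  expect_error(initialize_unknowns(D[1, , drop = FALSE],
                                   mark_unknown(lib3, c("B", "U"))),
               "fewer observations")
})

test_that("initialization is invariant to observation order (as a set of spectra)", {
  wn <- wavenumber_axis(600, 1400, 8)
  lib <- make_component_spectra(
    list(A = band_table(800, 20, 1),
         U1 = band_table(950, 15, 1), U2 = band_table(1250, 15, 1)), wn)
  part <- mark_unknown(lib, c("U1", "U2"))
  withr::with_seed(7, {
    C <- cbind(runif(10, 0, 1), runif(10, 0, 1), runif(10, 0, 1))
  })
  D <- C %*% lib$spectra
  S0 <- initialize_unknowns(D, part)
  perm <- c(4, 9, 1, 7, 2, 10, 5, 3, 8, 6)
  S0p <- initialize_unknowns(D[perm, ], part)
  key <- function(S) unname(apply(S[!part$known, , drop = FALSE], 1, paste, collapse = ","))
  expect_setequal(key(S0p), key(S0))
})

test_that("with all components known, one constrained solve recovers C", {
  sim <- simulate_scenario(tiny_tp4(), seed = 1, noise = FALSE)
  best <- select_best_position(snr_per_position(sim$scan, 1))
  tr <- extract_trace(sim$scan, best)
  fit <- mcr_als(tr, sim$library)
  truthC <- sim$truth_field[, best, ]
  expect_lt(max(abs(fit$C - truthC)), 1e-6)
  expect_lt(fit$lof, 1e-6)
  expect_identical(fit$S, sim$library$spectra)
})

test_that("mcr_als honours its constraint invariants", {
  sim <- simulate_scenario(tiny_tp4(), seed = 2, noise = TRUE)
  best <- select_best_position(snr_per_position(sim$scan, 1))
  tr <- extract_trace(sim$scan, best)
  lib <- mark_unknown(sim$library, sim$scenario$metastable)
  fit <- suppressWarnings(mcr_als(tr, lib))
  # equality: known rows bit-identical
  for (lab in sim$scenario$stable) {
    expect_identical(fit$S[lab, ], lib$spectra[lab, ])
  }
  # closure and non-negativity
  expect_lt(max(abs(rowSums(fit$C) - 1)), 1e-9)
  expect_gte(min(fit$C), 0)
  expect_gte(min(fit$S), 0)
  # LoF decreases from initialization and the trace is recorded
  expect_lte(fit$lof, fit$lof_initial)
  expect_equal(length(fit$lof_trace), fit$iterations)
  # unimodality of the resolved (metastable) profiles
  for (j in which(!fit$known)) {
    expect_true(is_unimodal(fit$C[, j], tol = 1e-8))
  }
})

test_that("noiseless 2-known/2-unknown resolution recovers the hidden spectra", {
  sim <- simulate_scenario(tiny_tp4(), seed = 1, noise = FALSE)
  best <- select_best_position(snr_per_position(sim$scan, 1))
  lib <- mark_unknown(sim$library, sim$scenario$metastable)
  fit <- suppressWarnings(mcr_als(extract_trace(sim$scan, best), lib))
  asg <- assign_unknowns(fit, sim$library$spectra, sim$scenario$metastable)
  expect_true(all(asg$cosines >= 0.99))
  expect_lt(fit$avg_rel_residual, 0.1)
})

test_that("permuting observations permutes C identically", {
  sim <- simulate_scenario(tiny_tp4(), seed = 4, noise = TRUE)
  best <- select_best_position(snr_per_position(sim$scan, 1))
  tr <- extract_trace(sim$scan, best)
  lib <- mark_unknown(sim$library, sim$scenario$metastable)
  fit <- suppressWarnings(mcr_als(tr, lib))
  perm <- rev(seq_len(nrow(tr)))
  fit_p <- suppressWarnings(mcr_als(tr[perm, ], lib, time_order = perm))
  expect_equal(fit_p$C, fit$C[perm, ], tolerance = 1e-10)
  expect_equal(fit_p$S, fit$S, tolerance = 1e-10)
})

test_that("non-convergence is reported loudly, never silently", {
  sim <- simulate_scenario(tiny_tp4(), seed = 5, noise = TRUE)
  best <- select_best_position(snr_per_position(sim$scan, 1))
  lib <- mark_unknown(sim$library, sim$scenario$metastable)
  expect_warning(
    fit <- mcr_als(extract_trace(sim$scan, best), lib, max_iter = 2),
    "did not converge"
  )
  expect_false(fit$converged)
  expect_s3_class(glance(fit), "tbl_df")
  expect_false(glance(fit)$converged)
})

test_that("tidiers expose concentrations, spectra and the LoF trace", {
  sim <- simulate_scenario(tiny_tp4(), seed = 1, noise = FALSE)
  fit <- mcr_als(extract_trace(sim$scan, 10), sim$library)
  conc <- tidy(fit, "concentrations")
  expect_equal(nrow(conc), nrow(fit$C) * 4)
  spec <- tidy(fit, "spectra")
  expect_equal(nrow(spec), 4 * ncol(fit$S))
  expect_equal(tidy(fit, "lof")$lof, fit$lof_trace)
  g <- glance(fit)
  expect_equal(g$n_components, 4)
  expect_equal(g$lof, fit$lof)
  rl <- resolved_library(fit)
  expect_true(all(rl$known))
})
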