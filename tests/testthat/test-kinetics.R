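test_that("zero rates leave the field at the initial composition", {
  sch <- kinetic_scheme(c("A", "B", "C"), rates = c(0, 0))
  fld <- simulate_kinetics(sch, times = c(0, 10, 50), positions = c(0, 1))
  expect_true(all(fld[, , 1] == 1))
  expect_true(all(fld[, , 2:3] == 0))
})

test_that("the integrator matches the Bateman closed form on chains 2-4", {
  times <- seq(0, 80, by = 5)
  rate_sets <- list(0.07, c(0.1, 0.05), c(0.08, 0.05, 0.03))
  for (rates in rate_sets) {
    m <- length(rates) + 1
    sch <- kinetic_scheme(paste0("S", seq_len(m)), rates)
    fld <- simulate_kinetics(sch, times, positions = 0)
    got <- matrix(fld[, 1, ], ncol = m)
    expect_lt(max(abs(got - bateman_chain(rates, times))), 1e-8)
  }
})

test_that("a defect region converts by the first-order time scaling", {
  k <- 0.1
  t_half_fast <- log(2) / (2 * k)
  t_half_slow <- log(2) / k
  sch <- kinetic_scheme(c("A", "B"), rates = k)
  positions <- c(0.1, 0.9)
  mult <- defect_multipliers(positions,
    tibble::tibble(start_mm = 0.8, end_mm = 1.0, multiplier = 2))
  expect_equal(mult, c(1, 2))
  fld <- simulate_kinetics(sch, times = sort(c(t_half_fast, t_half_slow)),
                           positions = positions, multipliers = mult)
  expect_equal(fld[2, 1, 1], 0.5, tolerance = 1e-8)  # slow region at ln2/k
  expect_equal(fld[1, 2, 1], 0.5, tolerance = 1e-8)  # defect region at ln2/(2k)
})

test_that("closure is exact and fractions stay in [0, 1], defects and induction included", {
  sch <- kinetic_scheme(c("A", "B", "C", "D"), rates = c(0.08, 0.05, 0.03),
                        induction = c(1, 2, 1.5))
  positions <- line_positions(20, 1.8)
  mult <- defect_multipliers(positions,
    tibble::tibble(start_mm = 0.4, end_mm = 0.8, multiplier = 2.5))
  fld <- simulate_kinetics(sch, times = seq(0, 90, by = 3), positions, mult)
  sums <- apply(unclass(fld), c(1, 2), sum)
  expect_lt(max(abs(sums - 1)), 1e-9)
  expect_true(all(fld >= 0 & fld <= 1))
})

test_that("sequential kinetics give monotone ends and unimodal intermediates", {
  for (rates in list(c(0.1, 0.04), c(0.08, 0.05, 0.03), c(0.2, 0.1, 0.02))) {
    m <- length(rates) + 1
    sch <- kinetic_scheme(paste0("S", seq_len(m)), rates)
    fld <- simulate_kinetics(sch, times = seq(0, 120, by = 2),
                             positions = c(0, 1), multipliers = c(1, 1.7))
    for (x in 1:2) {
      expect_true(all(diff(fld[, x, 1]) <= 1e-12))       # first: non-increasing
      expect_true(all(diff(fld[, x, m]) >= -1e-12))      # last: non-decreasing
      for (j in seq(2, m - 1)) {
        prof <- fld[, x, j]
        d <- diff(prof)
        signs <- sign(d[abs(d) > 1e-12])
        # exactly one sign change of the discrete derivative
        expect_equal(sum(diff(signs) != 0), 1)
        expect_true(is_unimodal(prof, tol = 1e-12))
      }
    }
  }
})

test_that("invalid schemes and multiplier fields are rejected", {
  expect_error(kinetic_scheme(c("A", "B"), rates = -0.1), ">= 0")
  expect_error(kinetic_scheme(c("A", "B"), rates = c(0.1, 0.2)), "one rate")
  expect_error(kinetic_scheme(c("A", "B"), rates = 0.1, induction = 0.5), ">= 1")
  expect_error(defect_multipliers(c(0, 1),
    tibble::tibble(start_mm = 0, end_mm = 1, multiplier = 0)), "> 0")
  sch <- kinetic_scheme(c("A", "B"), rates = 0.1)
  expect_error(simulate_kinetics(sch, times = c(5, 2), positions = 0),
               "increasing")
})

test_that("tidy() of a field carries closure into long format", {
  sch <- kinetic_scheme(c("A", "B", "C"), rates = c(0.1, 0.05))
  fld <- simulate_kinetics(sch, times = seq(0, 30, by = 10), positions = c(0, 0.5))
  td <- tidy(fld)
  sums <- tapply(td$fraction, paste(td$time, td$position), sum)
  expect_lt(max(abs(sums - 1)), 1e-9)
})
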