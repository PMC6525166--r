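#' Define a sequential transformation scheme
#'
#' Describes the solid-state cascade traversed during dehydration, e.g.
#' monohydrate -> metastable 1 -> metastable 2 -> anhydrate. Each arrow is a
#' first-order step with rate constant `k` (1/min); an optional Avrami-type
#' induction exponent `n >= 1` per step turns the constant hazard `k` into
#' the time-dependent hazard `n k^n t^(n-1)` (sigmoidal conversion with an
#' induction period; `n = 1` recovers plain first-order kinetics).
#'
#' @param components Character vector of component names in transformation
#'   order.
#' @param rates Numeric vector of rate constants (1/min), one per step
#'   (`length(components) - 1`), all `>= 0`.
#' @param induction Avrami exponents per step, all `>= 1`; default 1.
#' @return A `kinetic_scheme` list.
#' @examples
#' kinetic_scheme(c("A", "B", "C"), rates = c(0.1, 0.05))
#' @export
kinetic_scheme <- function(components, rates, induction = rep(1, length(rates))) {
  components <- as.character(components)
  if (length(components) < 2) {
    stop("a kinetic scheme needs at least two components", call. = FALSE)
  }
  if (anyDuplicated(components)) {
    stop("component names must be unique", call. = FALSE)
  }
  if (length(rates) != length(components) - 1) {
    stop("need one rate per transformation step (", length(components) - 1, ")",
         call. = FALSE)
  }
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("rate constants must be finite and >= 0", call. = FALSE)
  }
  if (length(induction) != length(rates) || any(!is.finite(induction)) ||
      any(induction < 1)) {
    stop("induction exponents must be finite and >= 1, one per step", call. = FALSE)
  }
  structure(list(components = components, rates = as.numeric(rates),
                 induction = as.numeric(induction)),
            class = "kinetic_scheme")
}

#' Piecewise-constant defect rate multipliers along the line
#'
#' Real particles convert faster in defect-rich regions. This helper builds a
#' per-position rate multiplier that is 1 outside and `multiplier` inside the
#' given intervals (later intervals override earlier ones where they overlap).
#'
#' @param positions Lateral positions (mm), e.g. [line_positions()].
#' @param defects Tibble/data frame with columns `start_mm`, `end_mm`,
#'   `multiplier` (> 0); `NULL` for a homogeneous particle.
#' @return Numeric vector of multipliers, one per position, all > 0.
#' @examples
#' defect_multipliers(line_positions(20, 1.8),
#'                    tibble::tibble(start_mm = 0.5, end_mm = 1, multiplier = 2))
#' @export
defect_multipliers <- function(positions, defects = NULL) {
  mult <- rep(1, length(positions))
  if (is.null(defects) || nrow(defects) == 0) return(mult)
  need <- c("start_mm", "end_mm", "multiplier")
  if (!all(need %in% names(defects))) {
    stop("`defects` needs columns start_mm, end_mm, multiplier", call. = FALSE)
  }
  if (any(defects$multiplier <= 0)) {
    stop("defect multipliers must be > 0", call. = FALSE)
  }
  for (i in seq_len(nrow(defects))) {
    inside <- positions >= defects$start_mm[i] & positions <= defects$end_mm[i]
    mult[inside] <- defects$multiplier[i]
  }
  mult
}

#' Simulate dehydration kinetics over the laser line
#'
#' Integrates the sequential scheme at every lateral position and returns the
#' ground-truth concentration field. The first `m - 1` species are integrated
#' with a stiff ODE solver (tight tolerances); the terminal species is taken
#' as `1 - sum(others)` so closure holds exactly at every (time, position).
#'
#' Positions sharing the same rate multiplier share one integration, so the
#' piecewise-constant defect model costs no more than a handful of solves.
#'
#' @param scheme A [kinetic_scheme()].
#' @param times Strictly increasing time points (min); need not start at 0.
#' @param positions Lateral positions (mm).
#' @param multipliers Per-position rate multiplier (> 0), e.g. from
#'   [defect_multipliers()]; default homogeneous.
#' @return A `conc_field`: array (time x position x component) with closure
#'   `sum_j C = 1` exact and all entries in \[0, 1\].
#' @examples
#' sch <- kinetic_scheme(c("A", "B", "C"), rates = c(0.1, 0.05))
#' fld <- simulate_kinetics(sch, times = 0:60, positions = line_positions(5))
#' dim(fld)
#' @export
simulate_kinetics <- function(scheme, times, positions,
                              multipliers = rep(1, length(positions))) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  times <- as.numeric(times)
  if (length(times) < 1 || any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  if (any(times < 0)) stop("`times` must be >= 0", call. = FALSE)
  if (length(multipliers) != length(positions) || any(multipliers <= 0)) {
    stop("`multipliers` must be positive, one per position", call. = FALSE)
  }
  k <- length(scheme$components)
  field <- array(0, dim = c(length(times), length(positions), k))

  for (m in unique(multipliers)) {
    traj <- integrate_chain(scheme$rates * m, scheme$induction, times)
    idx <- which(multipliers == m)
    for (j in seq_len(k)) field[, idx, j] <- traj[, j]
  }

  new_conc_field(field, times = times, positions = positions,
                 components = scheme$components)
}

# Integrate a sequential first-order / Avrami chain; returns times x k matrix
# with the last species closed to exactly 1 - sum(others).
integrate_chain <- function(rates, induction, times) {
  k <- length(rates) + 1
  t_grid <- if (times[1] > 0) c(0, times) else times
  y0 <- c(1, rep(0, k - 2))
  if (all(rates == 0)) {
    lead <- matrix(rep(y0, each = length(times)), nrow = length(times))
  } else {
    deriv <- function(t, y, parms) {
      h <- parms$rates * parms$ind * (parms$rates * t)^(parms$ind - 1)
      h[parms$rates == 0] <- 0
      # species i (1..k-1): d y_i = h_{i-1} y_{i-1} - h_i y_i, with h_0 = 0
      dy <- numeric(length(y))
      for (i in seq_along(y)) {
        gain <- if (i > 1) h[i - 1] * y[i - 1] else 0
        loss <- if (i <= length(h)) h[i] * y[i] else 0
        dy[i] <- gain - loss
      }
      list(dy)
    }
    sol <- deSolve::lsoda(y = y0, times = t_grid, func = deriv,
                          parms = list(rates = rates, ind = induction),
                          rtol = 1e-12, atol = 1e-14)
    lead <- unname(sol[match(times, t_grid), -1, drop = FALSE])
  }
  lead <- pmin(pmax(lead, 0), 1)
  last <- 1 - rowSums(lead)
  neg <- last < 0
  if (any(neg)) {
    # integration round-off only; rescale the leading species to restore closure
    lead[neg, ] <- lead[neg, , drop = FALSE] / rowSums(lead[neg, , drop = FALSE])
    last[neg] <- 0
  }
  cbind(lead, last)
}

#' Concentration-field constructor
#'
#' @param field Array (time x position x component) of fractions.
#' @param times,positions,components Axis metadata.
#' @return A `conc_field` array with attributes.
#' @keywords internal
new_conc_field <- function(field, times, positions, components) {
  stopifnot(length(dim(field)) == 3,
            dim(field)[1] == length(times),
            dim(field)[2] == length(positions),
            dim(field)[3] == length(components))
  if (any(field < -1e-9) || any(field > 1 + 1e-9)) {
    stop("concentration fractions must lie in [0, 1]", call. = FALSE)
  }
  structure(field, times = as.numeric(times), positions = as.numeric(positions),
            components = as.character(components), class = "conc_field")
}

#' @export
print.conc_field <- function(x, ...) {
  d <- dim(x)
  cat("<conc_field> ", d[1], " times x ", d[2], " positions x ", d[3],
      " components (", paste(attr(x, "components"), collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

#' Tidy a concentration field into a long tibble
#'
#' @param x A `conc_field`.
#' @param ... Unused.
#' @return Tibble with columns `time`, `position`, `component`, `fraction`.
#' @export
tidy.conc_field <- function(x, ...) {
  d <- dim(x)
  tibble::tibble(
    time = rep(attr(x, "times"), times = d[2] * d[3]),
    position = rep(rep(attr(x, "positions"), each = d[1]), times = d[3]),
    component = rep(attr(x, "components"), each = d[1] * d[2]),
    fraction = as.vector(unclass(x))
  )
}
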