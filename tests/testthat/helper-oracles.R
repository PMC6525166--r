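# Independent oracles and small fixtures used across the suite.

cos_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# Closed-form Bateman solution for a consecutive first-order chain with
# distinct rates k_1..k_{m-1}; returns times x m matrix of fractions.
# Written from the analytic formula, independent of the ODE integrator.
bateman_chain <- function(rates, times) {
  m <- length(rates) + 1
  out <- matrix(0, length(times), m)
  for (i in seq_len(m)) {
    if (i == 1) {
      out[, 1] <- exp(-rates[1] * times)
    } else {
      ks <- rates[seq_len(i - 1)]          # rates feeding species i
      lam <- c(ks, if (i <= length(rates)) rates[i] else 0)
      # species i amplitude: prod(ks) * sum_j exp(-lam_j t)/prod_{l!=j}(lam_l-lam_j)
      acc <- 0
      for (j in seq_along(lam)) {
        denom <- prod(lam[-j] - lam[j])
        acc <- acc + exp(-lam[j] * times) / denom
      }
      out[, i] <- prod(ks) * acc
    }
  }
  out
}

# Hand-written pool-adjacent-violators for a non-decreasing fit.
pava_increasing <- function(y) {
  n <- length(y)
  if (n <= 1) return(y)
  vals <- numeric(n)
  wts <- numeric(n)
  idx <- 0
  for (i in seq_len(n)) {
    idx <- idx + 1
    vals[idx] <- y[i]
    wts[idx] <- 1
    while (idx > 1 && vals[idx - 1] > vals[idx]) {
      pooled <- (wts[idx - 1] * vals[idx - 1] + wts[idx] * vals[idx]) /
        (wts[idx - 1] + wts[idx])
      vals[idx - 1] <- pooled
      wts[idx - 1] <- wts[idx - 1] + wts[idx]
      idx <- idx - 1
    }
  }
  rep(vals[seq_len(idx)], times = wts[seq_len(idx)])
}

# Exhaustive unimodal least-squares oracle: every split into a non-decreasing
# prefix and non-increasing suffix, each fitted by the hand-written PAVA.
unimodal_oracle <- function(y) {
  n <- length(y)
  if (n == 0) return(y)
  best <- NULL
  best_sse <- Inf
  for (m in 0:n) {
    left <- if (m >= 1) pava_increasing(y[seq_len(m)]) else numeric(0)
    right <- if (m < n) rev(pava_increasing(rev(y[(m + 1):n]))) else numeric(0)
    fit <- c(left, right)
    sse <- sum((fit - y)^2)
    if (sse < best_sse) {
      best_sse <- sse
      best <- fit
    }
  }
  best
}

# Brute-force NNLS oracle: enumerate all active sets, solve the unconstrained
# LS on each passive set, keep feasible candidates, return the best.
nnls_oracle <- function(A, b) {
  k <- ncol(A)
  best_x <- rep(0, k)
  best_r <- sum(b^2)
  for (mask in 0:(2^k - 1)) {
    passive <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
    if (length(passive) == 0) next
    Ap <- A[, passive, drop = FALSE]
    xp <- tryCatch(solve(crossprod(Ap), crossprod(Ap, b)),
                   error = function(e) NULL)
    if (is.null(xp) || any(xp < 0)) next
    x <- rep(0, k)
    x[passive] <- xp
    r <- sum((A %*% x - b)^2)
    if (r < best_r - 1e-12) {
      best_r <- r
      best_x <- x
    }
  }
  best_x
}

# Best-match assignment of resolved unknown components to their ground-truth
# counterparts by maximal total cosine over all permutations (k is small).
assign_unknowns <- function(fit, truth_spectra, unknown_labels) {
  uidx <- which(!fit$known)
  perms <- perms_of(uidx)
  scores <- vapply(perms, function(p) {
    sum(vapply(seq_along(p), function(i) {
      cos_sim(fit$S[p[i], ], truth_spectra[unknown_labels[i], ])
    }, numeric(1)))
  }, numeric(1))
  p <- perms[[which.max(scores)]]
  ord <- seq_along(fit$known)
  ord[uidx] <- p
  list(order = ord, unknown_order = p,
       cosines = vapply(seq_along(p), function(i) {
         cos_sim(fit$S[p[i], ], truth_spectra[unknown_labels[i], ])
       }, numeric(1)))
}

perms_of <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perms_of(v[-i])) out <- c(out, list(c(v[i], rest)))
  }
  out
}

# Reduced-size theophylline-like scenario for fast unit tests: same band
# tables and kinetics as the TP4 preset, coarser grids.
tiny_tp4 <- function() {
  sc <- default_scenario("TP4")
  sc$times <- seq(0, 90, by = 6)
  sc$positions$n <- 40
  sc$axis$step <- 4
  sc
}
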