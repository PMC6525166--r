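#' Lack of fit of a bilinear reconstruction
#'
#' `LoF = 100 * sqrt( sum((D - C S)^2) / sum(D^2) )`, the percentage of the
#' data's total sum of squares left unexplained by the bilinear model.
#'
#' @param D Data matrix (observations x channels).
#' @param C Concentration matrix (observations x k).
#' @param S Spectra matrix (k x channels).
#' @return LoF in percent.
#' @examples
#' D <- matrix(c(1, 0, 0, 1), 2)
#' lack_of_fit(D, D, diag(2))  # exact model: 0
#' @export
lack_of_fit <- function(D, C, S) {
  D <- as.matrix(D); C <- as.matrix(C); S <- as.matrix(S)
  if (ncol(C) != nrow(S) || nrow(C) != nrow(D) || ncol(S) != ncol(D)) {
    stop("D, C, S are not conformable", call. = FALSE)
  }
  ss <- sum(D^2)
  if (ss == 0) stop("cannot compute lack of fit of an all-zero matrix", call. = FALSE)
  100 * sqrt(sum((D - C %*% S)^2) / ss)
}

#' Averaged relative residual of a reconstruction
#'
#' `100 * mean(|D - C S|) / mean(|D|)`: the mean absolute residual as a
#' percentage of the mean absolute signal.
#'
#' @inheritParams lack_of_fit
#' @return Percentage.
#' @export
avg_relative_residual <- function(D, C, S) {
  D <- as.matrix(D); C <- as.matrix(C); S <- as.matrix(S)
  denom <- mean(abs(D))
  if (denom == 0) stop("all-zero data matrix", call. = FALSE)
  100 * mean(abs(D - C %*% S)) / denom
}

#' Estimate the number of components by lack of fit
#'
#' Fits unconstrained truncated-SVD models of rank `k = 1..k_max` and reports
#' the lack of fit of each. The selected rank is the smallest `k` beyond
#' which adding another component improves LoF by less than
#' `improvement_threshold` (relative), i.e. the elbow of the LoF-vs-k curve;
#' exactly low-rank data short-circuit at an absolute LoF floor. Ties resolve
#' toward the smaller rank (parsimony).
#'
#' @param D Data matrix (observations x channels), not all zero.
#' @param k_max Largest rank to try; at most `min(dim(D))`.
#' @param improvement_threshold Relative LoF improvement below which an extra
#'   component is judged not worth keeping (default 0.25).
#' @param lof_floor Absolute LoF (percent) under which the fit is considered
#'   exact (default 1e-6).
#' @return A `rank_selection`: list with `k` (selected) and `table` (tibble
#'   of `k`, `lof`, `improvement`).
#' @examples
#' D <- tcrossprod(matrix(runif(20), 10, 2), matrix(runif(16), 8, 2))
#' estimate_rank(D, k_max = 5)$k
#' @export
estimate_rank <- function(D, k_max, improvement_threshold = 0.25,
                          lof_floor = 1e-6) {
  D <- as.matrix(D)
  if (all(D == 0)) stop("cannot estimate rank of an all-zero matrix", call. = FALSE)
  if (k_max < 1 || k_max > min(dim(D))) {
    stop("`k_max` must be in 1..min(dim(D))", call. = FALSE)
  }
  sv <- svd(D, nu = 0, nv = 0)$d
  total <- sum(sv^2)
  resid <- total - cumsum(sv^2)
  resid <- pmax(resid, 0)
  lof <- 100 * sqrt(resid[seq_len(k_max)] / total)
  improvement <- c(NA_real_, ifelse(lof[-k_max] > 0,
                                    (lof[-k_max] - lof[-1]) / lof[-k_max], 0))
  selected <- k_max
  for (k in seq_len(k_max)) {
    if (lof[k] <= lof_floor) { selected <- k; break }
    if (k < k_max && improvement[k + 1] < improvement_threshold) {
      selected <- k
      break
    }
  }
  structure(list(
    k = selected,
    table = tibble::tibble(k = seq_len(k_max), lof = lof,
                           improvement = improvement)
  ), class = "rank_selection")
}

#' @export
print.rank_selection <- function(x, ...) {
  cat("<rank_selection> k =", x$k, "\n")
  print(x$table)
  invisible(x)
}

#' @export
tidy.rank_selection <- function(x, ...) x$table

#' Initialize the unknown library rows
#'
#' Deterministic starting guess for the spectra MCR-ALS must resolve. The
#' stable-form contribution is removed from every observation by NNLS (the
#' residual-map logic); among the residual spectra, the most mutually
#' dissimilar high-purity rows are picked SIMPLISMA-style — purity
#' `sd / (mean + 5% offset)`, later picks down-weighted by a Gram-determinant
#' dissimilarity against those already chosen. Selection depends only on the
#' set of observations, not their order.
#'
#' @param D Data matrix (observations x channels).
#' @param library A `spectral_library` with known rows filled and unknown
#'   rows flagged.
#' @param offset_frac SIMPLISMA noise offset as a fraction of the largest
#'   mean (default 0.05).
#' @return Full spectra matrix (k x channels): known rows copied unchanged,
#'   unknown rows filled with non-negative, unit-max initial spectra.
#' @export
initialize_unknowns <- function(D, library, offset_frac = 0.05) {
  stopifnot(inherits(library, "spectral_library"))
  D <- as.matrix(D)
  if (ncol(D) != ncol(library$spectra)) {
    stop("`D` and library disagree on channel count", call. = FALSE)
  }
  S <- library$spectra
  u <- sum(!library$known)
  if (u == 0) return(S)
  if (nrow(D) < u) {
    stop("fewer observations (", nrow(D), ") than unknowns (", u, ")",
         call. = FALSE)
  }

  if (any(library$known)) {
    A <- t(S[library$known, , drop = FALSE])
    R <- t(apply(D, 1, function(b) b - as.vector(A %*% nnls_solve(A, b))))
  } else {
    R <- D
  }

  m <- rowMeans(abs(R))
  if (max(m) == 0) {
    stop("no residual signal left to initialize unknowns from", call. = FALSE)
  }
  s <- apply(R, 1, stats::sd)
  alpha <- offset_frac * max(m)
  purity <- s / (m + alpha)
  norms <- sqrt(rowSums(R^2))
  Y <- R / pmax(norms, .Machine$double.eps)

  chosen <- integer(0)
  for (q in seq_len(u)) {
    if (q == 1) {
      w <- rep(1, nrow(R))
    } else {
      w <- vapply(seq_len(nrow(R)), function(i) {
        G <- tcrossprod(Y[c(i, chosen), , drop = FALSE])
        det(G)
      }, numeric(1))
    }
    score <- purity * pmax(w, 0)
    score[chosen] <- -Inf
    chosen <- c(chosen, which.max(score))
  }

  init <- pmax(R[chosen, , drop = FALSE], 0)
  mx <- apply(init, 1, max)
  if (any(mx == 0)) {
    stop("selected residual spectra carry no positive signal", call. = FALSE)
  }
  S[!library$known, ] <- init / mx
  S
}

#' Constrained MCR-ALS with a partially known spectral library
#'
#' Resolves the bilinear model `D = C S + E` by alternating least squares
#' under the constraint set used for solid-state dehydration data:
#' non-negative `C` and `S`, closure (each observation's fractions sum to 1),
#' unimodality of concentration-time profiles, and an equality constraint
#' pinning the known (stable-form) library rows. Unknown rows are seeded by
#' [initialize_unknowns()].
#'
#' Each iteration runs a C-step (per-observation NNLS against the current
#' `S`, closure normalization, unimodal projection of the selected profiles
#' along time, re-closure) and an S-step (per-channel NNLS update of the
#' unknown rows only, with the known-row contribution subtracted out, then
#' unit-max renormalization of unknown rows with the compensating rescale
#' absorbed into `C`). Iteration stops when the relative change in lack of
#' fit falls below `tol` or after `max_iter` iterations; a final C-step
#' guarantees the returned `C` obeys closure against the returned `S`.
#'
#' @param D Data matrix (observations x channels), e.g. the highest-SNR trace
#'   from [extract_trace()].
#' @param library A `spectral_library`: known rows fixed, unknown rows (`NA`)
#'   resolved.
#' @param constraints Named list of toggles: `nonneg_C`, `nonneg_S`,
#'   `closure`, `unimodality` (all default `TRUE`).
#' @param unimodal_components `"unknown"` (default) to constrain only the
#'   resolved (metastable) profiles, or `"all"`.
#' @param tol Relative LoF-change convergence tolerance (default 1e-6).
#' @param max_iter Maximum iterations (default 200).
#' @param time_order Optional integer vector ranking the observations in
#'   acquisition time; unimodality is applied in this order (default: row
#'   order).
#' @return An `mcr_fit`: `C` (observations x k), `S` (k x channels, known
#'   rows bit-identical to input), `lof_trace`, `lof`, `avg_rel_residual`
#'   (percent), `iterations`, `converged`, plus labels/known metadata.
#' @examples
#' sim <- simulate_scenario(default_scenario("TP4"), seed = 42, noise = FALSE)
#' tr <- extract_trace(sim$scan, 110)
#' lib <- mark_unknown(sim$library, sim$scenario$metastable)
#' fit <- mcr_als(tr, lib)
#' glance(fit)
#' @export
mcr_als <- function(D, library,
                    constraints = list(),
                    unimodal_components = c("unknown", "all"),
                    tol = 1e-6, max_iter = 200, time_order = NULL) {
  stopifnot(inherits(library, "spectral_library"))
  unimodal_components <- match.arg(unimodal_components)
  cst <- utils::modifyList(
    list(nonneg_C = TRUE, nonneg_S = TRUE, closure = TRUE, unimodality = TRUE),
    constraints
  )
  D <- as.matrix(D)
  if (any(!is.finite(D))) stop("`D` must be finite", call. = FALSE)
  if (ncol(D) != ncol(library$spectra)) {
    stop("`D` and library disagree on channel count", call. = FALSE)
  }
  n_obs <- nrow(D)
  k <- nrow(library$spectra)
  known <- library$known
  labels <- library$labels
  if (is.null(time_order)) time_order <- seq_len(n_obs)
  ord <- order(time_order)
  uni_idx <- if (unimodal_components == "all") seq_len(k) else which(!known)

  S <- initialize_unknowns(D, library)
  S_known <- S[known, , drop = FALSE]

  c_step <- function(S) {
    C <- solve_rows_nnls(t(S), D, nonneg = cst$nonneg_C)
    colnames(C) <- labels
    if (cst$closure) C <- close_rows(C)
    if (cst$unimodality && length(uni_idx)) {
      for (j in uni_idx) C[ord, j] <- unimodality_project(C[ord, j])
      if (cst$closure) C <- close_rows(C)
    }
    C
  }

  C <- c_step(S)
  lof0 <- lack_of_fit(D, C, S)
  lof_trace <- numeric(0)
  lof_prev <- lof0
  converged <- FALSE
  iter <- 0

  while (iter < max_iter) {
    iter <- iter + 1
    # S-step: update unknown rows only, known rows held fixed
    if (any(!known)) {
      E <- D - C[, known, drop = FALSE] %*% S_known
      Su <- t(solve_rows_nnls(C[, !known, drop = FALSE], t(E),
                              nonneg = cst$nonneg_S))
      mx <- apply(Su, 1, max)
      pos <- mx > 0
      Su[pos, ] <- Su[pos, , drop = FALSE] / mx[pos]
      uidx <- which(!known)[pos]
      C[, uidx] <- C[, uidx, drop = FALSE] * rep(mx[pos], each = n_obs)
      S[!known, ] <- Su
    }
    C <- c_step(S)
    lof <- lack_of_fit(D, C, S)
    lof_trace <- c(lof_trace, lof)
    if (lof < 1e-9 ||
        abs(lof_prev - lof) / max(lof_prev, 1e-12) < tol) {
      converged <- TRUE
      break
    }
    lof_prev <- lof
  }
  if (!converged) {
    warning("MCR-ALS did not converge in ", max_iter, " iterations ",
            "(last LoF ", signif(lof_prev, 6), "%)", call. = FALSE)
  }

  fit <- structure(list(
    C = C, S = S,
    lof_trace = lof_trace, lof_initial = lof0,
    lof = if (length(lof_trace)) lof_trace[length(lof_trace)] else lof0,
    avg_rel_residual = avg_relative_residual(D, C, S),
    iterations = iter, converged = converged,
    labels = labels, known = known,
    wavenumbers = library$wavenumbers,
    time_order = time_order,
    constraints = cst
  ), class = "mcr_fit")
  fit
}

# Row-wise (non-negative) least squares: solve A x = b for every row b of B.
# Unconstrained normal-equation solve first, vectorized across rows; rows with
# any negative coefficient are re-solved exactly by Lawson-Hanson.
solve_rows_nnls <- function(A, B, nonneg = TRUE) {
  A <- as.matrix(A)
  B <- as.matrix(B)
  AtA <- crossprod(A)
  sol <- tryCatch(
    t(solve(AtA, crossprod(A, t(B)))),
    error = function(e) NULL
  )
  if (is.null(sol)) {
    sol <- t(apply(B, 1, function(b) stats::lsfit(A, b, intercept = FALSE)$coef))
  }
  if (!nonneg) return(sol)
  bad <- which(apply(sol, 1, function(x) any(x < 0)))
  for (i in bad) sol[i, ] <- nnls_solve(A, B[i, ])
  pmax(sol, 0)
}

close_rows <- function(C) {
  rs <- rowSums(C)
  pos <- rs > 0
  C[pos, ] <- C[pos, , drop = FALSE] / rs[pos]
  C
}

#' @export
print.mcr_fit <- function(x, ...) {
  cat("<mcr_fit> ", nrow(x$C), " observations x ", length(x$labels),
      " components\n", sep = "")
  cat("  LoF ", signif(x$lof, 6), "% after ", x$iterations, " iterations (",
      if (x$converged) "converged" else "NOT converged", ")\n", sep = "")
  cat("  averaged relative residual ", signif(x$avg_rel_residual, 6), "%\n",
      sep = "")
  invisible(x)
}

#' Tidy an MCR fit
#'
#' @param x An `mcr_fit`.
#' @param what `"concentrations"` (default: one row per observation and
#'   component), `"spectra"` (one row per component and channel) or `"lof"`
#'   (the iteration trace).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.mcr_fit <- function(x, what = c("concentrations", "spectra", "lof"), ...) {
  what <- match.arg(what)
  switch(what,
    concentrations = tibble::tibble(
      observation = rep(seq_len(nrow(x$C)), times = ncol(x$C)),
      component = rep(x$labels, each = nrow(x$C)),
      known = rep(x$known, each = nrow(x$C)),
      fraction = as.vector(x$C)
    ),
    spectra = tibble::tibble(
      component = rep(x$labels, each = ncol(x$S)),
      known = rep(x$known, each = ncol(x$S)),
      wavenumber = rep(x$wavenumbers, times = nrow(x$S)),
      intensity = as.vector(t(x$S))
    ),
    lof = tibble::tibble(iteration = seq_along(x$lof_trace), lof = x$lof_trace)
  )
}

#' One-row summary of an MCR fit
#'
#' @param x An `mcr_fit`.
#' @param ... Unused.
#' @return Tibble with `n_components`, `n_unknown`, `lof`,
#'   `avg_rel_residual`, `iterations`, `converged`.
#' @export
glance.mcr_fit <- function(x, ...) {
  tibble::tibble(
    n_components = length(x$labels),
    n_unknown = sum(!x$known),
    lof = x$lof,
    avg_rel_residual = x$avg_rel_residual,
    iterations = x$iterations,
    converged = x$converged
  )
}

#' Resolved spectral library from an MCR fit
#'
#' Packages the fitted `S` as a fully known `spectral_library`, ready for
#' NNLS mapping of the full line scan.
#'
#' @param fit An `mcr_fit`.
#' @return A `spectral_library` with every row known.
#' @export
resolved_library <- function(fit) {
  stopifnot(inherits(fit, "mcr_fit"))
  S <- fit$S
  rownames(S) <- fit$labels
  new_spectral_library(S, fit$wavenumbers, known = rep(TRUE, nrow(S)))
}
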