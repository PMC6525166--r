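#' Project a profile onto the unimodal cone
#'
#' Finds the least-squares closest vector that rises to a single maximum and
#' then falls (plateaus allowed). Every split of the sequence into a
#' non-decreasing prefix and a non-increasing suffix is scored — each side
#' fitted by isotonic regression — and the best split wins; any such
#' concatenation has exactly one local maximum. Monotone inputs are already
#' unimodal (mode at an end) and are returned unchanged, as is any input that
#' is already unimodal. Non-negativity is preserved: isotonic fits are
#' averages of the input.
#'
#' Used inside MCR-ALS to constrain concentration-time profiles: a transient
#' intermediate grows, peaks once and decays.
#'
#' @param profile Numeric vector with finite entries.
#' @return Numeric vector of the same length, unimodal, with squared error
#'   minimal over all mode positions.
#' @examples
#' unimodality_project(c(1, 3, 2, 4, 1))
#' unimodality_project(c(0, 1, 3, 2, 1))  # already unimodal: unchanged
#' @export
unimodality_project <- function(profile) {
  n <- length(profile)
  if (n == 0) return(profile)
  if (any(!is.finite(profile))) {
    stop("profile must be finite", call. = FALSE)
  }
  if (n == 1) return(profile)

  best <- NULL
  best_sse <- Inf
  for (m in 0:n) {
    left <- if (m >= 1) stats::isoreg(profile[seq_len(m)])$yf else numeric(0)
    right <- if (m < n) {
      rev(stats::isoreg(rev(profile[(m + 1):n]))$yf)
    } else numeric(0)
    fit <- c(left, right)
    sse <- sum((fit - profile)^2)
    if (sse < best_sse - 1e-15) {
      best_sse <- sse
      best <- fit
    }
    if (best_sse == 0) break
  }
  best
}

#' Check unimodality of a vector
#'
#' @param v Numeric vector.
#' @param tol Slack when comparing neighbours.
#' @return `TRUE` if `v` rises (weakly) to a single peak then falls (weakly).
#' @export
is_unimodal <- function(v, tol = 0) {
  if (length(v) <= 2) return(TRUE)
  d <- diff(v)
  sign3 <- ifelse(d > tol, 1L, ifelse(d < -tol, -1L, 0L))
  s <- sign3[sign3 != 0L]
  if (length(s) == 0) return(TRUE)
  !is.unsorted(rev(s))
}
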