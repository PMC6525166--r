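#' Non-negative least squares
#'
#' Solves `min ||A x - b||` subject to `x >= 0` with the Lawson-Hanson
#' active-set algorithm (via [pracma::lsqnonneg()]). Deterministic: the same
#' inputs always give the same coefficients.
#'
#' @param A Numeric matrix, channels x components. Column names, when
#'   present, are used in error messages and on the result.
#' @param b Numeric vector of length `nrow(A)`.
#' @return Named numeric vector of `ncol(A)` non-negative coefficients.
#' @examples
#' nnls_solve(diag(2), c(-1, 2))
#' @export
nnls_solve <- function(A, b) {
  A <- as.matrix(A)
  b <- as.numeric(b)
  if (nrow(A) != length(b)) {
    stop("`A` and `b` are not conformable", call. = FALSE)
  }
  if (any(!is.finite(A)) || any(!is.finite(b))) {
    stop("NNLS inputs must be finite", call. = FALSE)
  }
  zero_col <- colSums(abs(A)) == 0
  if (any(zero_col)) {
    nm <- colnames(A)
    bad <- if (is.null(nm)) paste("column", which(zero_col)) else nm[zero_col]
    stop("all-zero library column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  x <- pracma::lsqnonneg(A, b)$x
  names(x) <- colnames(A)
  pmax(x, 0)
}
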