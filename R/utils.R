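# Small numerical helpers shared across modules.

#' Trapezoidal quadrature weights
#'
#' Weights `w` such that `sum(w * f)` approximates the integral of `f`
#' over the (possibly non-uniform) grid `times`.
#'
#' @param times numeric vector, strictly increasing.
#' @return numeric vector of weights, same length as `times`.
#' @keywords internal
trapezoid_weights <- function(times) {
  n <- length(times)
  if (n < 2L) stop("need at least two time samples")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  w <- numeric(n)
  dt <- diff(times)
  w[1L] <- dt[1L] / 2
  w[n] <- dt[n - 1L] / 2
  if (n > 2L) w[2:(n - 1L)] <- (dt[-length(dt)] + dt[-1L]) / 2
  w
}

#' Row-wise Euclidean norm of a 3-column matrix
#' @keywords internal
row_norms <- function(m) sqrt(rowSums(m * m))

#' Normalise rows of a matrix to unit length
#'
#' Rows with norm below `tol` are returned as zero rows.
#' @keywords internal
normalize_rows <- function(m, tol = 1e-12) {
  nrm <- row_norms(m)
  scale <- ifelse(nrm > tol, 1 / nrm, 0)
  m * scale
}

#' Cross product of two 3-vectors (or row-wise for matrices)
#' @keywords internal
cross3 <- function(a, b) {
  if (is.matrix(a) || is.matrix(b)) {
    if (!is.matrix(a)) a <- matrix(a, nrow(b), 3, byrow = TRUE)
    if (!is.matrix(b)) b <- matrix(b, nrow(a), 3, byrow = TRUE)
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])
  } else {
    c(a[2] * b[3] - a[3] * b[2],
      a[3] * b[1] - a[1] * b[3],
      a[1] * b[2] - a[2] * b[1])
  }
}

#' Derive a reproducible sub-seed from a base seed and an index
#'
#' Keeps every derived seed inside the 32-bit integer range so that
#' `set.seed()` accepts it.
#' @keywords internal
derive_seed <- function(base_seed, index, stream = 0L) {
  base <- as.double(base_seed) %% 2147483647
  s <- (base * 48271 + as.double(index) * 104729 + as.double(stream) * 7919) %% 2147483647
  as.integer(s)
}

#' Dice overlap coefficient between two logical masks
#'
#' @param a,b logical vectors/matrices of equal size.
#' @return `2|A intersect B| / (|A| + |B|)`; 1 when both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(length(a) == length(b))
  a <- as.logical(a); b <- as.logical(b)
  denom <- sum(a, na.rm = TRUE) + sum(b, na.rm = TRUE)
  if (denom == 0) return(1)
  2 * sum(a & b, na.rm = TRUE) / denom
}
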