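# Orthonormal DCT-II and friends. The transform matrix
#   C[k, n] = c_k sqrt(2/N) cos(pi/N (n + 1/2) k),  c_0 = 1/sqrt(2), c_k = 1
# is orthogonal, so the inverse is its transpose and Parseval holds exactly.
# Matrices are cached per length; beat windows are a few hundred samples, so
# the dense product is both exact and fast.

.dct_cache <- new.env(parent = emptyenv())

dct_matrix <- function(n) {
  key <- as.character(n)
  if (!is.null(.dct_cache[[key]])) return(.dct_cache[[key]])
  k <- seq_len(n) - 1L
  m <- sqrt(2 / n) * cos(outer(k, k + 0.5) * pi / n)
  m[1L, ] <- m[1L, ] / sqrt(2)
  .dct_cache[[key]] <- m
  m
}

#' Orthonormal DCT-II of a beat
#'
#' Computes `X_c[k] = c_k sqrt(2/N) sum_n x[n] cos(pi/N (n + 1/2) k)` with
#' `c_0 = 1/sqrt(2)` and `c_k = 1` otherwise, for `k = 0 ... N-1`. With this
#' normalisation the transform is orthogonal: coefficient energy equals
#' sample energy (Parseval), and [dct_inverse()] is the exact adjoint.
#'
#' @param beat An [ecg_beat()], or a plain numeric vector of length >= 2.
#' @return An object of class `dct_coefficients`: list with `values`
#'   (numeric, length N), `n_samples`, and `fs` (NA for plain vectors).
#' @export
#' @examples
#' X <- dct_forward(rep(1, 256))
#' X$values[1]  # sqrt(256) = 16, all other coefficients ~ 0
dct_forward <- function(beat) {
  if (inherits(beat, "ecg_beat")) {
    x <- beat$samples
    fs <- beat$fs
  } else {
    x <- as.numeric(beat)
    fs <- NA_real_
  }
  n <- length(x)
  if (n < 2L) stop_invalid("dct_forward needs at least 2 samples, got %d", n)
  structure(
    list(values = drop(dct_matrix(n) %*% x), n_samples = n, fs = fs),
    class = "dct_coefficients"
  )
}

#' Inverse orthonormal DCT (DCT-III)
#'
#' Exact inverse of [dct_forward()]; round-trip error is at floating-point
#' level.
#'
#' @param coeffs A `dct_coefficients` object or numeric vector.
#' @return Numeric vector of reconstructed samples.
#' @export
dct_inverse <- function(coeffs) {
  if (inherits(coeffs, "dct_coefficients")) {
    v <- coeffs$values
    if (length(v) != coeffs$n_samples) {
      stop_invalid("coefficient length %d does not match declared N = %d",
                   length(v), coeffs$n_samples)
    }
  } else {
    v <- as.numeric(coeffs)
  }
  if (length(v) < 2L) stop_invalid("dct_inverse needs at least 2 coefficients")
  drop(crossprod(dct_matrix(length(v)), v))
}

#' @export
print.dct_coefficients <- function(x, ...) {
  cat(sprintf("<dct_coefficients> N=%d  fs=%s Hz  |X|max=%.4g at k=%d\n",
              x$n_samples, format(x$fs), max(abs(x$values)),
              which.max(abs(x$values)) - 1L))
  invisible(x)
}

#' Conventional (sum-of-squares) signal energy
#'
#' The Fourier-domain energy of a signal equals its time-domain sum of
#' squares (Parseval), so this energy depends only on amplitude, not
#' frequency: two equal-amplitude sinusoids of different frequencies have
#' the same conventional energy. That frequency-blindness is the contrast
#' that motivates the Teager operator ([teo_closed_form()]).
#'
#' @param samples Nonempty numeric vector.
#' @return Scalar `sum(samples^2)`.
#' @export
conventional_energy <- function(samples) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop_invalid("conventional_energy of empty input")
  sum(samples^2)
}
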