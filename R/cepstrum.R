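# The cepstrum baseline. The beat is modelled as action potential convolved
# with an excitation, so in the DCT domain the coefficient magnitudes are the
# product of a smooth system envelope and fine excitation structure. Taking
# logs turns that product into a sum; the low-quefrency part of the log
# sequence is the smooth envelope, which homomorphic (cepstral) low-pass
# liftering isolates.

#' DCT-cepstrum envelope of a beat's coefficient sequence
#'
#' Smooths `log(|X_c[k]| + delta)` with an ideal low-pass lifter of
#' `lifter_length` quefrency bins (kept symmetrically at both ends of the
#' DFT of the log sequence) and exponentiates back, yielding a strictly
#' positive envelope of the DCT magnitude sequence. `delta` is a floor of
#' `1e-12 * max |X_c|` guarding against `log(0)`.
#'
#' @param coeffs A `dct_coefficients` object from [dct_forward()], or a
#'   numeric vector of coefficients.
#' @param lifter_length Quefrency cutoff `L`, `1 <= L <= N/2`. Default 15.
#' @return An object of class `cepstral_envelope`: list with `values`
#'   (positive numeric, length N) and `lifter_length`.
#' @export
#' @examples
#' env <- dct_cepstrum_envelope(dct_forward(generate_beat("pvc")$samples))
#' which.max(env$values)  # dominant low-index peak
dct_cepstrum_envelope <- function(coeffs, lifter_length = 15L) {
  v <- if (inherits(coeffs, "dct_coefficients")) coeffs$values
       else as.numeric(coeffs)
  n <- length(v)
  lifter_length <- as.integer(lifter_length)
  if (lifter_length < 1L || lifter_length > n %/% 2L) {
    stop_invalid("lifter_length must be in [1, N/2] = [1, %d], got %d",
                 n %/% 2L, lifter_length)
  }
  mag <- abs(v)
  delta <- 1e-12 * max(mag)
  if (delta == 0) stop_invalid("all-zero coefficient sequence")
  logmag <- log(mag + delta)
  cep <- stats::fft(logmag)
  keep <- rep(0, n)
  keep[seq_len(lifter_length)] <- 1
  if (lifter_length > 1L) {
    keep[seq.int(n - lifter_length + 2L, n)] <- 1
  }
  smooth <- Re(stats::fft(cep * keep, inverse = TRUE)) / n
  structure(
    list(values = exp(smooth), lifter_length = lifter_length),
    class = "cepstral_envelope"
  )
}

#' @export
print.cepstral_envelope <- function(x, ...) {
  cat(sprintf("<cepstral_envelope> N=%d  L=%d  peak=%.4g at k=%d\n",
              length(x$values), x$lifter_length, max(x$values),
              which.max(x$values) - 1L))
  invisible(x)
}
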