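# Independent oracles and byte-level fixture builders. Everything here is
# deliberately naive (double loops, direct formula evaluation, manual byte
# packing) so it shares no code path with the implementation it checks.

# Orthonormal DCT-II by direct evaluation of the defining double sum.
dct_oracle <- function(x) {
  n <- length(x)
  vapply(0:(n - 1L), function(k) {
    ck <- if (k == 0L) 1 / sqrt(2) else 1
    ck * sqrt(2 / n) * sum(x * cos(pi / n * ((0:(n - 1L)) + 0.5) * k))
  }, numeric(1))
}

# Cepstral envelope by direct DFT double sums (no fft()): smooth
# log(|X| + delta) with an ideal low-pass lifter of L quefrency bins.
cepstrum_oracle <- function(x_coeffs, lifter_length) {
  n <- length(x_coeffs)
  mag <- abs(x_coeffs)
  l <- log(mag + 1e-12 * max(mag))
  dft <- function(v, q) sum(v * exp(-2i * pi * (0:(n - 1L)) * q / n))
  cep <- vapply(0:(n - 1L), function(q) dft(l, q), complex(1))
  keep <- c(0:(lifter_length - 1L),
            if (lifter_length > 1L) (n - lifter_length + 1L):(n - 1L))
  smooth <- vapply(0:(n - 1L), function(k) {
    Re(sum(cep[keep + 1L] * exp(2i * pi * keep * k / n))) / n
  }, numeric(1))
  exp(smooth)
}

# ---- WFDB fixture builders (manual byte packing, format 212) ------------

# Pack an even-length integer ADC stream into format-212 bytes.
pack_format212 <- function(adc) {
  stopifnot(length(adc) %% 2L == 0L, all(adc >= -2048L), all(adc <= 2047L))
  v <- ifelse(adc < 0L, adc + 4096L, adc)
  s1 <- v[seq(1L, length(v), by = 2L)]
  s2 <- v[seq(2L, length(v), by = 2L)]
  as.raw(as.vector(rbind(
    s1 %% 256L,
    (s1 %/% 256L) + 16L * (s2 %/% 256L),
    s2 %% 256L
  )))
}

# One MIT-format annotation word: 6-bit code, 10-bit interval.
ann_word <- function(code, interval) {
  stopifnot(interval >= 0L, interval < 1024L)
  as.raw(c(interval %% 256L, code * 4L + interval %/% 256L))
}

# Write a complete single-channel WFDB record + annotations into `dir`.
# `ann` is a data.frame(sample [0-based], code); gain ADC units per mV.
write_wfdb_fixture <- function(dir, record = "tst", adc, fs = 360,
                               gain = 200, ann = NULL) {
  writeLines(c(
    sprintf("%s 1 %g %d", record, fs, length(adc)),
    sprintf("%s.dat 212 %g 12 0 %d 0 0 MLII", record, gain, adc[1L])
  ), file.path(dir, paste0(record, ".hea")))
  if (length(adc) %% 2L == 1L) adc <- c(adc, 0L)  # pad to a full triplet
  writeBin(pack_format212(adc), file.path(dir, paste0(record, ".dat")))
  if (!is.null(ann)) {
    words <- raw(0)
    t_prev <- 0L
    for (i in seq_len(nrow(ann))) {
      words <- c(words, ann_word(ann$code[i], ann$sample[i] - t_prev))
      t_prev <- ann$sample[i]
    }
    words <- c(words, ann_word(0L, 0L))  # end marker
    writeBin(words, file.path(dir, paste0(record, ".atr")))
  }
  file.path(dir, record)
}

# Default synthetic study set used by several tests (seeded, 5% jitter).
study_set <- function(n = 100L, seed = 0L) {
  generate_beatset(n_normal = n, n_pvc = n, jitter_cv = 0.05, seed = seed)
}
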