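# The three corruptions used for robustness testing: white Gaussian noise at
# a target SNR, 50/60 Hz power-line interference, and ~0.1 Hz baseline
# wander. All are added to the time-domain beat before the DCT, matching the
# pipeline order of the detection method.

#' Add white Gaussian noise at a target SNR
#'
#' Signal power is the mean square over the full beat window,
#' `P = mean(x^2)`; unit-variance Gaussian samples are scaled by
#' `sigma = sqrt(P * 10^(-snr_db/10))` so the realized SNR approaches
#' `snr_db` for long windows.
#'
#' @param samples Numeric vector with nonzero power.
#' @param fs Sampling frequency in Hz (unused; kept for a uniform noise
#'   interface).
#' @param snr_db Target signal-to-noise ratio in dB.
#' @param seed Integer seed for the noise stream; `NULL` draws from the
#'   caller's RNG state.
#' @return Numeric vector `samples + noise`, same length.
#' @export
#' @examples
#' x <- generate_beat("normal")$samples
#' y <- add_gaussian_noise(x, 360, snr_db = 10, seed = 1)
add_gaussian_noise <- function(samples, fs, snr_db, seed = NULL) {
  x <- as.numeric(samples)
  p <- mean(x^2)
  if (p == 0) stop_invalid("zero-power signal: SNR is undefined")
  if (!is.finite(snr_db)) stop_invalid("snr_db must be finite")
  sigma <- sqrt(p * 10^(-snr_db / 10))
  x + sigma * with_seed(seed, stats::rnorm(length(x)))
}

#' Add sinusoidal power-line interference
#'
#' Adds `amplitude * sin(2 pi f0 n / fs + phase)` for `n = 0 ... N-1`,
#' emulating mains pickup through the recording cable.
#'
#' @param samples Numeric vector.
#' @param fs Sampling frequency in Hz.
#' @param f0 Interference frequency in Hz, default 50; must satisfy
#'   `0 < f0 < fs/2`.
#' @param amplitude Interference amplitude in mV, `>= 0`.
#' @param phase Initial phase in radians.
#' @return Numeric vector, same length.
#' @export
add_pli <- function(samples, fs, f0 = 50, amplitude = 0.1, phase = 0) {
  x <- as.numeric(samples)
  if (f0 <= 0 || f0 >= fs / 2) {
    stop_invalid("f0 = %g Hz would alias at fs = %g Hz (need 0 < f0 < fs/2)",
                 f0, fs)
  }
  if (amplitude < 0) stop_invalid("amplitude must be >= 0")
  n <- seq_along(x) - 1
  x + amplitude * sin(2 * pi * f0 * n / fs + phase)
}

#' Add low-frequency baseline wander
#'
#' A slow sinusoid (default 0.1 Hz, e.g. respiration) that shifts the
#' isoelectric line; within a sub-second beat window it is a near-monotone
#' drift. Same construction as [add_pli()] at low `f0`.
#'
#' @inheritParams add_pli
#' @param f0 Wander frequency in Hz, default 0.1.
#' @export
add_baseline_wander <- function(samples, fs, f0 = 0.1, amplitude = 0.1,
                                phase = 0) {
  add_pli(samples, fs = fs, f0 = f0, amplitude = amplitude, phase = phase)
}

#' Specify a beat corruption
#'
#' A serializable description of one corruption, applied with
#' [apply_noise()]. For the relative-amplitude convention used in the
#' comparison harness, set `amplitude = NA` and `amplitude_rel` to a
#' fraction of the beat's peak-to-peak range (defaults there: 0.2 for PLI,
#' 0.5 for baseline wander).
#'
#' @param kind `"gaussian"`, `"pli"` or `"baseline"`.
#' @param snr_db Target SNR in dB (gaussian only).
#' @param f0 Frequency in Hz (pli default 50, baseline default 0.1).
#' @param amplitude Absolute amplitude in mV, or `NA` to use
#'   `amplitude_rel`.
#' @param amplitude_rel Amplitude as a fraction of each beat's peak-to-peak
#'   range.
#' @param phase Initial phase in radians.
#' @param seed Integer seed (gaussian only).
#' @param label Optional condition name used in reports.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(kind = c("gaussian", "pli", "baseline"),
                       snr_db = NULL, f0 = NULL, amplitude = NA,
                       amplitude_rel = NULL, phase = 0, seed = NULL,
                       label = NULL) {
  kind <- match.arg(kind)
  if (kind == "gaussian") {
    if (is.null(snr_db) || !is.finite(snr_db)) {
      stop_invalid("gaussian noise requires a finite snr_db")
    }
  } else {
    if (is.null(f0)) f0 <- if (kind == "pli") 50 else 0.1
    if (is.na(amplitude) && is.null(amplitude_rel)) {
      amplitude_rel <- if (kind == "pli") 0.2 else 0.5
    }
    if (!is.na(amplitude) && amplitude < 0) {
      stop_invalid("amplitude must be >= 0")
    }
  }
  if (is.null(label)) {
    label <- switch(kind,
      gaussian = sprintf("gaussian %g dB", snr_db),
      pli = sprintf("pli %g Hz", f0),
      baseline = sprintf("baseline %g Hz", f0))
  }
  structure(
    list(kind = kind, snr_db = snr_db, f0 = f0, amplitude = amplitude,
         amplitude_rel = amplitude_rel, phase = phase, seed = seed,
         label = label),
    class = "noise_spec"
  )
}

#' @export
print.noise_spec <- function(x, ...) {
  cat(sprintf("<noise_spec> %s\n", x$label))
  invisible(x)
}

#' Apply a corruption to a beat or beat set
#'
#' Deterministic for sinusoidal corruptions; for Gaussian noise all beats
#' of a set are corrupted from a single RNG stream seeded by the spec's
#' seed, so the same spec applied to the same set reproduces bit-for-bit.
#' A relative interference amplitude (`amplitude_rel`) is resolved against
#' the *median* peak-to-peak range of the set: mains pickup and baseline
#' drift are properties of the recording, so one common amplitude is added
#' to every beat rather than an amplitude scaled to each beat's own height.
#' For a single beat the beat's own range is the only reference available.
#'
#' @param x An [ecg_beat()] or [beat_set()].
#' @param spec A [noise_spec()].
#' @return Object of the same class as `x` with corrupted samples.
#' @export
apply_noise <- function(x, spec) {
  if (!inherits(spec, "noise_spec")) stop_invalid("spec must be a noise_spec")
  if (inherits(x, "beat_set")) {
    ref_p2p <- stats::median(vapply(x$beats,
                                    function(b) diff(range(b$samples)),
                                    numeric(1)))
    corrupted <- with_seed(spec$seed, {
      lapply(x$beats,
             function(b) apply_noise_samples(b, spec, seed = NULL,
                                             ref_p2p = ref_p2p))
    })
    out <- beat_set(corrupted, source = paste0(x$source, "+", spec$label))
    return(out)
  }
  if (!inherits(x, "ecg_beat")) stop_invalid("x must be an ecg_beat or beat_set")
  with_seed(spec$seed, apply_noise_samples(x, spec, seed = NULL))
}

apply_noise_samples <- function(beat, spec, seed, ref_p2p = NULL) {
  if (is.null(ref_p2p)) ref_p2p <- diff(range(beat$samples))
  amp <- if (spec$kind == "gaussian") NA else if (!is.na(spec$amplitude)) {
    spec$amplitude
  } else {
    spec$amplitude_rel * ref_p2p
  }
  y <- switch(spec$kind,
    gaussian = add_gaussian_noise(beat$samples, beat$fs, spec$snr_db,
                                  seed = seed),
    pli = add_pli(beat$samples, beat$fs, f0 = spec$f0, amplitude = amp,
                  phase = spec$phase),
    baseline = add_baseline_wander(beat$samples, beat$fs, f0 = spec$f0,
                                   amplitude = amp, phase = spec$phase)
  )
  ecg_beat(y, fs = beat$fs, r_index = beat$r_index, label = beat$label,
           beat_id = beat$beat_id)
}
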