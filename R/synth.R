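# Synthetic single-beat generator. Each morphology is a sum of Gaussian
# waves (amplitude mV, centre s relative to the R peak, width = Gaussian
# sigma in s). The presets are minimal shapes reproducing the contrast the
# classifier exploits: a narrow-QRS normal beat with P and T waves versus
# wide-QRS ectopic morphologies without a P wave. Per-beat variability is
# multiplicative lognormal jitter on amplitudes and widths, so both stay
# positive.

.morphology_presets <- list(
  normal = data.frame(
    wave = c("P", "Q", "R", "S", "T"),
    amplitude = c(0.15, -0.10, 1.00, -0.20, 0.30),
    center = c(-0.200, -0.025, 0.000, 0.025, 0.200),
    width = c(0.025, 0.010, 0.012, 0.010, 0.060)
  ),
  pvc = data.frame(  # wide QRS, no P wave, discordant (inverted) T
    wave = c("R", "S", "T"),
    amplitude = c(1.30, -0.40, -0.35),
    center = c(0.000, 0.060, 0.280),
    width = c(0.035, 0.030, 0.080)
  ),
  paced = data.frame(  # pacing spike followed by a wide evoked complex
    wave = c("spike", "R"),
    amplitude = c(0.80, 1.00),
    center = c(-0.040, 0.010),
    width = c(0.004, 0.030)
  ),
  lbbb = data.frame(  # split QRS, second lobe wider
    wave = c("R1", "R2"),
    amplitude = c(0.90, 0.70),
    center = c(-0.020, 0.040),
    width = c(0.012, 0.030)
  ),
  rbbb = data.frame(  # split QRS, first lobe wider
    wave = c("R1", "R2"),
    amplitude = c(0.70, 0.90),
    center = c(-0.040, 0.020),
    width = c(0.030, 0.012)
  )
)

#' Built-in beat morphologies
#'
#' @param name Optional morphology name; omitted, the full preset list is
#'   returned.
#' @return A data.frame of wave components (`wave`, `amplitude` in mV,
#'   `center` in s relative to the R peak, `width` = Gaussian sigma in s),
#'   or a named list of such data.frames.
#' @export
#' @examples
#' morphology_presets("pvc")
morphology_presets <- function(name = NULL) {
  if (is.null(name)) return(.morphology_presets)
  if (!name %in% names(.morphology_presets)) {
    stop_invalid("unknown morphology '%s' (have: %s)", name,
                 paste(names(.morphology_presets), collapse = ", "))
  }
  .morphology_presets[[name]]
}

validate_morphology <- function(components) {
  need <- c("amplitude", "center", "width")
  if (!is.data.frame(components) || !all(need %in% names(components))) {
    stop_invalid("morphology components need columns %s",
                 paste(need, collapse = ", "))
  }
  if (any(components$width <= 0)) stop_invalid("wave widths must be > 0")
  components
}

#' Generate one synthetic beat
#'
#' Samples `x[n] = sum_c a_c exp(-(t_n - mu_c)^2 / (2 sigma_c^2))` on the
#' window time grid `t_n = (n - W/2) / fs` (R peak at t = 0, 0-based offset
#' `W/2`). With `jitter_cv > 0`, every amplitude and width is multiplied by
#' an independent lognormal factor with unit mean and coefficient of
#' variation `jitter_cv`.
#'
#' @param morphology A preset name (see [morphology_presets()]) or a
#'   component data.frame with columns `amplitude`, `center`, `width`.
#' @param fs Sampling frequency in Hz, default 360 (the MIT-BIH rate).
#' @param window_w Window length in samples; even, `>= 150`; default 256.
#' @param jitter_cv Coefficient of variation of the per-component jitter,
#'   `>= 0`; 0 gives a deterministic beat.
#' @param seed Integer seed for the jitter; `NULL` draws from the caller's
#'   RNG state.
#' @param label Ground-truth label; defaults to the morphology name (or
#'   `"unknown"` for a custom component table).
#' @param beat_id Identifier, defaults to the label.
#' @return An [ecg_beat()].
#' @export
#' @examples
#' b <- generate_beat("pvc", jitter_cv = 0.05, seed = 1)
generate_beat <- function(morphology = "normal", fs = 360, window_w = 256L,
                          jitter_cv = 0, seed = NULL, label = NULL,
                          beat_id = NULL) {
  if (is.character(morphology)) {
    if (is.null(label)) label <- morphology
    components <- morphology_presets(morphology)
  } else {
    if (is.null(label)) label <- "unknown"
    components <- morphology
  }
  components <- validate_morphology(components)
  window_w <- as.integer(window_w)
  if (window_w %% 2L != 0L || window_w < 150L) {
    stop_invalid("window_w must be even and >= 150, got %d", window_w)
  }
  if (jitter_cv < 0) stop_invalid("jitter_cv must be >= 0")
  if (is.null(beat_id)) beat_id <- label

  n_comp <- nrow(components)
  if (jitter_cv > 0) {
    sdlog <- sqrt(log(1 + jitter_cv^2))
    meanlog <- -sdlog^2 / 2  # unit-mean lognormal
    fac <- with_seed(seed, stats::rlnorm(2L * n_comp, meanlog, sdlog))
    amp <- components$amplitude * fac[seq_len(n_comp)]
    wid <- components$width * fac[n_comp + seq_len(n_comp)]
  } else {
    amp <- components$amplitude
    wid <- components$width
  }
  t_n <- (seq_len(window_w) - 1L - window_w %/% 2L) / fs
  x <- numeric(window_w)
  for (i in seq_len(n_comp)) {
    x <- x + amp[i] * exp(-(t_n - components$center[i])^2 / (2 * wid[i]^2))
  }
  ecg_beat(x, fs = fs, r_index = window_w %/% 2L, label = label,
           beat_id = beat_id)
}

#' Generate a labelled synthetic beat set
#'
#' Generates `n_normal` normal and `n_pvc` PVC beats plus, when
#' `n_other_per_class > 0`, that many paced, LBBB and RBBB beats each, all
#' with independent jitter from a single RNG stream, then shuffles the set
#' with the same stream. Deterministic given `seed`.
#'
#' @param n_normal,n_pvc,n_other_per_class Beat counts, `>= 0`.
#' @param fs,window_w,jitter_cv As in [generate_beat()]; `jitter_cv`
#'   defaults to 0.05.
#' @param seed Integer seed, default 0.
#' @return A [beat_set()] with source `"synthetic"`; beat ids are
#'   `<label>-<index>`.
#' @export
#' @examples
#' set <- generate_beatset(10, 10, seed = 0)
#' table(beat_labels(set))
generate_beatset <- function(n_normal = 100L, n_pvc = 100L,
                             n_other_per_class = 0L, fs = 360,
                             window_w = 256L, jitter_cv = 0.05, seed = 0L) {
  counts <- c(normal = as.integer(n_normal), pvc = as.integer(n_pvc),
              paced = as.integer(n_other_per_class),
              lbbb = as.integer(n_other_per_class),
              rbbb = as.integer(n_other_per_class))
  if (any(counts < 0L)) stop_invalid("beat counts must be >= 0")
  beats <- with_seed(seed, {
    out <- list()
    for (name in names(counts)) {
      for (i in seq_len(counts[[name]])) {
        out[[length(out) + 1L]] <- generate_beat(
          name, fs = fs, window_w = window_w, jitter_cv = jitter_cv,
          seed = NULL, beat_id = sprintf("%s-%03d", name, i)
        )
      }
    }
    if (length(out) > 1L) out <- out[sample.int(length(out))]
    out
  })
  beat_set(beats, source = "synthetic")
}
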