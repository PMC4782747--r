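#' Beat labels understood by the package
#'
#' @return Character vector of valid beat labels.
#' @export
beat_labels_known <- function() {
  c("normal", "pvc", "paced", "lbbb", "rbbb", "unknown")
}

#' Construct a single ECG beat
#'
#' A beat is a fixed-length window of ECG samples (in mV) centred on its
#' R peak. Downstream energy-packing analysis truncates envelopes at 150
#' coefficients, so windows must hold at least 150 samples.
#'
#' @param samples Numeric vector of ECG samples, in mV. Length `W >= 150`.
#' @param fs Sampling frequency in Hz (positive scalar).
#' @param r_index 0-based offset of the R-peak sample within the window
#'   (`0 <= r_index < W`). Windows cut by [extract_beats()] have
#'   `r_index = W/2`.
#' @param label Ground-truth beat label, one of [beat_labels_known()].
#' @param beat_id Opaque identifier string.
#'
#' @return An object of class `ecg_beat`: a list with fields `samples`,
#'   `fs`, `r_index`, `label`, `beat_id`.
#' @export
#' @examples
#' b <- ecg_beat(sin(seq(0, pi, length.out = 256)), fs = 360)
#' b
ecg_beat <- function(samples, fs, r_index = length(samples) %/% 2,
                     label = "unknown", beat_id = "beat") {
  samples <- as.numeric(samples)
  w <- length(samples)
  if (w < 150) {
    stop_invalid("beat window must hold >= 150 samples, got %d", w)
  }
  if (anyNA(samples) || any(!is.finite(samples))) {
    stop_invalid("beat samples must be finite")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop_invalid("fs must be a positive scalar (Hz)")
  }
  r_index <- as.integer(r_index)
  if (r_index < 0L || r_index >= w) {
    stop_invalid("r_index must satisfy 0 <= r_index < %d, got %d", w, r_index)
  }
  label <- match.arg(label, beat_labels_known())
  structure(
    list(samples = samples, fs = as.numeric(fs), r_index = r_index,
         label = label, beat_id = as.character(beat_id)),
    class = "ecg_beat"
  )
}

#' @export
print.ecg_beat <- function(x, ...) {
  cat(sprintf("<ecg_beat %s> label=%s  W=%d  fs=%g Hz  r_index=%d  range=[%.3g, %.3g] mV\n",
              x$beat_id, x$label, length(x$samples), x$fs, x$r_index,
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' Construct an ordered collection of beats
#'
#' All beats in a set share the same sampling frequency and window length.
#'
#' @param beats List of [ecg_beat()] objects.
#' @param source Provenance string, e.g. `"synthetic"`, `"csv:<path>"`,
#'   `"wfdb:<record>"`.
#'
#' @return An object of class `beat_set`.
#' @export
beat_set <- function(beats = list(), source = "unknown") {
  if (!is.list(beats) || !all(vapply(beats, inherits, logical(1), "ecg_beat"))) {
    stop_invalid("beats must be a list of ecg_beat objects")
  }
  if (length(beats) > 1L) {
    w <- vapply(beats, function(b) length(b$samples), integer(1))
    fs <- vapply(beats, function(b) b$fs, numeric(1))
    if (length(unique(w)) != 1L) {
      stop_invalid("all beats in a set must share the window length")
    }
    if (length(unique(fs)) != 1L) {
      stop_invalid("all beats in a set must share the sampling frequency")
    }
  }
  structure(list(beats = beats, source = as.character(source)),
            class = "beat_set")
}

#' @export
length.beat_set <- function(x) length(x$beats)

#' @export
`[.beat_set` <- function(x, i) beat_set(x$beats[i], source = x$source)

#' @export
`[[.beat_set` <- function(x, i) x$beats[[i]]

#' @export
print.beat_set <- function(x, ...) {
  n <- length(x)
  cat(sprintf("<beat_set> %d beats, source=%s\n", n, x$source))
  if (n > 0L) {
    tab <- table(beat_labels(x))
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
    cat(sprintf("  W=%d  fs=%g Hz\n", length(x$beats[[1L]]$samples),
                x$beats[[1L]]$fs))
  }
  invisible(x)
}

#' Ground-truth labels of a beat set
#'
#' @param set A [beat_set()].
#' @return Character vector of labels, one per beat, in set order.
#' @export
beat_labels <- function(set) {
  vapply(set$beats, function(b) b$label, character(1))
}

#' Beat identifiers of a beat set
#'
#' @param set A [beat_set()].
#' @return Character vector of beat ids, in set order.
#' @export
beat_ids <- function(set) {
  vapply(set$beats, function(b) b$beat_id, character(1))
}

#' Samples of a beat set as a matrix
#'
#' @param set A non-empty [beat_set()].
#' @return A `W x n` numeric matrix, one column per beat.
#' @export
beat_matrix <- function(set) {
  if (length(set) == 0L) stop_invalid("empty beat set")
  vapply(set$beats, function(b) b$samples,
         numeric(length(set$beats[[1L]]$samples)))
}

#' Cut fixed-length beat windows out of a continuous signal
#'
#' Windows are half-open around each annotated R peak: `W/2` samples before
#' the R sample and `W/2` samples from the R sample on, so the R peak sits at
#' 0-based offset `W/2` of the window. R peaks closer than `W/2` samples to
#' either end of the signal cannot yield a full window and are skipped; the
#' skip count is attached to the result.
#'
#' @param signal Numeric vector, the continuous ECG recording in mV.
#' @param fs Sampling frequency in Hz.
#' @param r_locations Integer vector of R-peak positions, 1-based sample
#'   indices into `signal`, sorted increasing.
#' @param window_w Window length in samples; even, `>= 150`.
#' @param labels Optional character vector of per-location labels (recycled
#'   `"unknown"` when missing).
#'
#' @return A [beat_set()] with attribute `skipped` (integer count of
#'   R locations too close to a signal edge) and `skipped_at` (their 1-based
#'   positions).
#' @export
#' @examples
#' sig <- as.numeric(0:999)
#' set <- extract_beats(sig, fs = 360, r_locations = 501, window_w = 256)
#' set[[1]]$samples[129]  # the R sample
extract_beats <- function(signal, fs, r_locations, window_w = 256,
                          labels = NULL) {
  signal <- as.numeric(signal)
  window_w <- as.integer(window_w)
  if (window_w %% 2L != 0L || window_w < 150L) {
    stop_invalid("window_w must be even and >= 150, got %d", window_w)
  }
  r_locations <- as.integer(r_locations)
  if (is.unsorted(r_locations)) {
    stop_invalid("r_locations must be sorted increasing")
  }
  if (length(r_locations) > 0L &&
      (min(r_locations) < 1L || max(r_locations) > length(signal))) {
    stop_invalid("r_locations must lie within the signal")
  }
  if (is.null(labels)) {
    labels <- rep("unknown", length(r_locations))
  } else if (length(labels) != length(r_locations)) {
    stop_invalid("labels must match r_locations in length")
  }

  half <- window_w %/% 2L
  beats <- list()
  skipped_at <- integer(0)
  for (i in seq_along(r_locations)) {
    r <- r_locations[i]
    lo <- r - half          # 1-based start of window
    hi <- r + half - 1L     # 1-based end of window
    if (lo < 1L || hi > length(signal)) {
      skipped_at <- c(skipped_at, r)
      next
    }
    beats[[length(beats) + 1L]] <- ecg_beat(
      signal[lo:hi], fs = fs, r_index = half, label = labels[i],
      beat_id = sprintf("r%d", r)
    )
  }
  out <- beat_set(beats, source = "extracted")
  attr(out, "skipped") <- length(skipped_at)
  attr(out, "skipped_at") <- skipped_at
  out
}
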