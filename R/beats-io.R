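# Beat CSV dialect: header `beat_id,label,fs,r_index,s0,...,s{W-1}`,
# one row per beat, samples in mV written with 17 significant digits so the
# doubles round-trip exactly. r_index is the 0-based R-peak offset.

#' Write a beat set to CSV
#'
#' @param set A [beat_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_beats_csv()]
#' @export
write_beats_csv <- function(set, path) {
  if (!inherits(set, "beat_set")) stop_invalid("set must be a beat_set")
  if (length(set) == 0L) stop_invalid("refusing to write an empty beat set")
  w <- length(set$beats[[1L]]$samples)
  header <- paste(c("beat_id", "label", "fs", "r_index",
                    paste0("s", seq_len(w) - 1L)), collapse = ",")
  rows <- vapply(set$beats, function(b) {
    paste(c(b$beat_id, b$label, sprintf("%.17g", b$fs), b$r_index,
            sprintf("%.17g", b$samples)), collapse = ",")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a beat set from CSV
#'
#' Parses the beat CSV dialect written by [write_beats_csv()]. Malformed
#' input (wrong header, ragged rows, non-numeric samples, window shorter
#' than 150 samples) raises an error naming the offending line.
#'
#' @param path Input file path.
#' @return A [beat_set()] with source `"csv:<path>"`.
#' @export
read_beats_csv <- function(path) {
  if (!file.exists(path)) stop_invalid("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) stop_invalid("parse error in %s: empty file", path)
  header <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  if (length(header) < 5L ||
      !identical(header[1:4], c("beat_id", "label", "fs", "r_index"))) {
    stop_invalid("parse error in %s line 1: malformed header", path)
  }
  w <- length(header) - 4L
  if (!identical(header[-(1:4)], paste0("s", seq_len(w) - 1L))) {
    stop_invalid("parse error in %s line 1: sample columns must be s0..s%d",
                 path, w - 1L)
  }
  if (w < 150L) {
    stop_invalid("invalid beat window in %s: W = %d < 150", path, w)
  }
  if (length(lines) < 2L) {
    stop_invalid("parse error in %s: no beat rows", path)
  }
  beats <- vector("list", length(lines) - 1L)
  for (i in seq.int(2L, length(lines))) {
    fields <- strsplit(lines[i], ",", fixed = TRUE)[[1L]]
    if (length(fields) != w + 4L) {
      stop_invalid("parse error in %s line %d: expected %d fields, got %d",
                   path, i, w + 4L, length(fields))
    }
    num <- suppressWarnings(as.numeric(fields[-(1:2)]))
    if (anyNA(num)) {
      stop_invalid("parse error in %s line %d: non-numeric value", path, i)
    }
    beats[[i - 1L]] <- ecg_beat(num[-(1:2)], fs = num[1L], r_index = num[2L],
                                label = fields[2L], beat_id = fields[1L])
  }
  beat_set(beats, source = paste0("csv:", path))
}
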