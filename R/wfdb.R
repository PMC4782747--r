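# Minimal read-only WFDB support: format-212 signal files and MIT-format
# beat annotations, enough to window user-supplied arrhythmia records around
# their annotated R peaks. Nothing is ever downloaded.

wfdb_annotation_map <- c(
  "1"  = "normal",  # N
  "2"  = "lbbb",    # L
  "3"  = "rbbb",    # R
  "5"  = "pvc",     # V
  "12" = "paced"    # /
)

# Parse a WFDB .hea file. Returns list(record, n_sig, fs, n_samp, signals)
# where signals is a data.frame with file, format, gain, baseline.
read_wfdb_header <- function(hea_path) {
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  rec <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (length(rec) < 3L) stop_invalid("malformed WFDB header: %s", hea_path)
  n_sig <- as.integer(rec[2L])
  fs <- as.numeric(strsplit(rec[3L], "/", fixed = TRUE)[[1L]][1L])
  n_samp <- if (length(rec) >= 4L) as.integer(rec[4L]) else NA_integer_
  sig <- lapply(lines[seq_len(n_sig) + 1L], function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1L]]
    fmt <- as.integer(sub("[x:+].*$", "", f[2L]))  # strip skew/offset suffixes
    gain_field <- if (length(f) >= 3L) f[3L] else "200"
    gain_num <- sub("\\(.*$", "", sub("/.*$", "", gain_field))
    gain <- as.numeric(gain_num)
    if (!is.finite(gain) || gain == 0) gain <- 200  # WFDB default
    baseline <- if (grepl("\\(", gain_field)) {
      as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_field))
    } else if (length(f) >= 5L) {
      as.numeric(f[5L])  # adczero
    } else 0
    data.frame(file = f[1L], format = fmt, gain = gain, baseline = baseline,
               stringsAsFactors = FALSE)
  })
  list(record = rec[1L], n_sig = n_sig, fs = fs, n_samp = n_samp,
       signals = do.call(rbind, sig))
}

# Unpack a format-212 byte stream into the interleaved sample stream.
# Each 3-byte group holds two 12-bit two's-complement samples.
decode_format212 <- function(bytes) {
  n_groups <- length(bytes) %/% 3L
  b <- matrix(as.integer(bytes[seq_len(3L * n_groups)]), nrow = 3L)
  s1 <- b[1L, ] + bitwShiftL(bitwAnd(b[2L, ], 0x0FL), 8L)
  s2 <- b[3L, ] + bitwShiftL(bitwAnd(bitwShiftR(b[2L, ], 4L), 0x0FL), 8L)
  out <- as.vector(rbind(s1, s2))
  ifelse(out > 2047L, out - 4096L, out)
}

# Parse a MIT-format annotation file. Returns data.frame(sample, code) with
# 0-based sample times of time-advancing annotations.
read_wfdb_annotations <- function(atr_path) {
  bytes <- as.integer(readBin(atr_path, "raw", n = file.size(atr_path)))
  samples <- integer(0)
  codes <- integer(0)
  t <- 0
  i <- 1L
  while (i + 1L <= length(bytes)) {
    b0 <- bytes[i]; b1 <- bytes[i + 1L]
    code <- bitwShiftR(b1, 2L)
    interval <- bitwShiftL(bitwAnd(b1, 0x03L), 8L) + b0
    i <- i + 2L
    if (code == 0L && interval == 0L) break      # end of file
    if (code == 59L) {                            # SKIP: 4-byte long interval
      if (i + 3L > length(bytes)) break
      high <- bytes[i] + bitwShiftL(bytes[i + 1L], 8L)
      low <- bytes[i + 2L] + bitwShiftL(bytes[i + 3L], 8L)
      t <- t + high * 65536 + low
      i <- i + 4L
    } else if (code %in% c(60L, 61L, 62L)) {      # NUM / SUB / CHN: no time
    } else if (code == 63L) {                     # AUX: skip payload (+ pad)
      i <- i + interval + interval %% 2L
    } else {
      t <- t + interval
      samples <- c(samples, t)
      codes <- c(codes, code)
    }
  }
  data.frame(sample = samples, code = codes)
}

#' Import beats from a user-supplied WFDB record
#'
#' Reads a local WFDB `.hea`/`.dat` pair (signal format 212, the format of
#' the MIT-BIH Arrhythmia Database) plus a MIT-format annotation file, and
#' windows channel 1 around every annotated beat. Annotation codes are
#' mapped N -> normal, V -> pvc, / -> paced, L -> lbbb, R -> rbbb; any other
#' code becomes `unknown` with a warning. Annotations closer than
#' `window_w/2` samples to either end of the record are skipped, as in
#' [extract_beats()]. This function never downloads data.
#'
#' @param record_path Path to the record, with or without the `.hea`
#'   extension.
#' @param annotation_path Path to the annotation file (e.g. `<record>.atr`).
#' @param window_w Window length in samples; even, `>= 150`.
#' @param channel 1-based signal channel to use; default 1 (MLII in MIT-BIH).
#' @return A [beat_set()] with source `"wfdb:<record>"`, samples in mV.
#' @export
import_wfdb_record <- function(record_path, annotation_path, window_w = 256,
                               channel = 1L) {
  hea_path <- if (grepl("\\.hea$", record_path)) record_path
              else paste0(record_path, ".hea")
  if (!file.exists(hea_path)) stop_invalid("no such file: %s", hea_path)
  if (!file.exists(annotation_path)) {
    stop_invalid("no such file: %s", annotation_path)
  }
  hdr <- read_wfdb_header(hea_path)
  if (channel < 1L || channel > hdr$n_sig) {
    stop_invalid("record has %d signals; channel %d requested",
                 hdr$n_sig, channel)
  }
  if (any(hdr$signals$format != 212L)) {
    stop_invalid("only WFDB signal format 212 is supported")
  }
  dat_path <- file.path(dirname(hea_path), hdr$signals$file[channel])
  if (!file.exists(dat_path)) stop_invalid("no such file: %s", dat_path)
  stream <- decode_format212(readBin(dat_path, "raw", n = file.size(dat_path)))
  adc <- stream[seq.int(channel, length(stream), by = hdr$n_sig)]
  if (!is.na(hdr$n_samp)) adc <- adc[seq_len(min(hdr$n_samp, length(adc)))]
  mv <- (adc - hdr$signals$baseline[channel]) / hdr$signals$gain[channel]

  ann <- read_wfdb_annotations(annotation_path)
  labels <- unname(wfdb_annotation_map[as.character(ann$code)])
  if (anyNA(labels)) {
    warning(sprintf("%d annotation(s) with unsupported codes labelled 'unknown'",
                    sum(is.na(labels))))
    labels[is.na(labels)] <- "unknown"
  }
  out <- extract_beats(mv, fs = hdr$fs, r_locations = ann$sample + 1L,
                       window_w = window_w, labels = labels)
  out$source <- paste0("wfdb:", hdr$record)
  out
}
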