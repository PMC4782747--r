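# Detection performance. PVC is the positive class; every other true label
# counts as negative. Sensitivity Se = 100*TP/(TP+FN), positive
# predictivity +P = 100*TP/(TP+FP), detection error rate
# DER = 100*(FP+FN)/total beats.

#' Evaluate PVC detection performance
#'
#' @param predictions A data.frame from [classify_beatset()] (needs columns
#'   `predicted_label` and, unless `truth` is given, `true_label`).
#' @param truth Optional character vector of true labels aligned with
#'   `predictions`; defaults to the `true_label` column.
#' @return An object of class `performance_report`: counts `tp`, `fp`,
#'   `fn`, `tn`, `total_beats`; percentages `sensitivity`,
#'   `positive_predictivity`, `detection_error_rate` (NaN with the matching
#'   `*_defined` flag set to FALSE when a denominator is zero); `method` and
#'   `threshold` carried over when unique in `predictions`.
#' @export
#' @examples
#' set <- generate_beatset(20, 20, seed = 1)
#' evaluate_detection(classify_beatset(set, "teo"))
evaluate_detection <- function(predictions, truth = NULL) {
  if (NROW(predictions) == 0L) stop_invalid("no predictions to evaluate")
  if (is.null(truth)) {
    if (is.null(predictions$true_label)) {
      stop_invalid("predictions carry no true_label and no truth was given")
    }
    truth <- predictions$true_label
  }
  if (length(truth) != nrow(predictions)) {
    stop_invalid("truth must align with predictions (%d vs %d)",
                 length(truth), nrow(predictions))
  }
  pred_pvc <- predictions$predicted_label == "pvc"
  true_pvc <- truth == "pvc"
  tp <- sum(pred_pvc & true_pvc)
  fp <- sum(pred_pvc & !true_pvc)
  fn <- sum(!pred_pvc & true_pvc)
  tn <- sum(!pred_pvc & !true_pvc)
  total <- length(truth)
  structure(
    list(
      tp = tp, fp = fp, fn = fn, tn = tn, total_beats = total,
      sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NaN,
      sensitivity_defined = tp + fn > 0,
      positive_predictivity = if (tp + fp > 0) 100 * tp / (tp + fp) else NaN,
      positive_predictivity_defined = tp + fp > 0,
      detection_error_rate = 100 * (fp + fn) / total,
      method = if (length(unique(predictions$method)) == 1L)
        predictions$method[1L] else NA_character_,
      threshold = if (length(unique(predictions$threshold)) == 1L)
        predictions$threshold[1L] else NA_integer_
    ),
    class = "performance_report"
  )
}

#' @export
print.performance_report <- function(x, digits = 2, ...) {
  fmt <- function(v, def) if (def) formatC(v, digits = digits, format = "f")
                          else "undefined"
  cat(sprintf("<performance_report> method=%s threshold=%s\n",
              x$method, format(x$threshold)))
  cat(sprintf("  PVCs %d  TP %d  FP %d  FN %d  (total beats %d)\n",
              x$tp + x$fn, x$tp, x$fp, x$fn, x$total_beats))
  cat(sprintf("  Se %s%%  +P %s%%  DER %s%%\n",
              fmt(x$sensitivity, x$sensitivity_defined),
              fmt(x$positive_predictivity, x$positive_predictivity_defined),
              formatC(x$detection_error_rate, digits = digits, format = "f")))
  invisible(x)
}

#' @export
as.data.frame.performance_report <- function(x, ...) {
  data.frame(method = x$method, threshold = x$threshold, tp = x$tp,
             fp = x$fp, fn = x$fn, total_beats = x$total_beats,
             sensitivity = x$sensitivity,
             positive_predictivity = x$positive_predictivity,
             detection_error_rate = x$detection_error_rate,
             stringsAsFactors = FALSE)
}

#' Compare the Teager and cepstrum methods across noise conditions
#'
#' Classifies the set with each method under the clean condition and under
#' each supplied corruption, reporting per-class decay-rate ranges alongside
#' the performance measures. Decay-rate ranges are reported both as 0-based
#' indices (`*_min`/`*_max`) and as coefficient counts (`+1`), since
#' published tables may use either convention.
#'
#' @param set A [beat_set()] with ground-truth labels.
#' @param methods Methods to run, default both.
#' @param thresholds Named integer vector of per-method thresholds; defaults
#'   to [default_threshold()] for each.
#' @param noise_specs List of [noise_spec()] objects (possibly empty).
#' @param lifter_length Cepstrum lifter cutoff.
#' @return A data.frame with one row per method x condition.
#' @export
#' @examples
#' set <- generate_beatset(20, 20, seed = 0)
#' compare_methods(set, noise_specs = list(noise_spec("pli")))
compare_methods <- function(set, methods = c("teo", "cepstrum"),
                            thresholds = NULL, noise_specs = list(),
                            lifter_length = 15L) {
  if (length(set) == 0L) stop_invalid("empty beat set")
  conditions <- c(list(clean = NULL),
                  stats::setNames(noise_specs,
                                  vapply(noise_specs, `[[`, "", "label")))
  rows <- list()
  for (cond_name in names(conditions)) {
    spec <- conditions[[cond_name]]
    cond_set <- if (is.null(spec)) set else apply_noise(set, spec)
    for (method in methods) {
      thr <- if (!is.null(thresholds) && method %in% names(thresholds)) {
        thresholds[[method]]
      } else {
        default_threshold(method)
      }
      cls <- classify_beatset(cond_set, method = method, threshold = thr,
                              lifter_length = lifter_length)
      rep <- evaluate_detection(cls)
      is_pvc <- cls$true_label == "pvc"
      rng <- function(v) if (length(v)) range(v) else c(NA_integer_, NA_integer_)
      pvc_rng <- rng(cls$decay_rate[is_pvc])
      nrm_rng <- rng(cls$decay_rate[cls$true_label == "normal"])
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond_name, method = method, threshold = thr,
        pvc_min = pvc_rng[1L], pvc_max = pvc_rng[2L],
        normal_min = nrm_rng[1L], normal_max = nrm_rng[2L],
        pvc_count_min = pvc_rng[1L] + 1L, pvc_count_max = pvc_rng[2L] + 1L,
        normal_count_min = nrm_rng[1L] + 1L,
        normal_count_max = nrm_rng[2L] + 1L,
        mean_pvc_decay = mean(cls$decay_rate[is_pvc]),
        sensitivity = rep$sensitivity,
        positive_predictivity = rep$positive_predictivity,
        detection_error_rate = rep$detection_error_rate,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
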