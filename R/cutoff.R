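#' Confusion-matrix metrics at a fixed cutoff
#'
#' Classifies each patient as predicted-to-die using a strict inequality in
#' the severe direction: for `"higher"` orientation a value *above* the
#' cutoff is a positive prediction, for `"lower"` a value *below* it (the
#' printed directions of the optimal-cutoff table, e.g. `NISS > 24`,
#' `RTS < 7.81`). Reports sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, accuracy `(TP+TN)/N`, positive and negative predictive
#' values and the Youden index `J = sensitivity + specificity - 1`. An empty
#' predicted-positive (or -negative) margin makes PPV (NPV) undefined; it is
#' reported as `NaN` with a warning, never as 0 or 1.
#'
#' @inheritParams roc_points
#' @param cutoff score value on the original scale.
#' @return one-row data frame with columns `cutoff`, `orientation`,
#'   `sensitivity`, `specificity`, `accuracy`, `ppv`, `npv`, `youden_j`,
#'   `tp`, `fn`, `fp`, `tn`.
#' @export
cutoff_metrics <- function(values, events, cutoff, orientation = "higher") {
  events <- check_roc_input(values, events)
  orientation <- normalize_orientation(orientation)
  ov <- orient_values(values, orientation)
  oc <- if (orientation == "lower") -cutoff else cutoff
  pred <- ov > oc
  tp <- sum(pred & events); fn <- sum(!pred & events)
  fp <- sum(pred & !events); tn <- sum(!pred & !events)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  acc <- (tp + tn) / length(events)
  if (tp + fp == 0L) {
    warning("no predicted positives at this cutoff; PPV undefined")
    ppv <- NaN
  } else ppv <- tp / (tp + fp)
  if (tn + fn == 0L) {
    warning("no predicted negatives at this cutoff; NPV undefined")
    npv <- NaN
  } else npv <- tn / (tn + fn)
  data.frame(cutoff = cutoff, orientation = orientation,
             sensitivity = sens, specificity = spec, accuracy = acc,
             ppv = ppv, npv = npv, youden_j = sens + spec - 1,
             tp = tp, fn = fn, fp = fp, tn = tn,
             stringsAsFactors = FALSE)
}

#' Youden-index optimal cutoff
#'
#' Scans every achievable operating point and returns the cutoff maximising
#' the Youden index `J = sensitivity + specificity - 1` (the vertical
#' distance between the ROC curve and the chance diagonal). Candidate
#' cutoffs are the midpoints between consecutive distinct observed values
#' plus one point beyond each extreme, so every achievable confusion table
#' is reachable under the strict-inequality classification rule of
#' [cutoff_metrics()]. Ties in J are broken toward the higher-specificity
#' cutoff (fewer false positives).
#'
#' @inheritParams roc_points
#' @return one-row data frame in the format of [cutoff_metrics()].
#' @export
youden_optimal_cutoff <- function(values, events, orientation = "higher") {
  events <- check_roc_input(values, events)
  orientation <- normalize_orientation(orientation)
  ov <- orient_values(values, orientation)
  v <- sort(unique(ov))
  cand <- c(v[1] - 1, if (length(v) > 1) (v[-1] + v[-length(v)]) / 2,
            v[length(v)] + 1)
  case_sorted <- sort(ov[events])
  ctrl_sorted <- sort(ov[!events])
  m <- length(case_sorted); n <- length(ctrl_sorted)
  # positives are strictly above the candidate cutoff
  tp <- m - findInterval(cand, case_sorted)
  fp <- n - findInterval(cand, ctrl_sorted)
  sens <- tp / m
  spec <- (n - fp) / n
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)
  best <- best[which.max(spec[best])]
  cutoff <- if (orientation == "lower") -cand[best] else cand[best]
  cutoff_metrics(values, events, cutoff, orientation)
}

#' Accuracy, PPV and NPV from sensitivity, specificity and prevalence
#'
#' The analytic identities linking a test's error rates to its predictive
#' values at a given event prevalence `p`:
#' `accuracy = sens * p + spec * (1 - p)`,
#' `PPV = sens * p / (sens * p + (1 - spec)(1 - p))`,
#' `NPV = spec * (1 - p) / (spec * (1 - p) + (1 - sens) * p)`.
#' A zero denominator makes the corresponding value undefined (`NaN`, with
#' a warning). Fed the empirical sensitivity, specificity and prevalence of
#' a confusion table, these reproduce its accuracy, PPV and NPV exactly.
#'
#' @param sensitivity,specificity,prevalence fractions in \[0, 1\].
#' @return list with numeric elements `accuracy`, `ppv`, `npv` (vectorised
#'   over the inputs).
#' @export
#' @examples
#' metrics_from_rates(0.866, 0.743, 239 / 2208)
metrics_from_rates <- function(sensitivity, specificity, prevalence) {
  args <- c(sensitivity, specificity, prevalence)
  if (anyNA(args) || any(args < 0 | args > 1)) {
    stop("all arguments must be fractions in [0, 1]", call. = FALSE)
  }
  p <- prevalence
  acc <- sensitivity * p + specificity * (1 - p)
  ppv_den <- sensitivity * p + (1 - specificity) * (1 - p)
  npv_den <- specificity * (1 - p) + (1 - sensitivity) * p
  if (any(ppv_den == 0)) warning("PPV undefined: no positives at these rates")
  if (any(npv_den == 0)) warning("NPV undefined: no negatives at these rates")
  list(accuracy = acc,
       ppv = ifelse(ppv_den == 0, NaN, sensitivity * p / ppv_den),
       npv = ifelse(npv_den == 0, NaN, specificity * (1 - p) / npv_den))
}
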