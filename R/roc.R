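# Orientation handling: every score is analysed as a predictor of death.
# NISS rises with severity ("higher" orientation); RTS and the two survival
# probabilities fall with severity ("lower"). Internally a "lower" score is
# negated once so all downstream code can assume higher = more likely to die.

normalize_orientation <- function(orientation) {
  map <- c(higher = "higher", lower = "lower",
           higher_predicts_event = "higher", lower_predicts_event = "lower")
  if (length(orientation) != 1L || !orientation %in% names(map)) {
    stop("orientation must be 'higher' or 'lower'", call. = FALSE)
  }
  unname(map[[orientation]])
}

orient_values <- function(values, orientation) {
  if (normalize_orientation(orientation) == "lower") -values else values
}

check_roc_input <- function(values, events, min_each = 1L) {
  events <- as.logical(events)
  if (length(values) != length(events)) {
    stop("values and events must have equal length", call. = FALSE)
  }
  if (anyNA(values) || anyNA(events)) {
    stop("values and events must not contain missing values", call. = FALSE)
  }
  m <- sum(events); n <- sum(!events)
  if (m < min_each) stop("degenerate input: fewer than ", min_each,
                         " event case(s)", call. = FALSE)
  if (n < min_each) stop("degenerate input: fewer than ", min_each,
                         " non-event case(s)", call. = FALSE)
  events
}

#' Empirical ROC curve
#'
#' Computes the empirical receiver operating characteristic curve of a score
#' against a binary event (in-hospital death). Every distinct observed score
#' value is a threshold; tied values are grouped, so ties appear as diagonal
#' segments. The curve always starts at (0, 0) (threshold above all values)
#' and ends at (1, 1).
#'
#' @param values numeric score vector.
#' @param events logical (or 0/1) event indicator, `TRUE` = death.
#' @param orientation `"higher"` if larger scores predict the event (NISS),
#'   `"lower"` if smaller scores do (RTS, survival probabilities).
#' @return data frame with columns `threshold` (on the original score scale;
#'   the (0,0) anchor has threshold `Inf` for `"higher"`, `-Inf` for
#'   `"lower"`), `tpr` and `fpr`; sensitivity at a row is the fraction of
#'   events at or beyond its threshold in the severe direction.
#' @export
roc_points <- function(values, events, orientation = "higher") {
  events <- check_roc_input(values, events)
  orientation <- normalize_orientation(orientation)
  ov <- orient_values(values, orientation)
  m <- sum(events); n <- sum(!events)
  o <- order(ov, decreasing = TRUE)
  ov_sorted <- ov[o]
  ev_sorted <- events[o]
  last_of_tie <- c(ov_sorted[-1] != ov_sorted[-length(ov_sorted)], TRUE)
  tp <- cumsum(ev_sorted)[last_of_tie]
  fp <- cumsum(!ev_sorted)[last_of_tie]
  thr <- ov_sorted[last_of_tie]
  out <- data.frame(
    threshold = c(Inf, if (orientation == "lower") -thr else thr),
    tpr = c(0, tp / m),
    fpr = c(0, fp / n)
  )
  if (orientation == "lower") out$threshold[1] <- -Inf
  out
}

#' AUC as a concordance probability
#'
#' Probability that a randomly chosen event case is ranked more severe than
#' a randomly chosen non-event case, ties counted one half. Equals the
#' trapezoidal area under [roc_points()].
#'
#' @inheritParams roc_points
#' @return a single number in \[0, 1\].
#' @export
auc_concordance <- function(values, events, orientation = "higher") {
  events <- check_roc_input(values, events)
  ov <- orient_values(values, orientation)
  m <- sum(events); n <- sum(!events)
  r <- rank(ov)  # midranks handle ties as half-concordances
  (sum(r[events]) - m * (m + 1) / 2) / (m * n)
}

# DeLong placement components via midranks (no m x n matrix).
# Returns list(auc, v10 [length m], v01 [length n]).
delong_components <- function(ov, events) {
  x <- ov[events]; y <- ov[!events]
  m <- length(x); n <- length(y)
  tz <- rank(c(x, y))
  tx <- rank(x)
  ty <- rank(y)
  v10 <- (tz[seq_len(m)] - tx) / n
  v01 <- 1 - (tz[m + seq_len(n)] - ty) / m
  list(auc = (sum(tz[seq_len(m)]) - m * (m + 1) / 2) / (m * n),
       v10 = v10, v01 = v01)
}

#' AUC with DeLong standard error and confidence interval
#'
#' Point estimate from [auc_concordance()]; the standard error comes from
#' the DeLong nonparametric structural components (per-case placement
#' values), and the interval is the normal approximation
#' `auc +/- z * se`, truncated to \[0, 1\]. No logit transform is applied.
#'
#' @inheritParams roc_points
#' @param level confidence level, default 0.95.
#' @return object of class `trauma_auc`: list with `auc`, `se`, `ci_low`,
#'   `ci_high`, `level`, `n_event`, `n_control`, `orientation`.
#' @references DeLong, DeLong & Clarke-Pearson (1988), Biometrics 44:837-845.
#' @export
auc_with_ci <- function(values, events, orientation = "higher", level = 0.95) {
  events <- check_roc_input(values, events, min_each = 2L)
  ov <- orient_values(values, orientation)
  cmp <- delong_components(ov, events)
  m <- sum(events); n <- sum(!events)
  v <- stats::var(cmp$v10) / m + stats::var(cmp$v01) / n
  se <- sqrt(max(v, 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(auc = cmp$auc, se = se,
                 ci_low = max(0, cmp$auc - z * se),
                 ci_high = min(1, cmp$auc + z * se),
                 level = level, n_event = m, n_control = n,
                 orientation = normalize_orientation(orientation)),
            class = "trauma_auc")
}

#' @export
print.trauma_auc <- function(x, ...) {
  cat(sprintf("AUC %.3f (DeLong se %.4f, %g%% CI %.3f to %.3f; %d events / %d non-events)\n",
              x$auc, x$se, 100 * x$level, x$ci_low, x$ci_high,
              x$n_event, x$n_control))
  invisible(x)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two scores measured on the same patients against
#' the same event vector, using the DeLong estimate of the variance of the
#' AUC difference (which accounts for the within-patient correlation):
#' `z = (auc_a - auc_b) / sqrt(var_a + var_b - 2 cov_ab)`, two-sided p from
#' the standard normal. When the difference has zero variance and the AUCs
#' are equal (e.g. identical scores) the test degenerates to `z = 0, p = 1`.
#'
#' @param values_a,values_b score vectors over the same patients.
#' @param events shared event indicator.
#' @param orientation_a,orientation_b orientation of each score.
#' @return object of class `trauma_delong`: list with `auc_a`, `auc_b`,
#'   `delta_auc`, `se_delta`, `z`, `p`.
#' @export
delong_paired_test <- function(values_a, values_b, events,
                               orientation_a = "higher",
                               orientation_b = orientation_a) {
  events <- check_roc_input(values_a, events, min_each = 2L)
  if (length(values_b) != length(values_a)) {
    stop("both score vectors must cover the same patients", call. = FALSE)
  }
  ca <- delong_components(orient_values(values_a, orientation_a), events)
  cb <- delong_components(orient_values(values_b, orientation_b), events)
  m <- sum(events); n <- sum(!events)
  var_delta <- stats::var(ca$v10 - cb$v10) / m + stats::var(ca$v01 - cb$v01) / n
  delta <- ca$auc - cb$auc
  if (var_delta <= .Machine$double.eps) {
    if (abs(delta) <= sqrt(.Machine$double.eps)) {
      z <- 0; p <- 1; se <- 0
    } else {
      warning("zero DeLong variance with unequal AUCs; reporting p = 0")
      z <- sign(delta) * Inf; p <- 0; se <- 0
    }
  } else {
    se <- sqrt(var_delta)
    z <- delta / se
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(auc_a = ca$auc, auc_b = cb$auc, delta_auc = delta,
                 se_delta = se, z = z, p = p),
            class = "trauma_delong")
}

#' @export
print.trauma_delong <- function(x, ...) {
  cat(sprintf("Paired DeLong test: AUC %.3f vs %.3f, delta %.4f, z = %.3f, p = %s\n",
              x$auc_a, x$auc_b, x$delta_auc, x$z, format_pvalue(x$p)))
  invisible(x)
}

# Display convention for p-values: 4 decimals, "< 0.001" below 1e-4.
format_pvalue <- function(p) {
  ifelse(p < 1e-4, "< 0.001", sprintf("%.4f", p))
}
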