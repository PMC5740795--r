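# The four scores evaluated as death predictors and their directions.
# NISS rises with severity; RTS and both survival probabilities fall.

#' Score orientations used throughout the analysis
#'
#' @return named character vector mapping score column to orientation.
#' @export
score_orientations <- function() {
  c(niss = "higher", rts = "lower", ps_mtos = "lower", ps_ntrd = "lower")
}

#' AUC table and pairwise DeLong comparison for the four scores
#'
#' Computes, on a scored cohort, the AUC (with DeLong standard error and
#' confidence interval) of NISS, RTS, MTOS-TRISS and NTrD-TRISS for
#' in-hospital death, and the 4 x 4 matrix of paired DeLong tests between
#' them. The p matrix is symmetric with an empty (NA) diagonal; the z matrix
#' is antisymmetric (`z[a, b] = -z[b, a]`).
#'
#' @param scored data frame from [score_cohort()] (columns `niss`, `rts`,
#'   `ps_mtos`, `ps_ntrd` present).
#' @param events event indicator; defaults to `scored$died`.
#' @param level confidence level for the AUC intervals.
#' @return list with `auc` (data frame: score, auc, se, ci_low, ci_high),
#'   `p` and `z` (4 x 4 matrices), `n_event`, `n_control`.
#' @export
pairwise_auc_table <- function(scored, events = scored$died, level = 0.95) {
  orient <- score_orientations()
  scores <- names(orient)
  missing_cols <- setdiff(scores, names(scored))
  if (length(missing_cols)) {
    stop("scored cohort lacks column(s): ", paste(missing_cols, collapse = ", "),
         "; run score_cohort() first", call. = FALSE)
  }
  events <- check_roc_input(scored[[scores[1]]], events, min_each = 2L)
  auc_rows <- lapply(scores, function(s) {
    a <- auc_with_ci(scored[[s]], events, orient[[s]], level = level)
    data.frame(score = s, auc = a$auc, se = a$se,
               ci_low = a$ci_low, ci_high = a$ci_high,
               stringsAsFactors = FALSE)
  })
  p <- z <- matrix(NA_real_, 4, 4, dimnames = list(scores, scores))
  for (i in 1:3) {
    for (j in (i + 1):4) {
      d <- delong_paired_test(scored[[scores[i]]], scored[[scores[j]]], events,
                              orient[[scores[i]]], orient[[scores[j]]])
      p[i, j] <- p[j, i] <- d$p
      z[i, j] <- d$z
      z[j, i] <- -d$z
    }
  }
  list(auc = do.call(rbind, auc_rows), p = p, z = z,
       n_event = sum(events), n_control = sum(!events))
}

#' Youden-optimal cutoff table for the four scores
#'
#' One [youden_optimal_cutoff()] row per score, in the fixed score order
#' NISS, RTS, MTOS-TRISS, NTrD-TRISS with their standard orientations.
#'
#' @inheritParams pairwise_auc_table
#' @return data frame with a leading `score` column followed by the
#'   [cutoff_metrics()] columns.
#' @export
cutoff_table <- function(scored, events = scored$died) {
  orient <- score_orientations()
  rows <- lapply(names(orient), function(s) {
    r <- youden_optimal_cutoff(scored[[s]], events, orient[[s]])
    cbind(data.frame(score = s, stringsAsFactors = FALSE), r)
  })
  do.call(rbind, rows)
}
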