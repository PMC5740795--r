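# RTS weights and TRISS logistic coefficients, at published precision.
RTS_WEIGHTS <- c(rr = 0.2908, sbp = 0.7326, gcs = 0.9368)
RTS_MAX <- 4 * sum(RTS_WEIGHTS)  # 7.8408

MTOS_COEF <- list(
  blunt       = c(intercept = -0.4499, rts = 0.8085, iss = -0.0835, age = -1.7430),
  penetrating = c(intercept = -2.5355, rts = 0.9934, iss = -0.0651, age = -1.1360)
)

NTRD_COEF <- c(intercept = -3.6167, niss = -0.0160, age = -1.1358,
               rr = 0.2671, sbp = 0.8206, gcs = 0.6071)

#' Categorise physiology for the Revised Trauma Score
#'
#' Each first-recorded physiological variable is mapped to an ordinal score
#' 0-4, the physiologically normal band scoring 4:
#'
#' * respiratory rate (breaths/min): 10-29 -> 4, >29 -> 3, 6-9 -> 2,
#'   1-5 -> 1, 0 -> 0;
#' * systolic blood pressure (mmHg): >89 -> 4, 76-89 -> 3, 50-75 -> 2,
#'   1-49 -> 1, 0 -> 0;
#' * Glasgow Coma Scale: 13-15 -> 4, 9-12 -> 3, 6-8 -> 2, 4-5 -> 1, 3 -> 0.
#'
#' @param rr respiratory rate in breaths/min, non-negative.
#' @param sbp systolic blood pressure in mmHg, non-negative.
#' @param gcs Glasgow Coma Scale, 3-15.
#' @return integer vector of category scores in 0-4.
#' @export
score_respiratory_rate <- function(rr) {
  if (anyNA(rr) || any(rr < 0)) stop("respiratory rate must be non-negative",
                                     call. = FALSE)
  ifelse(rr >= 10 & rr <= 29, 4L,
  ifelse(rr > 29, 3L,
  ifelse(rr >= 6, 2L,
  ifelse(rr > 0, 1L, 0L))))
}

#' @rdname score_respiratory_rate
#' @export
score_systolic_bp <- function(sbp) {
  if (anyNA(sbp) || any(sbp < 0)) stop("systolic blood pressure must be non-negative",
                                       call. = FALSE)
  ifelse(sbp > 89, 4L,
  ifelse(sbp >= 76, 3L,
  ifelse(sbp >= 50, 2L,
  ifelse(sbp > 0, 1L, 0L))))
}

#' @rdname score_respiratory_rate
#' @export
score_gcs <- function(gcs) {
  if (anyNA(gcs) || any(gcs < 3 | gcs > 15)) stop("GCS must be in [3, 15]",
                                                  call. = FALSE)
  ifelse(gcs >= 13, 4L,
  ifelse(gcs >= 9, 3L,
  ifelse(gcs >= 6, 2L,
  ifelse(gcs >= 4, 1L, 0L))))
}

#' Revised Trauma Score
#'
#' Weighted sum of the three physiology category scores,
#' `RTS = 0.2908 * RRscore + 0.7326 * SBPscore + 0.9368 * GCSscore`,
#' ranging from 0 (all categories 0) to 7.8408 (all categories 4).
#'
#' @inheritParams score_respiratory_rate
#' @return numeric vector in \[0, 7.8408\].
#' @export
#' @examples
#' compute_rts(20, 120, 15)  # 7.8408
compute_rts <- function(rr, sbp, gcs) {
  RTS_WEIGHTS[["rr"]]  * score_respiratory_rate(rr) +
  RTS_WEIGHTS[["sbp"]] * score_systolic_bp(sbp) +
  RTS_WEIGHTS[["gcs"]] * score_gcs(gcs)
}

check_severities <- function(severity) {
  severity <- as.integer(severity)
  if (anyNA(severity) || any(severity < 1L | severity > 6L)) {
    stop("AIS severities must be integers in 1-6", call. = FALSE)
  }
  severity
}

#' Injury Severity Score from AIS-coded injuries
#'
#' `compute_iss()` squares the single highest AIS severity in each of the
#' three most severely injured distinct body regions and sums the squares.
#' `compute_niss()` squares the three highest AIS severities regardless of
#' body region, so `NISS >= ISS` always. Both range 0-75; an AIS severity
#' of 6 (unsurvivable) forces the conventional maximum of 75.
#'
#' @param region character vector of body regions, one per injury (ignored
#'   by `compute_niss`).
#' @param severity integer vector of AIS severities 1-6, one per injury.
#' @return a single integer in 0-75.
#' @export
#' @examples
#' compute_iss(c("head_neck", "chest"), c(5, 3))           # 34
#' compute_niss(c(5, 4, 3, 2))                             # 50
compute_iss <- function(region, severity) {
  if (length(severity) == 0L) return(0L)
  severity <- check_severities(severity)
  if (any(severity == 6L)) return(75L)
  stopifnot(length(region) == length(severity))
  per_region <- tapply(severity, region, max)
  top <- sort(as.integer(per_region), decreasing = TRUE)
  sum(utils::head(top, 3L)^2)
}

#' @rdname compute_iss
#' @export
compute_niss <- function(severity) {
  if (length(severity) == 0L) return(0L)
  severity <- check_severities(severity)
  if (any(severity == 6L)) return(75L)
  top <- sort(severity, decreasing = TRUE)
  sum(utils::head(top, 3L)^2)
}

#' Age index for the TRISS models
#'
#' Binary age covariate of both TRISS variants: 0 for ages below 55 and 1
#' for ages 55 and above. The source models define it for ages 15-54 vs
#' >= 55; patients under 15 (the cohort floor is 14) take 0, consistent
#' with applying the adult blunt specification to children.
#'
#' @param age age in years, non-negative.
#' @return integer vector of 0/1.
#' @export
age_index <- function(age) {
  if (anyNA(age) || any(age < 0)) stop("age must be non-negative", call. = FALSE)
  as.integer(age >= 55)
}

#' Coefficient set used by MTOS-TRISS for a patient
#'
#' The MTOS model has separate blunt and penetrating coefficient sets for
#' adults (age >= 15). The blunt set is applied universally to children
#' under 15 regardless of mechanism, and to blast injuries (a mechanism the
#' MTOS model does not define; blunt is the conservative mapping).
#'
#' @inheritParams age_index
#' @param mechanism `"blunt"`, `"penetrating"` or `"blast"`.
#' @return character vector, `"blunt"` or `"penetrating"`.
#' @export
mtos_coefficient_set <- function(age, mechanism) {
  if (!all(mechanism %in% MECHANISMS)) {
    stop("unknown mechanism: ",
         paste(unique(mechanism[!mechanism %in% MECHANISMS]), collapse = ", "),
         call. = FALSE)
  }
  ifelse(mechanism == "penetrating" & age >= 15, "penetrating", "blunt")
}

#' TRISS probability of survival, MTOS coefficients
#'
#' `Ps = 1 / (1 + exp(-b))` with
#' `b = -0.4499 + 0.8085 RTS - 0.0835 ISS - 1.7430 AgeIndex` for the blunt
#' set and `b = -2.5355 + 0.9934 RTS - 0.0651 ISS - 1.1360 AgeIndex` for
#' the penetrating set; see [mtos_coefficient_set()] for which set applies.
#'
#' @param rts Revised Trauma Score, in \[0, 7.8408\].
#' @param iss Injury Severity Score, 0-75.
#' @inheritParams mtos_coefficient_set
#' @return probability of survival, strictly inside (0, 1).
#' @export
#' @examples
#' ps_mtos_triss(7.8408, 0, 36, "blunt")  # ~0.9972
ps_mtos_triss <- function(rts, iss, age, mechanism) {
  set <- mtos_coefficient_set(age, mechanism)
  cf <- do.call(rbind, MTOS_COEF[set])
  b <- cf[, "intercept"] + cf[, "rts"] * rts + cf[, "iss"] * iss +
    cf[, "age"] * age_index(age)
  unname(stats::plogis(b))
}

#' TRISS probability of survival, NTrD coefficients
#'
#' Single coefficient set for all mechanisms, refit on the Malaysian
#' National Trauma Database and using NISS plus the three physiology
#' category scores:
#' `b = -3.6167 - 0.0160 NISS - 1.1358 AgeIndex + 0.2671 RRscore
#'  + 0.8206 SBPscore + 0.6071 GCSscore`.
#'
#' @param niss New Injury Severity Score, 0-75.
#' @inheritParams age_index
#' @param rr_score,sbp_score,gcs_score physiology category scores 0-4 from
#'   [score_respiratory_rate()] and friends.
#' @return probability of survival, strictly inside (0, 1).
#' @export
ps_ntrd_triss <- function(niss, age, rr_score, sbp_score, gcs_score) {
  b <- NTRD_COEF[["intercept"]] + NTRD_COEF[["niss"]] * niss +
    NTRD_COEF[["age"]] * age_index(age) +
    NTRD_COEF[["rr"]] * rr_score + NTRD_COEF[["sbp"]] * sbp_score +
    NTRD_COEF[["gcs"]] * gcs_score
  stats::plogis(b)
}

#' Compute all trauma scores for a cohort
#'
#' Appends to the registry data frame the columns `rr_score`, `sbp_score`,
#' `gcs_score`, `iss`, `niss`, `rts`, `age_index`, `coefficient_set`
#' (the MTOS set used), `ps_mtos` and `ps_ntrd`.
#'
#' @param cohort registry data frame (see [read_registry()]).
#' @return the cohort with score columns appended.
#' @export
score_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  check_cohort_fields(cohort)
  inj <- parse_injuries(cohort$injuries)
  out <- cohort
  out$rr_score  <- score_respiratory_rate(cohort$rr)
  out$sbp_score <- score_systolic_bp(cohort$sbp)
  out$gcs_score <- score_gcs(cohort$gcs)
  out$iss  <- vapply(inj, function(d) as.integer(compute_iss(d$region, d$severity)),
                     integer(1))
  out$niss <- vapply(inj, function(d) as.integer(compute_niss(d$severity)),
                     integer(1))
  out$rts <- RTS_WEIGHTS[["rr"]] * out$rr_score +
    RTS_WEIGHTS[["sbp"]] * out$sbp_score + RTS_WEIGHTS[["gcs"]] * out$gcs_score
  out$age_index <- age_index(cohort$age)
  out$coefficient_set <- mtos_coefficient_set(cohort$age, cohort$mechanism)
  out$ps_mtos <- ps_mtos_triss(out$rts, out$iss, cohort$age, cohort$mechanism)
  out$ps_ntrd <- ps_ntrd_triss(out$niss, cohort$age, out$rr_score,
                               out$sbp_score, out$gcs_score)
  out
}

#' Score panel for a single patient record
#'
#' Convenience wrapper around [score_cohort()] for one record.
#'
#' @param record one-row registry data frame.
#' @return named list with elements `iss`, `niss`, `rts`, `ps_mtos`,
#'   `ps_ntrd`, `rr_score`, `sbp_score`, `gcs_score`, `age_index`,
#'   `coefficient_set`.
#' @export
score_panel <- function(record) {
  stopifnot(is.data.frame(record), nrow(record) == 1L)
  s <- score_cohort(record)
  list(iss = s$iss, niss = s$niss, rts = s$rts,
       ps_mtos = s$ps_mtos, ps_ntrd = s$ps_ntrd,
       rr_score = s$rr_score, sbp_score = s$sbp_score, gcs_score = s$gcs_score,
       age_index = s$age_index, coefficient_set = s$coefficient_set)
}
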