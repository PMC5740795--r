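# Shared fixtures and independent oracles. Oracles are deliberately naive
# (enumeration / brute force) and never share code with the implementation.

make_record <- function(patient_id = "P1", age = 36, sex = "male",
                        mechanism = "blunt", rr = 20, sbp = 120, gcs = 15,
                        died = FALSE, injuries = "head_neck:3;chest:4") {
  data.frame(patient_id = patient_id, age = age, sex = sex,
             mechanism = mechanism, rr = rr, sbp = sbp, gcs = gcs,
             died = died, injuries = injuries, stringsAsFactors = FALSE)
}

# random score/event instance with ties and both classes guaranteed
random_instance <- function(n = 30, tie_prob = 0.5) {
  values <- if (runif(1) < tie_prob) sample(1:8, n, replace = TRUE)
            else rnorm(n)
  events <- runif(n) < runif(1, 0.15, 0.6)
  if (!any(events)) events[sample(n, 1)] <- TRUE
  if (all(events)) events[sample(n, 1)] <- FALSE
  list(values = values, events = events)
}

random_injury_list <- function(max_n = 6) {
  k <- sample(0:max_n, 1)
  data.frame(region = sample(c("head_neck", "face", "chest", "abdomen",
                               "extremities", "external"), k, replace = TRUE),
             severity = sample(1:5, k, replace = TRUE))
}

# ISS by enumeration: best set of <= 3 distinct regions, each contributing
# its single highest severity squared
iss_oracle <- function(region, severity) {
  if (length(severity) == 0) return(0)
  if (any(severity == 6)) return(75)
  per_region <- vapply(unique(region), function(r) max(severity[region == r]),
                       numeric(1))
  best <- 0
  regions <- seq_along(per_region)
  for (size in 1:min(3, length(regions))) {
    for (pick in utils::combn(regions, size, simplify = FALSE)) {
      best <- max(best, sum(per_region[pick]^2))
    }
  }
  best
}

# NISS by enumeration over all subsets of <= 3 individual injuries
niss_oracle <- function(severity) {
  if (length(severity) == 0) return(0)
  if (any(severity == 6)) return(75)
  best <- 0
  for (size in 1:min(3, length(severity))) {
    for (pick in utils::combn(seq_along(severity), size, simplify = FALSE)) {
      best <- max(best, sum(severity[pick]^2))
    }
  }
  best
}

# AUC by brute-force counting over all case/control pairs
auc_oracle <- function(values, events, orientation = "higher") {
  v <- if (orientation == "lower") -values else values
  cases <- v[events]; controls <- v[!events]
  total <- 0
  for (x in cases) total <- total + sum(x > controls) + 0.5 * sum(x == controls)
  total / (length(cases) * length(controls))
}

# trapezoidal area under an ROC curve data frame
trapezoid_area <- function(curve) {
  sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) + utils::tail(curve$tpr, -1)) / 2)
}

# Youden scan by direct confusion-table evaluation at every candidate cutoff
youden_oracle <- function(values, events, orientation = "higher") {
  v <- if (orientation == "lower") -values else values
  sv <- sort(unique(v))
  cand <- c(sv[1] - 1, if (length(sv) > 1) (sv[-1] + sv[-length(sv)]) / 2,
            sv[length(sv)] + 1)
  best_j <- -Inf
  for (cut in cand) {
    pred <- v > cut
    sens <- sum(pred & events) / sum(events)
    spec <- sum(!pred & !events) / sum(!events)
    best_j <- max(best_j, sens + spec - 1)
  }
  best_j
}

# rank-based AUC for the permutation oracle (higher orientation, fast)
auc_rank <- function(v, events, m, n) {
  (sum(rank(v)[events]) - m * (m + 1) / 2) / (m * n)
}

# Within-patient label-swap permutation test for the AUC difference of two
# paired scores (both already oriented so higher predicts the event).
permutation_paired_p <- function(a, b, events, reps = 1e4) {
  m <- sum(events); n <- sum(!events)
  obs <- abs(auc_rank(a, events, m, n) - auc_rank(b, events, m, n))
  hits <- 0L
  N <- length(a)
  for (r in seq_len(reps)) {
    swap <- runif(N) < 0.5
    a2 <- ifelse(swap, b, a)
    b2 <- ifelse(swap, a, b)
    d <- abs(auc_rank(a2, events, m, n) - auc_rank(b2, events, m, n))
    if (d >= obs - 1e-12) hits <- hits + 1L
  }
  hits / reps
}

# small cohort with a mix of severities and at least two deaths/survivors
toy_cohort <- function() {
  generate_cohort(synthetic_config(n = 20), seed = 17)
}

# dependence severed but prevalence kept: the chance-level reference model
null_config <- function(n) {
  synthetic_config(n = n, outcome_niss_coef = 0, outcome_phys_coef = 0,
                   physiology_coupling = 0,
                   outcome_intercept = qlogis(0.108))
}
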