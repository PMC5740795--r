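#' Run the full score-validation study
#'
#' Reproduces the analysis shape of the validation study on a cohort:
#' validate and exclude records, compute the four scores, then evaluate
#' discrimination for in-hospital death (AUC table with DeLong intervals,
#' pairwise paired DeLong tests, Youden-optimal cutoff table) alongside the
#' cohort summary. Given a configuration instead of a cohort, a synthetic
#' cohort is generated first, making the whole run a pure function of
#' `(config, seed)`.
#'
#' @param cohort registry data frame, or `NULL` to generate one.
#' @param config [synthetic_config()] used when `cohort` is `NULL`.
#' @param seed RNG seed for generation.
#' @param level confidence level for AUC intervals.
#' @return object of class `trauma_report`: list with `cohort_summary`,
#'   `auc_table` (data frame), `pairwise_p`, `pairwise_z` (4 x 4 matrices),
#'   `cutoff_table` (data frame), `scored` (the analysed scored cohort),
#'   `exclusions` (list: `n_read`, `n_analyzed`, `n_excluded`, `issues`),
#'   and `provenance` (config, seed, package version).
#' @export
run_study <- function(cohort = NULL, config = calibrate_defaults(),
                      seed = config$seed, level = 0.95) {
  provenance <- list(
    source = if (is.null(cohort)) "synthetic" else "supplied",
    config = if (is.null(cohort)) unclass(config) else NULL,
    seed = if (is.null(cohort)) as.integer(seed) else NA_integer_,
    package_version = as.character(utils::packageVersion("traumascore")))
  if (is.null(cohort)) cohort <- generate_cohort(config, seed)
  n_read <- nrow(cohort)
  excl <- apply_exclusions(cohort)
  analyzed <- excl$cohort
  stopifnot(nrow(analyzed) + nrow(excl$excluded) == n_read)
  if (nrow(analyzed) == 0L) {
    stop("no records left after exclusions", call. = FALSE)
  }
  if (length(unique(analyzed$died)) < 2L) {
    stop("degenerate outcome after exclusions: all records have died = ",
         unique(analyzed$died), " (", nrow(excl$excluded),
         " record(s) excluded)", call. = FALSE)
  }
  scored <- score_cohort(analyzed)
  pw <- pairwise_auc_table(scored, scored$died, level = level)
  structure(list(
    cohort_summary = summarize_cohort(analyzed),
    auc_table = pw$auc,
    pairwise_p = pw$p,
    pairwise_z = pw$z,
    cutoff_table = cutoff_table(scored, scored$died),
    scored = scored,
    exclusions = list(n_read = n_read, n_analyzed = nrow(analyzed),
                      n_excluded = nrow(excl$excluded), issues = excl$issues),
    provenance = provenance
  ), class = "trauma_report")
}

#' @export
print.trauma_report <- function(x, ...) {
  cs <- x$cohort_summary
  cat(sprintf("Trauma score validation report: %d patients analysed (%d excluded), mortality %.1f%%\n",
              cs$n, x$exclusions$n_excluded, 100 * cs$mortality_fraction))
  cat("\nAUC (DeLong 95% CI):\n")
  a <- x$auc_table
  for (i in seq_len(nrow(a))) {
    cat(sprintf("  %-8s %.3f (%.3f to %.3f)\n", a$score[i], a$auc[i],
                a$ci_low[i], a$ci_high[i]))
  }
  cat("\nYouden-optimal cutoffs:\n")
  ct <- x$cutoff_table
  for (i in seq_len(nrow(ct))) {
    cat(sprintf("  %-8s %s %.4g  sens %.1f%% spec %.1f%% acc %.2f%% ppv %.2f%% npv %.2f%%\n",
                ct$score[i], ifelse(ct$orientation[i] == "higher", ">", "<"),
                ct$cutoff[i], 100 * ct$sensitivity[i], 100 * ct$specificity[i],
                100 * ct$accuracy[i], 100 * ct$ppv[i], 100 * ct$npv[i]))
  }
  invisible(x)
}

summary_as_df <- function(cs) {
  data.frame(
    statistic = c("n", "mortality_fraction", "age_mean", "age_sd",
                  "male_fraction", "blunt_fraction", "penetrating_fraction",
                  "blast_fraction", "niss_mean", "niss_sd", "rts_mean",
                  "rts_sd", "ps_mtos_mean", "ps_ntrd_mean"),
    value = c(cs$n, cs$mortality_fraction, cs$age_mean, cs$age_sd,
              cs$male_fraction, cs$mechanism_fractions[["blunt"]],
              cs$mechanism_fractions[["penetrating"]],
              cs$mechanism_fractions[["blast"]], cs$niss_mean, cs$niss_sd,
              cs$rts_mean, cs$rts_sd, cs$ps_mtos_mean, cs$ps_ntrd_mean),
    stringsAsFactors = FALSE)
}

#' Render a study report to files
#'
#' Writes the report tables as CSV, the provenance block as YAML, a run log,
#' and an ROC overlay figure of the four scores:
#' `cohort_summary.csv`, `auc_table.csv`, `pairwise_p.csv` (symmetric 4 x 4
#' with empty diagonal), `cutoffs.csv`, `provenance.yaml`, `run_log.txt`,
#' and `roc_overlay.png` (and/or `.svg`).
#'
#' @param report a [run_study()] result.
#' @param out_dir output directory, created if absent.
#' @param formats figure formats, subset of `c("png", "svg")`.
#' @return character vector of the files written, invisibly.
#' @export
render_report <- function(report, out_dir, formats = "png") {
  stopifnot(inherits(report, "trauma_report"))
  formats <- match.arg(formats, c("png", "svg"), several.ok = TRUE)
  ok <- tryCatch({dir.create(out_dir, recursive = TRUE, showWarnings = FALSE); TRUE},
                 error = function(e) e)
  if (!isTRUE(ok) || !dir.exists(out_dir)) {
    stop("cannot create output directory '", out_dir, "'", call. = FALSE)
  }
  files <- character(0)
  put <- function(name) {
    files <<- c(files, file.path(out_dir, name))
    file.path(out_dir, name)
  }

  utils::write.csv(summary_as_df(report$cohort_summary),
                   put("cohort_summary.csv"), row.names = FALSE)
  auc <- report$auc_table
  auc[, c("auc", "se", "ci_low", "ci_high")] <-
    round(auc[, c("auc", "se", "ci_low", "ci_high")], 4)
  utils::write.csv(auc, put("auc_table.csv"), row.names = FALSE)
  p <- round(report$pairwise_p, 4)
  utils::write.csv(cbind(data.frame(score = rownames(p)), as.data.frame(p)),
                   put("pairwise_p.csv"), row.names = FALSE)
  ct <- report$cutoff_table
  num <- vapply(ct, is.numeric, logical(1))
  ct[num] <- lapply(ct[num], round, 4)
  utils::write.csv(ct, put("cutoffs.csv"), row.names = FALSE)
  yaml::write_yaml(report$provenance, put("provenance.yaml"))

  log_lines <- c(
    sprintf("records read: %d", report$exclusions$n_read),
    sprintf("records analysed: %d", report$exclusions$n_analyzed),
    sprintf("records excluded (fatal issues): %d", report$exclusions$n_excluded))
  iss <- report$exclusions$issues
  if (nrow(iss)) {
    counts <- table(iss$rule)
    log_lines <- c(log_lines,
                   sprintf("issue %s: %d record(s)", names(counts), counts))
    fatal <- iss[iss$fatal, , drop = FALSE]
    log_lines <- c(log_lines,
                   sprintf("excluded %s (%s)", fatal$patient_id, fatal$rule))
  }
  ppv_nan <- is.nan(report$cutoff_table$ppv)
  npv_nan <- is.nan(report$cutoff_table$npv)
  if (any(ppv_nan | npv_nan)) {
    log_lines <- c(log_lines, sprintf(
      "undefined predictive value for score %s",
      report$cutoff_table$score[ppv_nan | npv_nan]))
  }
  writeLines(log_lines, put("run_log.txt"))

  for (fmt in formats) {
    file <- put(paste0("roc_overlay.", fmt))
    if (fmt == "png") grDevices::png(file, width = 1600, height = 1600,
                                     res = 240)
    else grDevices::svg(file, width = 7, height = 7)
    plot_roc_overlay(report)
    grDevices::dev.off()
  }
  invisible(files)
}

#' ROC overlay of the four scores
#'
#' Plots the empirical ROC curves of NISS, RTS, MTOS-TRISS and NTrD-TRISS
#' for in-hospital death on the current device.
#'
#' @param report a [run_study()] result.
#' @return `NULL`, invisibly.
#' @export
plot_roc_overlay <- function(report) {
  scored <- report$scored
  orient <- score_orientations()
  cols <- c(niss = "#1b6ca8", rts = "#c0392b", ps_mtos = "#27ae60",
            ps_ntrd = "#8e44ad")
  labels <- c(niss = "NISS", rts = "RTS", ps_mtos = "MTOS-TRISS",
              ps_ntrd = "NTrD-TRISS")
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 3, col = "grey50",
                 xlab = "1 - specificity", ylab = "Sensitivity",
                 main = "ROC curves for in-hospital mortality")
  for (s in names(orient)) {
    curve <- roc_points(scored[[s]], scored$died, orient[[s]])
    graphics::lines(curve$fpr, curve$tpr, col = cols[[s]], lwd = 2)
  }
  auc <- report$auc_table
  graphics::legend("bottomright", bty = "n", lwd = 2, col = cols[auc$score],
                   legend = sprintf("%s (AUC %.3f)", labels[auc$score], auc$auc))
  invisible(NULL)
}
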