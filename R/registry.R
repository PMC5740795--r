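# Canonical registry columns, in file order. Extra columns are passed through.
REGISTRY_COLUMNS <- c("patient_id", "age", "sex", "mechanism",
                      "rr", "sbp", "gcs", "died", "injuries")

AIS_REGIONS <- c("head_neck", "face", "chest", "abdomen", "extremities", "external")
MECHANISMS  <- c("blunt", "penetrating", "blast")

#' Parse injury-list strings into per-patient injury tables
#'
#' A registry row stores all AIS-coded injuries of one patient in a single
#' cell using the grammar `"region:severity;region:severity;..."`, e.g.
#' `"head_neck:3;chest:4"`. Regions are the six ISS body regions
#' (`head_neck`, `face`, `chest`, `abdomen`, `extremities`, `external`) and
#' severity is the Abbreviated Injury Scale grade 1-6. An empty string means
#' no coded injuries.
#'
#' @param x character vector of injury-list cells.
#' @return A list (one element per cell) of data frames with columns
#'   `region` and `severity`.
#' @export
#' @examples
#' parse_injuries(c("head_neck:3;chest:4", ""))
parse_injuries <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  lapply(x, function(cell) {
    cell <- trimws(cell)
    if (!nzchar(cell)) {
      return(data.frame(region = character(0), severity = integer(0)))
    }
    toks <- strsplit(cell, ";", fixed = TRUE)[[1]]
    toks <- trimws(toks)
    toks <- toks[nzchar(toks)]
    parts <- strsplit(toks, ":", fixed = TRUE)
    bad <- lengths(parts) != 2L
    if (any(bad)) {
      stop("malformed injury token(s): ", paste(toks[bad], collapse = ", "),
           call. = FALSE)
    }
    region <- trimws(vapply(parts, `[[`, "", 1L))
    sev_chr <- trimws(vapply(parts, `[[`, "", 2L))
    severity <- suppressWarnings(as.integer(sev_chr))
    if (anyNA(severity)) {
      stop("non-integer AIS severity in injury token(s): ",
           paste(toks[is.na(severity)], collapse = ", "), call. = FALSE)
    }
    if (!all(region %in% AIS_REGIONS)) {
      stop("unknown body region(s): ",
           paste(unique(region[!region %in% AIS_REGIONS]), collapse = ", "),
           call. = FALSE)
    }
    if (any(severity < 1L | severity > 6L)) {
      stop("AIS severity out of range 1-6: ",
           paste(severity[severity < 1L | severity > 6L], collapse = ", "),
           call. = FALSE)
    }
    data.frame(region = region, severity = severity)
  })
}

#' Format per-patient injury tables back into registry strings
#'
#' Inverse of [parse_injuries()].
#'
#' @param injuries list of data frames with columns `region` and `severity`.
#' @return character vector of `"region:severity;..."` cells.
#' @export
format_injuries <- function(injuries) {
  vapply(injuries, function(df) {
    if (nrow(df) == 0L) return("")
    paste(paste(df$region, df$severity, sep = ":"), collapse = ";")
  }, character(1))
}

check_cohort_fields <- function(cohort, rows = NULL) {
  # Type-level invariants; violation is a hard error (not a validation issue).
  where <- function(bad) {
    idx <- which(bad)
    if (!is.null(rows)) idx <- rows[idx]
    paste(utils::head(idx, 5), collapse = ", ")
  }
  if (anyNA(cohort$age) || any(cohort$age < 0)) {
    stop("age must be a non-negative number (rows ",
         where(is.na(cohort$age) | cohort$age < 0), ")", call. = FALSE)
  }
  bad_sex <- !cohort$sex %in% c("male", "female")
  if (any(bad_sex)) {
    stop("sex must be 'male' or 'female' (rows ", where(bad_sex), ")",
         call. = FALSE)
  }
  bad_mech <- !cohort$mechanism %in% MECHANISMS
  if (any(bad_mech)) {
    stop("mechanism must be one of ", paste(MECHANISMS, collapse = "/"),
         " (rows ", where(bad_mech), ")", call. = FALSE)
  }
  if (anyNA(cohort$rr) || any(cohort$rr < 0)) {
    stop("respiratory rate must be non-negative (rows ",
         where(is.na(cohort$rr) | cohort$rr < 0), ")", call. = FALSE)
  }
  if (anyNA(cohort$sbp) || any(cohort$sbp < 0)) {
    stop("systolic blood pressure must be non-negative (rows ",
         where(is.na(cohort$sbp) | cohort$sbp < 0), ")", call. = FALSE)
  }
  bad_gcs <- is.na(cohort$gcs) | cohort$gcs < 3 | cohort$gcs > 15
  if (any(bad_gcs)) {
    stop("GCS must be in [3, 15] (rows ", where(bad_gcs), ")", call. = FALSE)
  }
  if (anyNA(cohort$died)) {
    stop("died must be 0/1 with no missing values (rows ",
         where(is.na(cohort$died)), ")", call. = FALSE)
  }
  invisible(cohort)
}

#' Read a patient-level trauma registry from delimited text
#'
#' Reads a one-row-per-patient table with a mandatory header row and the
#' required columns `patient_id`, `age`, `sex`, `mechanism`, `rr`, `sbp`,
#' `gcs`, `died` (0/1) and `injuries` (see [parse_injuries()] for the cell
#' grammar). Unknown columns are preserved unchanged. Structural problems
#' (missing columns, unparseable cells, out-of-range physiology) are hard
#' errors; study-level inclusion rules are checked separately by
#' [validate_cohort()].
#'
#' @param path path to a delimited text file (UTF-8).
#' @param delim field delimiter; `","` (default) or e.g. `"\t"`.
#' @param dec decimal mark for numeric columns.
#' @return A data frame with the canonical columns (plus any extras) and one
#'   row per patient; `died` is logical, `injuries` stays in its string form.
#' @seealso [write_registry()], [validate_cohort()]
#' @export
read_registry <- function(path, delim = ",", dec = ".") {
  df <- utils::read.table(path, header = TRUE, sep = delim, dec = dec,
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", na.strings = NULL,
                          encoding = "UTF-8")
  missing_cols <- setdiff(REGISTRY_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("registry is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  to_num <- function(col) {
    x <- trimws(df[[col]])
    if (dec != ".") x <- gsub(dec, ".", x, fixed = TRUE)
    out <- suppressWarnings(as.numeric(x))
    bad <- is.na(out) & nzchar(x)
    empty <- !nzchar(x)
    if (any(bad | empty)) {
      stop("unparseable or missing '", col, "' value at data row(s) ",
           paste(utils::head(which(bad | empty), 5), collapse = ", "),
           call. = FALSE)
    }
    out
  }
  cohort <- data.frame(
    patient_id = trimws(df$patient_id),
    age        = to_num("age"),
    sex        = trimws(df$sex),
    mechanism  = trimws(df$mechanism),
    rr         = to_num("rr"),
    sbp        = to_num("sbp"),
    gcs        = to_num("gcs"),
    died       = to_num("died"),
    injuries   = df$injuries,
    stringsAsFactors = FALSE
  )
  if (!all(cohort$died %in% c(0, 1))) {
    stop("'died' must be 0 or 1 at data row(s) ",
         paste(utils::head(which(!cohort$died %in% c(0, 1)), 5),
               collapse = ", "), call. = FALSE)
  }
  cohort$died <- cohort$died == 1
  check_cohort_fields(cohort)
  # injuries parsed once here so malformed cells fail at read time
  parse_injuries(cohort$injuries)
  extras <- setdiff(names(df), REGISTRY_COLUMNS)
  for (col in extras) cohort[[col]] <- df[[col]]
  cohort
}

#' Write a trauma cohort to delimited text
#'
#' Writes the canonical registry columns (plus pass-through extras) so that
#' [read_registry()] reproduces the cohort field for field.
#'
#' @param cohort data frame as returned by [read_registry()] or
#'   [generate_cohort()].
#' @param path output file path.
#' @param delim field delimiter.
#' @param dec decimal mark for numeric columns.
#' @return `path`, invisibly.
#' @export
write_registry <- function(cohort, path, delim = ",", dec = ".") {
  stopifnot(is.data.frame(cohort))
  missing_cols <- setdiff(REGISTRY_COLUMNS, names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- cohort
  out$died <- as.integer(out$died)
  extras <- setdiff(names(out), REGISTRY_COLUMNS)
  out <- out[, c(REGISTRY_COLUMNS, extras), drop = FALSE]
  ok <- tryCatch({
    utils::write.table(out, path, sep = delim, dec = dec, row.names = FALSE,
                       quote = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write registry to '", path, "': ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Check study inclusion rules on a cohort
#'
#' Applies the record-level validation rules of the validation study:
#' patients aged 13 or younger are excluded (`fatal = TRUE`, rule
#' `age_exclusion`) since they are managed by a separate paediatric service;
#' a record with no coded injuries (`no_injuries`) or with an AIS severity
#' of 6 (`unsurvivable_ais`, which forces ISS/NISS to 75 when scoring) is
#' flagged but kept. Exclusions for mechanism-specific criteria the record
#' schema cannot express (burns, hanging, drowning, pathological fractures,
#' isolated uncompromised head injury) are the caller's responsibility.
#'
#' The check is pure: the same cohort always yields the same issue table.
#'
#' @param cohort registry data frame.
#' @return data frame with columns `patient_id`, `rule`, `message`, `fatal`
#'   (zero rows when every record conforms).
#' @seealso [apply_exclusions()]
#' @export
validate_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  check_cohort_fields(cohort)
  inj <- parse_injuries(cohort$injuries)
  issues <- list()
  add <- function(idx, rule, message, fatal) {
    if (!length(idx)) return()
    issues[[length(issues) + 1L]] <<- data.frame(
      patient_id = cohort$patient_id[idx],
      rule = rule, message = message, fatal = fatal,
      stringsAsFactors = FALSE)
  }
  add(which(cohort$age <= 13), "age_exclusion",
      "age 13 or below: excluded from analysis", TRUE)
  add(which(lengths(lapply(inj, `[[`, "severity")) == 0L), "no_injuries",
      "no coded AIS injuries; anatomic scores will be 0", FALSE)
  add(which(vapply(inj, function(d) any(d$severity == 6L), logical(1))),
      "unsurvivable_ais",
      "AIS severity 6 present; ISS/NISS set to 75", FALSE)
  if (!length(issues)) {
    return(data.frame(patient_id = character(0), rule = character(0),
                      message = character(0), fatal = logical(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, issues)
}

#' @rdname validate_cohort
#' @param record a one-row cohort data frame.
#' @export
validate_record <- function(record) validate_cohort(record)

#' Drop records failing the study inclusion rules
#'
#' @param cohort registry data frame.
#' @return list with elements `cohort` (records kept), `excluded` (records
#'   dropped), and `issues` (the full [validate_cohort()] table). Always
#'   satisfies `nrow(cohort) + nrow(excluded) == nrow(input)`.
#' @export
apply_exclusions <- function(cohort) {
  issues <- validate_cohort(cohort)
  fatal_ids <- unique(issues$patient_id[issues$fatal])
  drop <- cohort$patient_id %in% fatal_ids
  list(cohort = cohort[!drop, , drop = FALSE],
       excluded = cohort[drop, , drop = FALSE],
       issues = issues)
}
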