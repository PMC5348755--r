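#' @importFrom stats median rnorm runif sd quantile
#' @importFrom utils read.csv write.csv packageVersion
NULL

# Canonical long-format record columns. `calibration_state` is "na" for
# methods without a pre/post auto-calibration distinction (the reference).
RECORD_COLUMNS <- c("subject", "timepoint", "method", "variable",
                    "calibration_state", "value")
CALIBRATION_STATES <- c("precal", "postcal", "na")

#' Construct a study dataset
#'
#' A study dataset holds per-subject, per-timepoint measurements (cardiac
#' output in L/min, stroke volume in mL) from one reference method and one or
#' more test devices, each possibly in a pre- and post-auto-calibration state,
#' on a declared ordered schedule of timepoints.
#'
#' @param records data.frame with columns `subject`, `timepoint`, `method`,
#'   `variable` (one of `"CO"`, `"SV"`), `calibration_state` (one of
#'   `"precal"`, `"postcal"`, `"na"`), and non-negative numeric `value`.
#' @param schedule ordered character vector of timepoint labels; default
#'   `T0`..`T7`, the perioperative schedule from induction to 16 h after ICU
#'   admission.
#' @param fluid_challenge_interval length-2 character vector of adjacent
#'   schedule labels bracketing the fluid bolus (default `c("T4", "T5")`).
#' @return an object of class `study_dataset`: a list with elements
#'   `records`, `schedule` and `fluid_challenge_interval`.
#' @examples
#' rec <- data.frame(subject = "S01", timepoint = "T0", method = "td",
#'                   variable = "CO", calibration_state = "na", value = 5.1)
#' study_dataset(rec)
#' @export
study_dataset <- function(records,
                          schedule = paste0("T", 0:7),
                          fluid_challenge_interval = c("T4", "T5")) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  ds <- structure(
    list(records = records,
         schedule = as.character(schedule),
         fluid_challenge_interval = as.character(fluid_challenge_interval)),
    class = "study_dataset")
  validate_study_dataset(ds)
  ds
}

#' Validate a study dataset
#'
#' Checks the record schema, value range, schedule membership, key uniqueness
#' and the fluid-challenge interval. Errors name the offending rows.
#'
#' @param ds a `study_dataset`.
#' @return `ds`, invisibly, if valid.
#' @export
validate_study_dataset <- function(ds) {
  rec <- ds$records
  missing_cols <- setdiff(RECORD_COLUMNS, names(rec))
  if (length(missing_cols) > 0)
    stop_validation("missing record column(s): %s",
                    paste(missing_cols, collapse = ", "))
  if (anyDuplicated(ds$schedule))
    stop_validation("schedule labels must be unique")
  fci <- ds$fluid_challenge_interval
  if (length(fci) != 2)
    stop_validation("fluid_challenge_interval must have exactly 2 timepoints")
  pos <- match(fci, ds$schedule)
  if (anyNA(pos) || pos[2] != pos[1] + 1)
    stop_validation(
      "fluid_challenge_interval (%s, %s) must be adjacent schedule entries",
      fci[1], fci[2])
  if (nrow(rec) == 0) return(invisible(ds))

  if (!is.numeric(rec$value)) {
    bad <- which(is.na(suppressWarnings(as.numeric(rec$value))))
    stop_validation("non-numeric value in row(s): %s",
                    paste(utils::head(bad, 5), collapse = ", "))
  }
  bad <- which(!is.finite(rec$value) | rec$value < 0)
  if (length(bad) > 0)
    stop_validation("negative or non-finite value in row(s): %s",
                    paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(!rec$timepoint %in% ds$schedule)
  if (length(bad) > 0)
    stop_validation("timepoint outside declared schedule in row(s): %s",
                    paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(!rec$calibration_state %in% CALIBRATION_STATES)
  if (length(bad) > 0)
    stop_validation("unknown calibration_state in row(s): %s",
                    paste(utils::head(bad, 5), collapse = ", "))
  key <- do.call(paste, c(rec[c("subject", "timepoint", "method",
                                "variable", "calibration_state")],
                          sep = "\r"))
  dup <- which(duplicated(key))
  if (length(dup) > 0)
    stop_validation(
      "duplicate (subject, timepoint, method, variable, state) key in row(s): %s",
      paste(utils::head(dup, 5), collapse = ", "))
  invisible(ds)
}

#' @export
print.study_dataset <- function(x, ...) {
  rec <- x$records
  cat("Study dataset:", length(unique(rec$subject)), "subjects,",
      nrow(rec), "records\n")
  cat("  schedule:", paste(x$schedule, collapse = " "), "\n")
  cat("  fluid challenge:", paste(x$fluid_challenge_interval, collapse = " -> "),
      "\n")
  if (nrow(rec) > 0) {
    tab <- table(rec$method, rec$variable)
    cat("  records per method x variable:\n")
    print(tab)
  }
  invisible(x)
}

#' Read measurements from a long-format CSV file
#'
#' Expects a comma-separated, period-decimal file with a header row carrying
#' the canonical columns (`subject`, `timepoint`, `method`, `variable`,
#' `calibration_state`, `value`); a schema configuration can remap
#' non-standard column names.
#'
#' @param path CSV file path.
#' @param schema_config optional column remapping: either a named list/vector
#'   mapping canonical names to the names used in the file (e.g.
#'   `list(subject = "pat_id")`), or the path of a JSON file holding such a
#'   mapping.
#' @inheritParams study_dataset
#' @return a validated `study_dataset`.
#' @export
read_measurements <- function(path, schema_config = NULL,
                              schedule = paste0("T", 0:7),
                              fluid_challenge_interval = c("T4", "T5")) {
  if (!file.exists(path))
    stop_validation("input file not found: %s", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!is.null(schema_config)) {
    if (is.character(schema_config) && length(schema_config) == 1 &&
        file.exists(schema_config))
      schema_config <- jsonlite::read_json(schema_config, simplifyVector = TRUE)
    for (std in names(schema_config)) {
      actual <- schema_config[[std]]
      if (actual %in% names(raw))
        names(raw)[names(raw) == actual] <- std
    }
  }
  missing_cols <- setdiff(RECORD_COLUMNS, names(raw))
  if (length(missing_cols) > 0)
    stop_validation("%s: missing column(s): %s", path,
                    paste(missing_cols, collapse = ", "))
  val <- suppressWarnings(as.numeric(raw$value))
  bad <- which(is.na(val) & !is.na(raw$value) & nzchar(raw$value))
  if (length(bad) > 0)
    stop_validation("%s: non-numeric value at data row(s): %s", path,
                    paste(utils::head(bad, 5), collapse = ", "))
  raw$value <- val
  study_dataset(raw[RECORD_COLUMNS], schedule = schedule,
                fluid_challenge_interval = fluid_challenge_interval)
}

#' Write a study dataset to CSV
#'
#' Values are written with 17 significant digits so that a write/read
#' round-trip reproduces every record exactly.
#'
#' @param ds a `study_dataset`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(ds, path) {
  rec <- ds$records[RECORD_COLUMNS]
  rec$value <- sprintf("%.17g", rec$value)
  write.csv(rec, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a thermodilution measurement set
#'
#' One timepoint's transpulmonary thermodilution readings: cardiac output in
#' triplicate, each paired with the global end-diastolic volume (GEDV) reading
#' from the same dilution curve, plus an optional fourth reading taken when
#' the GEDV readings varied excessively.
#'
#' @param subject_id subject identifier.
#' @param timepoint timepoint label.
#' @param co numeric vector (length 3 or 4) of CO readings, L/min, all > 0.
#' @param gedv numeric vector of the paired GEDV readings, mL, all > 0.
#' @return an object of class `thermodilution_set`.
#' @export
thermodilution_set <- function(subject_id, timepoint, co, gedv) {
  if (length(co) != length(gedv))
    stop_validation("co and gedv must have equal length")
  if (length(co) < 3 || length(co) > 4)
    stop_validation("a thermodilution set holds 3 or 4 readings, got %d",
                    length(co))
  if (any(!is.finite(co)) || any(co <= 0))
    stop_validation("all CO readings must be finite and > 0")
  if (any(!is.finite(gedv)) || any(gedv <= 0))
    stop_validation("all GEDV readings must be finite and > 0")
  structure(list(subject_id = subject_id, timepoint = timepoint,
                 co = as.numeric(co), gedv = as.numeric(gedv)),
            class = "thermodilution_set")
}

#' Reduce a thermodilution set to a single CO value
#'
#' Implements the triplicate-averaging rule with the GEDV quality filter:
#' with three readings whose GEDV spread (range divided by mean) is within
#' the threshold, the mean CO is returned. If a fourth reading is present
#' (taken because the GEDV readings varied by more than the threshold), the
#' reading whose GEDV lies farthest from the median GEDV is discarded as the
#' extreme one and the mean of the remaining three CO values is returned.
#' Ties on GEDV distance are broken by the larger CO deviation from the CO
#' median, then by the later position.
#'
#' @param tdset a `thermodilution_set`.
#' @param spread_threshold maximal acceptable relative GEDV range
#'   (max - min) / mean; default 0.10.
#' @return the reduced CO value, L/min.
#' @export
reduce_thermodilution <- function(tdset, spread_threshold = 0.10) {
  co <- tdset$co
  gedv <- tdset$gedv
  if (length(co) == 3) {
    spread <- (max(gedv) - min(gedv)) / mean(gedv)
    if (spread > spread_threshold)
      stop_incomplete_set(
        paste0("GEDV spread %.1f%% exceeds %.0f%% for subject %s at %s and no ",
               "4th reading is available; supply a 4th reading or raise the ",
               "threshold"),
        100 * spread, 100 * spread_threshold,
        tdset$subject_id, tdset$timepoint)
    return(mean(co))
  }
  gd <- abs(gedv - median(gedv))
  worst <- which(gd == max(gd))
  if (length(worst) > 1) {
    cd <- abs(co - median(co))[worst]
    worst <- worst[cd == max(cd)]
    worst <- worst[length(worst)]
  }
  mean(co[-worst])
}

#' Construct pre-aligned paired samples
#'
#' Builds the paired (reference, test) container directly, for data that are
#' already aligned; `align_pairs()` builds the same container from a
#' `study_dataset`.
#'
#' @param subject subject identifiers.
#' @param timepoint timepoint labels.
#' @param ref_value reference-method values (> 0).
#' @param test_value test-method values (> 0), same units.
#' @param calibration_state calibration state of the test values.
#' @param schedule ordered timepoint labels (attached as an attribute, used
#'   by `compute_deltas()`).
#' @return a data.frame of class `paired_samples`.
#' @export
paired_samples <- function(subject, timepoint, ref_value, test_value,
                           calibration_state = "na",
                           schedule = unique(timepoint)) {
  if (any(!is.finite(ref_value)) || any(ref_value <= 0) ||
      any(!is.finite(test_value)) || any(test_value <= 0))
    stop_validation("paired values must be finite and > 0")
  out <- data.frame(subject = as.character(subject),
                    timepoint = as.character(timepoint),
                    ref_value = as.numeric(ref_value),
                    test_value = as.numeric(test_value),
                    calibration_state = calibration_state,
                    stringsAsFactors = FALSE)
  attr(out, "schedule") <- as.character(schedule)
  class(out) <- c("paired_samples", "data.frame")
  out
}

#' Align reference and test measurements into paired samples
#'
#' Forms one pair per (subject, timepoint) at which both the reference and the
#' test method report a value for the requested variable and calibration
#' state. Timepoints observed on only one side are skipped and counted in the
#' `n_skipped` attribute. The reference side uses its own `"na"` calibration
#' state when present (the reference has no auto-calibration), otherwise the
#' requested state.
#'
#' @param ds a `study_dataset`.
#' @param ref_method reference method identifier (e.g. `"td"`).
#' @param test_method test method identifier (e.g. `"pR"`).
#' @param variable `"CO"` or `"SV"`.
#' @param calibration_state test-device calibration state (`"precal"`,
#'   `"postcal"`, or `"na"`).
#' @return a `paired_samples` data.frame ordered by subject then schedule
#'   position, with attributes `n_skipped` and `schedule`.
#' @export
align_pairs <- function(ds, ref_method, test_method, variable = "CO",
                        calibration_state = "precal") {
  rec <- ds$records
  for (m in c(ref_method, test_method))
    if (!any(rec$method == m))
      stop_validation("method '%s' not present in dataset", m)
  ref <- rec[rec$method == ref_method & rec$variable == variable, ]
  ref_state <- if (any(ref$calibration_state == "na")) "na" else calibration_state
  ref <- ref[ref$calibration_state == ref_state, ]
  tst <- rec[rec$method == test_method & rec$variable == variable &
               rec$calibration_state == calibration_state, ]
  if (nrow(ref) == 0 || nrow(tst) == 0)
    stop_empty_result(
      "no overlapping (%s, %s) pairs for variable %s in state %s",
      ref_method, test_method, variable, calibration_state)
  key_ref <- paste(ref$subject, ref$timepoint, sep = "\r")
  key_tst <- paste(tst$subject, tst$timepoint, sep = "\r")
  common <- intersect(key_ref, key_tst)
  n_skipped <- (length(key_ref) - length(common)) +
    (length(key_tst) - length(common))
  if (length(common) == 0)
    stop_empty_result(
      "no overlapping (%s, %s) pairs for variable %s in state %s",
      ref_method, test_method, variable, calibration_state)
  ri <- match(common, key_ref)
  ti <- match(common, key_tst)
  out <- paired_samples(subject = ref$subject[ri],
                        timepoint = ref$timepoint[ri],
                        ref_value = ref$value[ri],
                        test_value = tst$value[ti],
                        calibration_state = calibration_state,
                        schedule = ds$schedule)
  ord <- order(out$subject, match(out$timepoint, ds$schedule))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("paired_samples", "data.frame")
  attr(out, "schedule") <- ds$schedule
  attr(out, "n_skipped") <- n_skipped
  attr(out, "ref_method") <- ref_method
  attr(out, "test_method") <- test_method
  attr(out, "variable") <- variable
  out
}
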