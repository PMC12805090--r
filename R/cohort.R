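# Cohort table: one row per participant, canonical units mmol/L for lipids
# and glucose, mmHg for blood pressure, years for time.

COHORT_COLUMNS <- c(
  "id", "age", "sex", "ethnicity", "systolic_bp", "on_bp_treatment",
  "total_chol", "hdl_chol", "current_smoker", "physician_dx_diabetes",
  "fasting_glucose", "random_glucose", "hba1c", "diabetes", "prevalent_cvd",
  "follow_up_years", "event_code", "event_fatal", "event_time_years")

COHORT_BOOL_COLS <- c("on_bp_treatment", "current_smoker",
                      "physician_dx_diabetes", "diabetes", "prevalent_cvd",
                      "event_fatal")
COHORT_NUM_COLS <- c("age", "systolic_bp", "total_chol", "hdl_chol",
                     "fasting_glucose", "random_glucose", "hba1c",
                     "follow_up_years", "event_time_years")

SEX_LEVELS <- c("male", "female")
ETHNICITY_LEVELS <- c("Chinese", "Malay", "Indian")

#' Derive baseline diabetes status
#'
#' Diabetes at baseline is defined as physician-diagnosed diabetes, or
#' fasting glucose >= 7 mmol/L, or random glucose >= 11 mmol/L, or
#' HbA1c >= 6.5%.  Missing source fields contribute `FALSE`; a participant
#' with all four sources missing has underivable status, which is an error.
#'
#' @param physician_dx logical: physician-diagnosed diabetes (NA allowed).
#' @param fasting_glucose fasting blood glucose, mmol/L (NA allowed).
#' @param random_glucose random blood glucose, mmol/L (NA allowed).
#' @param hba1c glycated haemoglobin, % (NA allowed).
#' @return logical vector.
#' @examples
#' derive_diabetes(NA, fasting_glucose = 7.2, NA, NA)  # TRUE
#' derive_diabetes(NA, NA, NA, hba1c = 6.4)            # FALSE
#' @export
derive_diabetes <- function(physician_dx = NA, fasting_glucose = NA,
                            random_glucose = NA, hba1c = NA) {
  n <- max(length(physician_dx), length(fasting_glucose),
           length(random_glucose), length(hba1c))
  physician_dx <- rep_len(as.logical(physician_dx), n)
  fasting_glucose <- rep_len(as.numeric(fasting_glucose), n)
  random_glucose <- rep_len(as.numeric(random_glucose), n)
  hba1c <- rep_len(as.numeric(hba1c), n)
  all_missing <- is.na(physician_dx) & is.na(fasting_glucose) &
    is.na(random_glucose) & is.na(hba1c)
  if (any(all_missing))
    stop("diabetes status underivable: all four source fields missing for ",
         sum(all_missing), " participant(s)")
  isTRUE_v <- function(x) !is.na(x) & x
  isTRUE_v(physician_dx) |
    isTRUE_v(fasting_glucose >= 7) |
    isTRUE_v(random_glucose >= 11) |
    isTRUE_v(hba1c >= 6.5)
}

#' Fill the derived diabetes column of a cohort
#'
#' Rows with `diabetes` already supplied are kept; missing entries are
#' derived with [derive_diabetes()].
#'
#' @param cohort cohort data frame.
#' @return the cohort with a complete logical `diabetes` column.
#' @export
resolve_diabetes <- function(cohort) {
  dm <- as.logical(cohort$diabetes)
  need <- is.na(dm)
  if (any(need))
    dm[need] <- derive_diabetes(cohort$physician_dx_diabetes[need],
                                cohort$fasting_glucose[need],
                                cohort$random_glucose[need],
                                cohort$hba1c[need])
  cohort$diabetes <- dm
  cohort
}

#' Validate a cohort table
#'
#' Checks column presence and the row invariants: positive age, systolic
#' blood pressure in (60, 300) mmHg, total cholesterol above HDL above
#' zero, non-negative follow-up, and event time no later than end of
#' follow-up when an event is recorded.
#'
#' @param cohort cohort data frame.
#' @return the validated cohort, invisibly.
#' @export
validate_cohort <- function(cohort) {
  missing_cols <- setdiff(COHORT_COLUMNS, names(cohort))
  if (length(missing_cols))
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "))
  bad <- function(cond, msg) if (any(cond, na.rm = TRUE))
    stop(msg, " (", sum(cond, na.rm = TRUE), " row(s))")
  bad(cohort$age <= 0, "age must be positive")
  bad(cohort$systolic_bp <= 60 | cohort$systolic_bp >= 300,
      "systolic_bp outside (60, 300) mmHg")
  bad(cohort$hdl_chol <= 0, "hdl_chol must be positive")
  bad(cohort$total_chol <= cohort$hdl_chol,
      "total_chol must exceed hdl_chol")
  bad(cohort$follow_up_years < 0, "follow_up_years must be non-negative")
  has_ev <- !is.na(cohort$event_code) & nzchar(cohort$event_code)
  bad(has_ev & (is.na(cohort$event_time_years) |
                  cohort$event_time_years > cohort$follow_up_years),
      "event_time_years must be present and <= follow_up_years for events")
  bad(!(cohort$sex %in% SEX_LEVELS), "sex must be 'male' or 'female'")
  bad(!(cohort$ethnicity %in% ETHNICITY_LEVELS),
      "ethnicity must be one of Chinese/Malay/Indian")
  invisible(cohort)
}

#' Read / write a cohort CSV
#'
#' The CSV uses the fixed 19-column layout documented in
#' `COHORT_COLUMNS`; booleans are encoded 0/1 and missing values as empty
#' cells.  `write_cohort_csv()` followed by `read_cohort_csv()` is
#' lossless.
#'
#' @param path file path.
#' @return `read_cohort_csv()` returns the cohort data frame.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  missing_cols <- setdiff(COHORT_COLUMNS, names(df))
  if (length(missing_cols))
    stop("cohort file lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- df[COHORT_COLUMNS]
  df$id <- as.character(df$id)
  df$event_code <- as.character(df$event_code)
  for (cl in COHORT_NUM_COLS) {
    v <- df[[cl]]
    if (!is.numeric(v)) {
      coerced <- suppressWarnings(as.numeric(v))
      if (any(is.na(coerced) & !is.na(v)))
        stop("non-numeric value in numeric column '", cl, "'")
      v <- coerced
    }
    df[[cl]] <- v
  }
  for (cl in COHORT_BOOL_COLS) {
    v <- df[[cl]]
    if (!all(v %in% c(0, 1, NA)))
      stop("column '", cl, "' must be 0/1/empty")
    df[[cl]] <- as.logical(v)
  }
  validate_cohort(df)
  df
}

#' @rdname read_cohort_csv
#' @param cohort cohort data frame to write.
#' @export
write_cohort_csv <- function(cohort, path) {
  validate_cohort(cohort)
  out <- cohort[COHORT_COLUMNS]
  for (cl in COHORT_BOOL_COLS) out[[cl]] <- as.integer(out[[cl]])
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

# canonical model-family key from the many spellings in use
match_model_family <- function(model) {
  key <- gsub("[^a-z0-9]", "", tolower(model))
  if (key %in% c("sgfrs", "sgfrs2023", "frs", "atp3", "atpiii")) return("sgfrs")
  if (key %in% c("pce", "pcew", "pceaa")) return("pce")
  if (key %in% c("score2", "score2ap", "score2asiapacific")) return("score2")
  stop("unknown model: ", model)
}

MODEL_AGE_WINDOWS <- list(sgfrs = c(20, 79), pce = c(40, 79),
                          score2 = c(40, 69))
MODEL_EXCLUDES_DIABETES <- c(sgfrs = TRUE, pce = FALSE, score2 = TRUE)

#' Apply a model's eligibility filters to a cohort
#'
#' All models exclude prevalent cardiovascular disease.  Age windows are
#' 20-79 years (SG-FRS-2023), 40-79 (PCE) and 40-69 (SCORE2); participants
#' with baseline diabetes are additionally excluded for SG-FRS-2023 and
#' SCORE2 (the PCE includes diabetes as a predictor).  The returned cohort
#' carries the step-by-step exclusion counts as `attr(., "exclusions")`,
#' in the style of a study flow chart.
#'
#' @param cohort cohort data frame with `diabetes` and `prevalent_cvd`
#'   resolved for every row.
#' @param model model name (`"sgfrs"`, `"pce"`, `"score2"`, or common
#'   aliases such as `"SG-FRS-2023"`, `"PCE-W"`, `"SCORE2-AP"`).
#' @return the eligible subset, with an exclusion ledger attribute.
#' @export
filter_eligible <- function(cohort, model) {
  fam <- match_model_family(model)
  if (any(is.na(cohort$prevalent_cvd)) || any(is.na(cohort$diabetes)))
    stop("prevalent_cvd and diabetes must be resolved before filtering; ",
         "see resolve_diabetes()")
  ledger <- data.frame(step = character(), n_removed = integer(),
                       n_remaining = integer())
  note <- function(step, keep, df) {
    ledger <<- rbind(ledger, data.frame(
      step = step, n_removed = sum(!keep), n_remaining = sum(keep)))
    df[keep, , drop = FALSE]
  }
  out <- note("prevalent CVD at baseline", !cohort$prevalent_cvd, cohort)
  win <- MODEL_AGE_WINDOWS[[fam]]
  out <- note(sprintf("age outside %d-%d years", win[1], win[2]),
              out$age >= win[1] & out$age < win[2] + 1, out)
  if (MODEL_EXCLUDES_DIABETES[[fam]])
    out <- note("diabetes at baseline", !out$diabetes, out)
  attr(out, "exclusions") <- ledger
  attr(out, "model") <- fam
  out
}
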