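# ICD-10 code ranges and endpoint definitions.
#
# Each endpoint (CHD, ASCVD, CVD) is a pair of ICD-10 range sets, one for
# non-fatal events and one for fatal events.  Range semantics are
# root-based: a code matches a range when its 3-character root (letter plus
# two digits) falls inside the inclusive letter-number interval, so "I63.9"
# matches "I60-I63" through its root "I63".

ICD10_ROOT_RE <- "^[A-Z][0-9]{2}"

# parse "I20-I25", "I67–I69" or a single root "I70" into letter + interval
parse_icd10_range <- function(range) {
  stopifnot(is.character(range), length(range) == 1L)
  x <- gsub("–|—", "-", trimws(range))
  parts <- strsplit(x, "-", fixed = TRUE)[[1]]
  if (length(parts) == 1L) parts <- c(parts, parts)
  if (length(parts) != 2L || !all(grepl("^[A-Z][0-9]{2}$", parts)))
    stop("malformed ICD-10 range: ", range)
  letters_ <- substr(parts, 1L, 1L)
  if (letters_[1] != letters_[2])
    stop("ICD-10 range must stay within one letter block: ", range)
  nums <- as.integer(substr(parts, 2L, 3L))
  if (nums[1] > nums[2]) stop("ICD-10 range is reversed: ", range)
  list(letter = letters_[1], lo = nums[1], hi = nums[2])
}

icd10_root <- function(code) {
  code <- toupper(trimws(code))
  ok <- grepl(ICD10_ROOT_RE, code)
  if (any(!ok))
    stop("malformed ICD-10 code(s): ",
         paste(unique(code[!ok]), collapse = ", "))
  substr(code, 1L, 3L)
}

# vectorised membership of codes in a character vector of ranges
icd10_in_ranges <- function(codes, ranges) {
  if (length(codes) == 0L) return(logical(0))
  roots <- icd10_root(codes)
  letter <- substr(roots, 1L, 1L)
  num <- as.integer(substr(roots, 2L, 3L))
  hit <- rep(FALSE, length(codes))
  for (r in lapply(ranges, parse_icd10_range))
    hit <- hit | (letter == r$letter & num >= r$lo & num <= r$hi)
  hit
}

#' Define a cardiovascular endpoint as ICD-10 range sets
#'
#' @param name endpoint name, one of `"CHD"`, `"ASCVD"`, `"CVD"` (other
#'   labels are allowed for custom endpoints).
#' @param nonfatal character vector of ICD-10 ranges (e.g. `"I21-I22"`)
#'   defining qualifying non-fatal events.
#' @param fatal character vector of ICD-10 ranges defining qualifying
#'   causes of death.
#' @return an object of class `endpoint_spec`.
#' @seealso [default_endpoints()] for the shipped CHD/ASCVD/CVD definitions.
#' @export
endpoint_spec <- function(name, nonfatal, fatal) {
  lapply(c(nonfatal, fatal), parse_icd10_range)  # validate eagerly
  structure(list(name = name,
                 nonfatal = as.character(nonfatal),
                 fatal = as.character(fatal)),
            class = "endpoint_spec")
}

#' @export
print.endpoint_spec <- function(x, ...) {
  cat("Endpoint:", x$name, "\n")
  cat("  non-fatal:", paste(x$nonfatal, collapse = ", "), "\n")
  cat("  fatal:    ", paste(x$fatal, collapse = ", "), "\n")
  invisible(x)
}

#' Shipped endpoint definitions
#'
#' Reads the packaged endpoint configuration: CHD (non-fatal myocardial
#' infarction plus ischaemic heart disease mortality, I20-I25), ASCVD
#' (CHD plus non-fatal stroke and cerebrovascular mortality, I60-I63 and
#' I67-I69) and the broader CVD endpoint used by SCORE2 (hypertensive
#' disease, ischaemic heart disease, arrhythmias and heart failure,
#' cerebrovascular disease and atherosclerosis).  The exact CVD code set is
#' configurable: pass your own JSON file to [read_endpoint_specs()] to
#' override it.
#'
#' @return named list of [endpoint_spec()] objects.
#' @export
default_endpoints <- function() {
  read_endpoint_specs(system.file("extdata", "endpoints.json",
                                  package = "cvdrecal", mustWork = TRUE))
}

#' Read endpoint definitions from a JSON file
#'
#' The file maps endpoint name to `{"nonfatal": [ranges], "fatal": [ranges]}`.
#'
#' @param path path to a JSON endpoint configuration.
#' @return named list of [endpoint_spec()] objects.
#' @export
read_endpoint_specs <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(names(raw), function(nm)
    endpoint_spec(nm, raw[[nm]]$nonfatal, raw[[nm]]$fatal))
  setNames(out, names(raw))
}

#' Does an event code qualify for an endpoint?
#'
#' @param event_code character vector of ICD-10 codes (sub-codes such as
#'   `"I63.9"` match through their 3-character root).
#' @param fatal logical vector: was the event fatal?  Fatal events are
#'   matched against the endpoint's fatal range set, non-fatal events
#'   against the non-fatal set.
#' @param spec an [endpoint_spec()].
#' @return logical vector.
#' @examples
#' ep <- default_endpoints()
#' map_event_to_endpoint("I63", fatal = TRUE, ep$ASCVD)   # TRUE
#' map_event_to_endpoint("I63", fatal = TRUE, ep$CHD)     # FALSE
#' @export
map_event_to_endpoint <- function(event_code, fatal, spec) {
  stopifnot(inherits(spec, "endpoint_spec"), is.logical(fatal))
  fatal <- rep_len(fatal, length(event_code))
  out <- logical(length(event_code))
  if (any(!fatal))
    out[!fatal] <- icd10_in_ranges(event_code[!fatal], spec$nonfatal)
  if (any(fatal))
    out[fatal] <- icd10_in_ranges(event_code[fatal], spec$fatal)
  out
}

#' Resolve per-participant survival outcomes for one endpoint
#'
#' Maps each participant's recorded first event (if any) onto the endpoint:
#' participants whose event qualifies contribute an event at
#' `event_time_years`; everyone else is censored at `follow_up_years`
#' (non-qualifying events, including deaths from other causes, censor at
#' the recorded follow-up end).
#'
#' @param cohort a cohort data frame (see [read_cohort_csv()]).
#' @param spec an [endpoint_spec()].
#' @return data frame with columns `time` (years) and `event` (0/1).
#' @export
survival_outcomes <- function(cohort, spec) {
  has_code <- !is.na(cohort$event_code) & nzchar(cohort$event_code)
  event <- logical(nrow(cohort))
  if (any(has_code)) {
    fatal <- as.logical(cohort$event_fatal[has_code])
    fatal[is.na(fatal)] <- FALSE
    event[has_code] <- map_event_to_endpoint(cohort$event_code[has_code],
                                             fatal, spec)
  }
  time <- ifelse(event, cohort$event_time_years, cohort$follow_up_years)
  if (any(is.na(time)))
    stop("missing event_time_years for rows with a qualifying event, ",
         "or missing follow_up_years")
  data.frame(time = time, event = as.integer(event))
}
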