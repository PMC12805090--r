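# Coefficient-driven 10-year risk engines.
#
# Every engine shares one functional form: a linear predictor LP built from
# transformed risk factors, and risk = 1 - S0(10)^exp(LP - mean LP), where
# S0(10) is the stratum's average 10-year event-free survival.  The engines
# differ only in their coefficient sets, which ship as versioned JSON files
# under inst/extdata/coefficients (PCE for Whites and African Americans,
# Framingham ATP-III hard-CHD, SCORE2).  Transcription errors are therefore
# data bugs, not code bugs, and the evaluator can be tested with synthetic
# coefficient sets.

# fields that are indicator variables: passed through products untouched,
# never log-transformed or centred
BOOLEAN_FIELDS <- c("current_smoker", "on_bp_treatment", "off_bp_treatment",
                    "diabetes")
CHOL_FIELDS <- c("total_chol", "hdl_chol")
MG_PER_MMOL_CHOL <- 38.67

#' Construct a coefficient set
#'
#' A coefficient set is one stratum (sex, and optionally ethnicity or
#' region) of one published risk model.  Each term is a product of one or
#' more predictors joined by `":"` in `name`; per-factor options `cap`
#' (upper truncation), `center` and `scale` (affine standardisation) are
#' applied before `transform` (`"identity"`, `"ln"`, or `"ln2"` for
#' squared log).  Indicator predictors enter products as 0/1 regardless of
#' the transform.
#'
#' @param model model identifier string (e.g. `"pce_w"`).
#' @param stratum list with `sex` and optional `group` (ethnicity/region).
#' @param units list with `chol` (`"mg/dL"` or `"mmol/L"`) and `sbp`
#'   (`"mmHg"`); cohort lipids in mmol/L are converted automatically.
#' @param terms list of term lists: `name`, `transform`, `coef`, optional
#'   `cap`, `center`, `scale` (scalar or per-factor vector).
#' @param mean_lp population mean of the linear predictor (subtracted
#'   before exponentiation; engines published already centred use 0).
#' @param baseline_survival_10y average 10-year event-free survival
#'   S0(10), in (0, 1].
#' @param source free-text provenance of the coefficients.
#' @return object of class `coef_set`.
#' @export
coefficient_set <- function(model, stratum, units, terms, mean_lp,
                            baseline_survival_10y, source = "") {
  stopifnot(is.list(terms), length(terms) >= 0,
            is.finite(mean_lp),
            baseline_survival_10y > 0, baseline_survival_10y <= 1)
  if (!is.null(units$chol) && !units$chol %in% c("mg/dL", "mmol/L"))
    stop("units$chol must be 'mg/dL' or 'mmol/L'")
  for (tm in terms) {
    stopifnot(is.character(tm$name), is.numeric(tm$coef))
    if (!tm$transform %in% c("identity", "ln", "ln2"))
      stop("unknown transform: ", tm$transform)
  }
  structure(list(model = model, stratum = stratum, units = units,
                 terms = terms, mean_lp = mean_lp,
                 baseline_survival_10y = baseline_survival_10y,
                 source = source),
            class = "coef_set")
}

#' @export
print.coef_set <- function(x, ...) {
  cat(sprintf("<coef_set %s | %s%s>  %d terms, mean LP %.4g, S0(10) %.4f\n",
              x$model, x$stratum$sex,
              if (is.null(x$stratum$group)) "" else paste0("/", x$stratum$group),
              length(x$terms), x$mean_lp, x$baseline_survival_10y))
  invisible(x)
}

# resolve one predictor column in the coefficient set's units
resolve_predictor <- function(cohort, name, units) {
  if (name == "off_bp_treatment") {
    # complement on the prevalence scale so mean-profile rows (fractional
    # indicators) evaluate correctly
    x <- 1 - as.numeric(cohort$on_bp_treatment)
  } else {
    if (is.null(cohort[[name]]))
      stop("unresolvable predictor name: ", name)
    x <- as.numeric(cohort[[name]])
  }
  if (name %in% CHOL_FIELDS && identical(units$chol, "mg/dL"))
    x <- x * MG_PER_MMOL_CHOL
  x
}

eval_term <- function(cohort, term, units) {
  factors <- strsplit(term$name, ":", fixed = TRUE)[[1]]
  get_opt <- function(opt, k) {
    v <- term[[opt]]
    if (is.null(v)) return(NA_real_)
    v <- unlist(v)
    if (length(v) == 1L && length(factors) > 1L) v <- rep(v, length(factors))
    as.numeric(v[k])
  }
  out <- 1
  for (k in seq_along(factors)) {
    nm <- factors[k]
    x <- resolve_predictor(cohort, nm, units)
    if (!nm %in% BOOLEAN_FIELDS) {
      cap <- get_opt("cap", k)
      if (!is.na(cap)) x <- pmin(x, cap)
      ctr <- get_opt("center", k)
      scl <- get_opt("scale", k)
      if (!is.na(ctr)) x <- x - ctr
      if (!is.na(scl)) x <- x / scl
      if (term$transform %in% c("ln", "ln2")) {
        if (any(x <= 0, na.rm = TRUE))
          stop("non-positive value passed to ln for predictor '", nm, "'")
        x <- log(x)
        if (term$transform == "ln2") x <- x^2
      }
    }
    out <- out * x
  }
  out
}

#' Linear predictor of a coefficient set
#'
#' Evaluates `LP = sum(coef * transform(predictor))` for every row of the
#' cohort, in the coefficient set's declared units.
#'
#' @param cohort cohort data frame (or any data frame exposing the
#'   predictors the term list names; indicator predictors may be
#'   fractional, as when evaluating at a mean risk-factor profile).
#' @param cs a [coefficient_set()].
#' @return numeric vector of linear predictors.
#' @export
linear_predictor <- function(cohort, cs) {
  stopifnot(inherits(cs, "coef_set"))
  lp <- numeric(nrow(cohort))
  for (tm in cs$terms) lp <- lp + tm$coef * eval_term(cohort, tm, cs$units)
  if (any(is.na(lp)))
    stop("missing predictor values for ", sum(is.na(lp)), " row(s)")
  lp
}

#' 10-year risk from a linear predictor
#'
#' `risk = 1 - S0(10)^exp(lp - mean_lp)`: the Cox-type survival formula
#' with the stratum's average 10-year survival as baseline.  Strictly
#' increasing in `lp`.
#'
#' @param lp numeric vector of linear predictors.
#' @param cs a [coefficient_set()].
#' @return numeric vector of probabilities in `[0, 1)`.
#' @export
risk_from_lp <- function(lp, cs) {
  stopifnot(inherits(cs, "coef_set"))
  1 - cs$baseline_survival_10y^exp(lp - cs$mean_lp)
}

#' Batch 10-year risk prediction
#'
#' Matches each cohort row to the coefficient set for its stratum (by sex,
#' and by ethnicity when the sets carry an ethnic `group`) and returns one
#' risk per row.  Deterministic given the coefficient files.
#'
#' @param cohort cohort data frame, pre-filtered with [filter_eligible()]
#'   for the model in question.
#' @param coefsets a single [coefficient_set()] applied to every row, or a
#'   list of sets covering all sex (x ethnicity) strata present.
#' @return data frame `id`, `model`, `risk_10y`.
#' @export
predict_risk <- function(cohort, coefsets) {
  if (inherits(coefsets, "coef_set")) coefsets <- list(coefsets)
  model <- coefsets[[1]]$model
  if (nrow(cohort) == 0L)
    return(data.frame(id = character(0), model = character(0),
                      risk_10y = numeric(0)))
  risk <- rep(NA_real_, nrow(cohort))
  for (cs in coefsets) {
    sel <- cohort$sex == cs$stratum$sex
    if (!is.null(cs$stratum$group) && cs$stratum$group %in% ETHNICITY_LEVELS)
      sel <- sel & cohort$ethnicity == cs$stratum$group
    if (!any(sel)) next
    lp <- linear_predictor(cohort[sel, , drop = FALSE], cs)
    risk[sel] <- risk_from_lp(lp, cs)
  }
  if (any(is.na(risk)))
    stop("no coefficient set matches ", sum(is.na(risk)),
         " row(s); offending ids: ",
         paste(head(cohort$id[is.na(risk)], 5), collapse = ", "))
  data.frame(id = cohort$id, model = model, risk_10y = risk)
}

#' Localise a Framingham-type model by baseline-survival substitution
#'
#' Re-derives a model for a local population by replacing the published
#' average 10-year survival with each sex-by-ethnicity stratum's
#' Kaplan-Meier 10-year event-free survival for the chosen endpoint, with
#' all coefficients unchanged.  This is the construction behind locally
#' recalibrated Framingham/ATP-III scores; being a monotone transform of
#' the linear predictor it leaves within-stratum discrimination untouched.
#'
#' @param base_sets list of [coefficient_set()] per sex (the published
#'   model).
#' @param cohort development cohort, already filtered to the model's
#'   eligibility.
#' @param spec [endpoint_spec()] defining the endpoint (default CHD).
#' @param horizon risk horizon in years.
#' @return list of coefficient sets, one per sex-by-ethnicity stratum
#'   present in the cohort.
#' @export
sg_frs_localize <- function(base_sets, cohort, spec = default_endpoints()$CHD,
                            horizon = 10) {
  if (inherits(base_sets, "coef_set")) base_sets <- list(base_sets)
  out <- list()
  for (cs in base_sets) {
    for (eth in intersect(ETHNICITY_LEVELS, unique(cohort$ethnicity))) {
      sel <- cohort$sex == cs$stratum$sex & cohort$ethnicity == eth
      if (!any(sel)) next
      oc <- survival_outcomes(cohort[sel, , drop = FALSE], spec)
      km <- km_observed_risk(oc$time, oc$event, horizon = horizon)
      if (is.na(km$risk))
        stop("inestimable 10-year survival for stratum ",
             cs$stratum$sex, "/", eth)
      loc <- cs
      loc$model <- paste0(cs$model, "_localized")
      loc$stratum$group <- eth
      loc$baseline_survival_10y <- 1 - km$risk
      loc$source <- paste0(cs$source, "; S0(10) replaced by stratum ",
                           "Kaplan-Meier estimate")
      out[[paste(cs$stratum$sex, eth, sep = "_")]] <- loc
    }
  }
  out
}

#' Regional rescaling of an uncalibrated SCORE2 risk
#'
#' Applies the published region-specific rescaling factors on the cloglog
#' scale (shared transform with [apply_recalibration()]).
#'
#' @param uncalibrated_risk probabilities strictly in (0, 1).
#' @param factors list with `scale1` and `scale2`.
#' @return rescaled probabilities.
#' @export
score2_region_rescale <- function(uncalibrated_risk, factors) {
  cloglog_rescale(uncalibrated_risk, factors$scale1, factors$scale2)
}

# ---- coefficient file I/O -------------------------------------------------

coef_dir <- function() system.file("extdata", "coefficients",
                                   package = "cvdrecal", mustWork = TRUE)

#' Read / write a coefficient set as JSON
#'
#' @param path JSON file path.
#' @return `read_coefficient_set()` returns a [coefficient_set()].
#' @export
read_coefficient_set <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  coefficient_set(model = raw$model, stratum = raw$stratum,
                  units = raw$units,
                  terms = lapply(raw$terms, function(tm) {
                    tm$coef <- as.numeric(tm$coef); tm
                  }),
                  mean_lp = as.numeric(raw$mean_lp),
                  baseline_survival_10y = as.numeric(raw$baseline_survival_10y),
                  source = if (is.null(raw$source)) "" else raw$source)
}

#' @rdname read_coefficient_set
#' @param cs a [coefficient_set()] to write.
#' @export
write_coefficient_set <- function(cs, path) {
  jsonlite::write_json(unclass(cs), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load the packaged coefficient sets for a model
#'
#' @param model one of `"pce_w"`, `"pce_aa"`, `"frs_atp3"` (the base model
#'   behind SG-FRS-type localisation), `"score2"`.
#' @return named list with elements `male` and `female`.
#' @export
load_coefficient_sets <- function(model = c("pce_w", "pce_aa", "frs_atp3",
                                            "score2")) {
  model <- match.arg(model)
  sets <- lapply(c(male = "male", female = "female"), function(sx)
    read_coefficient_set(file.path(coef_dir(),
                                   sprintf("%s_%s.json", model, sx))))
  sets
}

#' Packaged low-risk-region rescaling factors for SCORE2
#'
#' @return named list of per-sex factor lists (`scale1`, `scale2`).
#' @export
load_score2_rescaling <- function() {
  raw <- jsonlite::read_json(file.path(coef_dir(),
                                       "score2_rescaling_low.json"),
                             simplifyVector = FALSE)
  out <- lapply(raw$strata, function(s)
    list(scale1 = as.numeric(s$scale1), scale2 = as.numeric(s$scale2)))
  setNames(out, vapply(raw$strata, `[[`, "", "sex"))
}

#' Verify packaged coefficient files against the shipped checksums
#'
#' The manifest records an md5 checksum per coefficient file so silent
#' edits to the transcribed published coefficients are detectable.
#'
#' @return `TRUE` invisibly on success; stops on mismatch.
#' @export
verify_coefficients <- function() {
  manifest <- jsonlite::read_json(file.path(coef_dir(), "manifest.json"),
                                  simplifyVector = TRUE)
  for (f in names(manifest)) {
    sum <- unname(tools::md5sum(file.path(coef_dir(), f)))
    if (!identical(sum, manifest[[f]]))
      stop("coefficient file '", f, "' fails its checksum")
  }
  invisible(TRUE)
}
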