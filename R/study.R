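# End-to-end study workflow: simulate (or load) a development and a
# validation cohort, predict with each model, derive recalibration
# factors on the development cohort only, validate on the independent
# cohort, and emit table-style artifacts.

eval_by_strata <- function(cohort, risk, spec, n_groups = 5, horizon = 10) {
  oc <- survival_outcomes(cohort, spec)
  overall <- evaluate_model(risk, oc$time, oc$event, n_groups, horizon)
  strata <- list()
  for (sx in intersect(SEX_LEVELS, unique(cohort$sex)))
    for (eth in intersect(ETHNICITY_LEVELS, unique(cohort$ethnicity))) {
      i <- cohort$sex == sx & cohort$ethnicity == eth
      if (sum(i) < 2 || sum(oc$event[i]) == 0) next
      strata[[paste(sx, eth, sep = "_")]] <-
        tryCatch(evaluate_model(risk[i], oc$time[i], oc$event[i],
                                n_groups, horizon),
                 error = function(e) list(error = conditionMessage(e)))
    }
  list(overall = overall, strata = strata)
}

predict_for_model <- function(model, dev, val, spec_list, factors_env) {
  ep <- switch(model, sgfrs = spec_list$CHD, pce_w = spec_list$ASCVD,
               pce_aa = spec_list$ASCVD, score2 = spec_list$CVD)
  dev_f <- filter_eligible(dev, if (model %in% c("pce_w", "pce_aa"))
    "pce" else if (model == "sgfrs") "sgfrs" else "score2")
  val_f <- filter_eligible(val, attr(dev_f, "model"))
  out <- list(endpoint = ep$name,
              exclusions = list(dev = attr(dev_f, "exclusions"),
                                val = attr(val_f, "exclusions")))
  if (model == "sgfrs") {
    base <- load_coefficient_sets("frs_atp3")
    localized <- sg_frs_localize(base, dev_f, spec = ep)
    out$risk_dev <- predict_risk(dev_f, localized)$risk_10y
    out$risk_val <- predict_risk(val_f, localized)$risk_10y
  } else if (model %in% c("pce_w", "pce_aa")) {
    sets <- load_coefficient_sets(model)
    raw_dev <- predict_risk(dev_f, sets)$risk_10y
    raw_val <- predict_risk(val_f, sets)$risk_10y
    bands <- age_bands(MODEL_AGE_WINDOWS$pce[1], MODEL_AGE_WINDOWS$pce[2])
    summ <- band_summaries(dev_f, sets, ep, bands)
    factors <- derive_rescaling_factors(summ)
    factors_env[[model]] <- factors
    out$factors <- factors
    out$risk_dev <- apply_recalibration(raw_dev, factors, dev_f$sex,
                                        dev_f$ethnicity)
    out$risk_val <- apply_recalibration(raw_val, factors, val_f$sex,
                                        val_f$ethnicity)
    out$risk_dev_original <- raw_dev
    out$risk_val_original <- raw_val
  } else if (model == "score2") {
    sets <- load_coefficient_sets("score2")
    resc <- load_score2_rescaling()
    raw_dev <- predict_risk(dev_f, sets)$risk_10y
    raw_val <- predict_risk(val_f, sets)$risk_10y
    out$risk_dev <- ifelse(dev_f$sex == "male",
                           score2_region_rescale(raw_dev, resc$male),
                           score2_region_rescale(raw_dev, resc$female))
    out$risk_val <- ifelse(val_f$sex == "male",
                           score2_region_rescale(raw_val, resc$male),
                           score2_region_rescale(raw_val, resc$female))
  } else stop("unknown model: ", model)
  out$dev <- dev_f
  out$val <- val_f
  out
}

#' Run the full recalibration-and-validation study workflow
#'
#' Simulates a development and a validation cohort, computes each model's
#' predictions (SG-FRS-style localisation and PCE recalibration factors
#' are derived on the development cohort only and applied unchanged to
#' the validation cohort - nothing is refit on validation data), and
#' evaluates discrimination, calibration, goodness-of-fit, quantile
#' tables and decision curves per cohort, overall and per sex-by-ethnicity
#' stratum.
#'
#' @param dev_config [generator_config()] for the development cohort.
#' @param val_config [generator_config()] for the validation cohort.
#' @param models character vector drawn from `"sgfrs"`, `"pce_w"`,
#'   `"pce_aa"`, `"score2"`.
#' @param seed root seed; the development and validation cohorts are
#'   drawn from seeds derived from it.
#' @param out_dir optional directory; when given, the report JSON and the
#'   table CSVs are written there.
#' @param n_groups risk-quantile groups for calibration tables.
#' @return object of class `cvd_study`: per-model evaluations,
#'   rescaling factors, exclusion ledgers, decision curves, and a
#'   provenance block (seeds and config hashes).
#' @export
run_study <- function(dev_config, val_config,
                      models = c("sgfrs", "pce_w", "score2"),
                      seed = 1L, out_dir = NULL, n_groups = 5) {
  stopifnot(inherits(dev_config, "generator_config"),
            inherits(val_config, "generator_config"))
  dev <- generate_cohort(dev_config, seed = seed)
  val <- generate_cohort(val_config, seed = seed + 1L)
  spec_list <- default_endpoints()
  factors_env <- new.env()
  report <- list(models = list(), decision_curves = list())
  for (m in models) {
    pm <- predict_for_model(m, dev, val, spec_list, factors_env)
    ep <- spec_list[[pm$endpoint]]
    entry <- list(
      endpoint = pm$endpoint,
      exclusions = pm$exclusions,
      dev = eval_by_strata(pm$dev, pm$risk_dev, ep, n_groups),
      val = eval_by_strata(pm$val, pm$risk_val, ep, n_groups))
    if (!is.null(pm$factors)) entry$factors <- pm$factors
    report$models[[m]] <- entry
    oc_val <- survival_outcomes(pm$val, ep)
    report$decision_curves[[m]] <-
      decision_curve(pm$risk_val, oc_val$time, oc_val$event)
  }
  report$provenance <- list(
    seed = seed,
    dev_seed = seed, val_seed = seed + 1L,
    dev_config_hash = config_hash(dev_config),
    val_config_hash = config_hash(val_config),
    models = models,
    package_version = as.character(utils::packageVersion("cvdrecal")))
  report <- structure(report, class = "cvd_study")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(study_report_json(report),
                         file.path(out_dir, "study_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    render_tables(report, out_dir)
  }
  report
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA),
             tmp)
  unname(tools::md5sum(tmp))
}

# strip non-serialisable pieces for the JSON report
study_report_json <- function(report) {
  scrub <- function(x) {
    if (inherits(x, "cvd_eval")) return(unclass(x))
    if (is.data.frame(x)) return(x)
    if (is.list(x)) return(lapply(x, scrub))
    x
  }
  scrub(unclass(report))
}

eval_row <- function(ev) {
  if (!is.null(ev$error))
    return(data.frame(n = NA, c_index = NA, c_lower = NA, c_upper = NA,
                      band = NA, n_observed_events = NA,
                      n_predicted_events = NA, citl = NA, citl_lower = NA,
                      citl_upper = NA, slope = NA, slope_lower = NA,
                      slope_upper = NA, deviance = NA, poor_fit = NA,
                      reason = ev$error))
  data.frame(
    n = ev$n,
    c_index = ev$c_index$c_index, c_lower = ev$c_index$lower,
    c_upper = ev$c_index$upper, band = ev$discrimination_band,
    n_observed_events = ev$n_observed_events_adj,
    n_predicted_events = ev$n_predicted_events,
    citl = ev$calibration$citl, citl_lower = ev$calibration$citl_lower,
    citl_upper = ev$calibration$citl_upper,
    slope = ev$calibration$slope,
    slope_lower = ev$calibration$slope_lower,
    slope_upper = ev$calibration$slope_upper,
    deviance = ev$gof$deviance, poor_fit = ev$gof$poor_fit,
    reason = "")
}

#' Write table-style CSV artifacts from a study report
#'
#' Emits `table1.csv` (C-indices per model, cohort and stratum),
#' `table2.csv` (observed/predicted events, calibration-in-the-large,
#' slope and deviance per stratum, with poor-fit flags), `exclusions.csv`
#' (flow-chart ledgers) and `decision_curves.csv`.  Inestimable cells are
#' written as `NA` with the reason in a `reason` column.
#'
#' @param report a `cvd_study` from [run_study()].
#' @param out_dir output directory.
#' @return invisibly, the paths written.
#' @export
render_tables <- function(report, out_dir) {
  stopifnot(inherits(report, "cvd_study"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list(); excl <- list(); dca <- list()
  for (m in names(report$models)) {
    entry <- report$models[[m]]
    for (coh in c("dev", "val")) {
      evs <- c(list(overall = entry[[coh]]$overall), entry[[coh]]$strata)
      for (nm in names(evs)) {
        r <- eval_row(evs[[nm]])
        r <- cbind(data.frame(model = m, cohort = coh, stratum = nm), r)
        rows[[length(rows) + 1L]] <- r
      }
      ex <- entry$exclusions[[coh]]
      excl[[length(excl) + 1L]] <-
        cbind(data.frame(model = m, cohort = coh), ex)
    }
    dca[[length(dca) + 1L]] <-
      cbind(data.frame(model = m), report$decision_curves[[m]])
  }
  tab <- do.call(rbind, rows)
  table1 <- tab[c("model", "cohort", "stratum", "n", "c_index", "c_lower",
                  "c_upper", "band", "reason")]
  table2 <- tab[c("model", "cohort", "stratum", "n", "n_observed_events",
                  "n_predicted_events", "citl", "citl_lower", "citl_upper",
                  "slope", "slope_lower", "slope_upper", "deviance",
                  "poor_fit", "reason")]
  paths <- c(table1 = file.path(out_dir, "table1.csv"),
             table2 = file.path(out_dir, "table2.csv"),
             exclusions = file.path(out_dir, "exclusions.csv"),
             dca = file.path(out_dir, "decision_curves.csv"))
  utils::write.csv(table1, paths["table1"], row.names = FALSE, na = "NA")
  utils::write.csv(table2, paths["table2"], row.names = FALSE, na = "NA")
  utils::write.csv(do.call(rbind, excl), paths["exclusions"],
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, dca), paths["dca"], row.names = FALSE)
  invisible(paths)
}

#' @export
print.cvd_study <- function(x, ...) {
  cat("CVD risk model study report\n")
  for (m in names(x$models)) {
    e <- x$models[[m]]
    cat(sprintf("  %s (%s): dev C %.3f, val C %.3f; val CITL %.3f, slope %.3f\n",
                m, e$endpoint,
                e$dev$overall$c_index$c_index,
                e$val$overall$c_index$c_index,
                e$val$overall$calibration$citl,
                e$val$overall$calibration$slope))
  }
  invisible(x)
}
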