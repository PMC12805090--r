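# Sex- and ethnicity-specific recalibration of a risk engine.
#
# The procedure relates, within each sex-by-ethnicity stratum, the
# age-band average expected 10-year risk (Kaplan-Meier) to the age-band
# average predicted risk (the engine evaluated at the band's mean
# risk-factor profile), fits a weighted least-squares line on the
# complementary log-log scale, and applies the fitted intercept/slope
# (scale1, scale2) to individual predictions.  With scale2 > 0 the map is
# strictly monotone, so recalibration never changes discrimination.

#' Five-year age bands over an age window
#'
#' @param lo,hi window bounds in years (bands are `[lo, lo+width)`, ...).
#' @param width band width in years (default 5).
#' @return data frame with columns `lo` and `hi`.
#' @export
age_bands <- function(lo, hi, width = 5) {
  starts <- seq(lo, hi, by = width)
  starts <- starts[starts < hi + 1]
  data.frame(lo = starts, hi = pmin(starts + width, hi + 1))
}

#' Age-band expected and predicted 10-year risk per stratum
#'
#' For every sex-by-ethnicity stratum and age band: the expected risk is
#' the Kaplan-Meier cumulative event probability at the horizon among the
#' band's members; the predicted risk is, by default, the engine
#' evaluated once at the band's mean risk-factor profile (binary
#' predictors entering as prevalences), or alternatively the mean of the
#' individual predicted risks (`predicted = "mean_risk"`).
#'
#' @param cohort cohort filtered to the engine's eligibility.
#' @param coefsets coefficient set(s) as accepted by [predict_risk()].
#' @param spec [endpoint_spec()] for the outcome.
#' @param bands data frame from [age_bands()].
#' @param predicted `"mean_profile"` (default) or `"mean_risk"`.
#' @param horizon risk horizon in years.
#' @return data frame with one row per stratum x band: `sex`,
#'   `ethnicity`, `age_lo`, `age_hi`, `n`, `n_events`,
#'   `expected_risk_10y`, `predicted_risk_10y`.
#' @export
band_summaries <- function(cohort, coefsets, spec, bands,
                           predicted = c("mean_profile", "mean_risk"),
                           horizon = 10) {
  predicted <- match.arg(predicted)
  if (inherits(coefsets, "coef_set")) coefsets <- list(coefsets)
  profile_cols <- c("age", "systolic_bp", "total_chol", "hdl_chol",
                    "current_smoker", "on_bp_treatment", "diabetes")
  rows <- list()
  for (sx in intersect(SEX_LEVELS, unique(cohort$sex))) {
    for (eth in intersect(ETHNICITY_LEVELS, unique(cohort$ethnicity))) {
      in_stratum <- cohort$sex == sx & cohort$ethnicity == eth
      if (!any(in_stratum)) next
      for (b in seq_len(nrow(bands))) {
        i <- in_stratum & cohort$age >= bands$lo[b] & cohort$age < bands$hi[b]
        n <- sum(i)
        if (n == 0L) {
          rows[[length(rows) + 1L]] <- data.frame(
            sex = sx, ethnicity = eth, age_lo = bands$lo[b],
            age_hi = bands$hi[b], n = 0L, n_events = 0L,
            expected_risk_10y = NA_real_, predicted_risk_10y = NA_real_)
          next
        }
        members <- cohort[i, , drop = FALSE]
        oc <- survival_outcomes(members, spec)
        km <- km_observed_risk(oc$time, oc$event, horizon)
        pred <- if (predicted == "mean_profile") {
          profile <- as.data.frame(lapply(members[profile_cols],
                                          function(x) mean(as.numeric(x))))
          profile$sex <- sx
          profile$ethnicity <- eth
          profile$id <- "band_mean"
          predict_risk(profile, coefsets)$risk_10y
        } else {
          mean(predict_risk(members, coefsets)$risk_10y)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          sex = sx, ethnicity = eth, age_lo = bands$lo[b],
          age_hi = bands$hi[b], n = n, n_events = km$n_events,
          expected_risk_10y = km$risk, predicted_risk_10y = pred)
      }
    }
  }
  do.call(rbind, rows)
}

#' Derive per-stratum rescaling factors from band summaries
#'
#' Per sex-by-ethnicity stratum, fits
#' `cloglog(expected) = scale1 + scale2 * cloglog(predicted)`
#' across usable age bands by least squares weighted by band size.
#' Bands with fewer than `min_n` members, zero events, or risks outside
#' (0, 1) are dropped.  At least two usable bands are required; a
#' non-positive fitted slope is flagged (it would break rank
#' preservation).
#'
#' @param summaries data frame from [band_summaries()].
#' @param min_n minimum band size entering the regression (default 30).
#' @return data frame of class `rescaling_factors`: one row per stratum
#'   with `sex`, `ethnicity`, `scale1`, `scale2`, `n_bands`, `fit_r2`,
#'   `flagged`.
#' @export
derive_rescaling_factors <- function(summaries, min_n = 30) {
  usable <- with(summaries,
    n >= min_n & n_events > 0 &
      !is.na(expected_risk_10y) & !is.na(predicted_risk_10y) &
      expected_risk_10y > 0 & expected_risk_10y < 1 &
      predicted_risk_10y > 0 & predicted_risk_10y < 1)
  strata <- unique(summaries[c("sex", "ethnicity")])
  rows <- lapply(seq_len(nrow(strata)), function(k) {
    sel <- usable & summaries$sex == strata$sex[k] &
      summaries$ethnicity == strata$ethnicity[k]
    if (sum(sel) < 2)
      stop("underdetermined: stratum ", strata$sex[k], "/",
           strata$ethnicity[k], " has fewer than 2 usable age bands")
    y <- cloglog(summaries$expected_risk_10y[sel])
    x <- cloglog(summaries$predicted_risk_10y[sel])
    fit <- lm(y ~ x, weights = summaries$n[sel])
    s1 <- unname(coef(fit)[1]); s2 <- unname(coef(fit)[2])
    flagged <- s2 <= 0
    if (flagged)
      warning("non-positive rescaling slope in stratum ", strata$sex[k],
              "/", strata$ethnicity[k], "; factors flagged")
    w <- summaries$n[sel]
    r2 <- 1 - sum(w * fit$residuals^2) /
      sum(w * (y - weighted.mean(y, w))^2)
    data.frame(sex = strata$sex[k], ethnicity = strata$ethnicity[k],
               scale1 = s1, scale2 = s2, n_bands = sum(sel),
               fit_r2 = r2, flagged = flagged)
  })
  structure(do.call(rbind, rows), class = c("rescaling_factors",
                                            "data.frame"))
}

#' Recalibrate individual risks with rescaling factors
#'
#' Applies the cloglog-scale map (shared with [score2_region_rescale()]).
#' Strictly monotone for `scale2 > 0`, so any rank statistic of the risk
#' vector - C-index, quantile membership - is unchanged.
#'
#' @param risk probabilities strictly in (0, 1).
#' @param factors either a list/row with `scale1` and `scale2`, or a
#'   `rescaling_factors` data frame together with `sex`/`ethnicity`
#'   vectors locating each risk's stratum.
#' @param sex,ethnicity stratum labels per element of `risk`; required
#'   when `factors` has more than one stratum.
#' @return recalibrated probabilities.
#' @export
apply_recalibration <- function(risk, factors, sex = NULL, ethnicity = NULL) {
  if (is.data.frame(factors) && nrow(factors) > 1) {
    stopifnot(!is.null(sex), !is.null(ethnicity),
              length(sex) == length(risk),
              length(ethnicity) == length(risk))
    out <- rep(NA_real_, length(risk))
    for (k in seq_len(nrow(factors))) {
      i <- sex == factors$sex[k] & ethnicity == factors$ethnicity[k]
      if (any(i))
        out[i] <- cloglog_rescale(risk[i], factors$scale1[k],
                                  factors$scale2[k])
    }
    if (any(is.na(out)))
      stop("no rescaling factors for ", sum(is.na(out)), " risk(s)")
    return(out)
  }
  cloglog_rescale(risk, factors$scale1[[1]], factors$scale2[[1]])
}

#' Read / write rescaling factors as JSON
#'
#' @param path JSON file path.
#' @param model model identifier stored alongside the factors.
#' @return `read_rescaling_factors()` returns a `rescaling_factors`
#'   data frame.
#' @export
write_rescaling_factors <- function(factors, path, model = "pce_w") {
  jsonlite::write_json(list(model = model,
                            strata = as.data.frame(factors)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_rescaling_factors
#' @param factors a `rescaling_factors` data frame (for writing).
#' @export
read_rescaling_factors <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(raw$strata, class = c("rescaling_factors", "data.frame"))
}
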