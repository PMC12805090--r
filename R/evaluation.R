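# Evaluation of a 10-year risk vector against censored survival outcomes:
# discrimination (Harrell's C), calibration (Kaplan-Meier observed risk,
# Crowson-style Poisson calibration-in-the-large and slope), analysis-of-
# deviance goodness-of-fit, observed-vs-predicted quintile tables, and
# decision-curve net benefit.
#
# All risks are 10-year risks, so follow-up is truncated at the horizon:
# events after `horizon` count as censored at `horizon`.

truncate_followup <- function(time, event, horizon) {
  stopifnot(length(time) == length(event), all(time >= 0),
            all(event %in% 0:1))
  over <- time > horizon
  event[over] <- 0L
  time[over] <- horizon
  list(time = time, event = as.integer(event))
}

#' Harrell's concordance index for a risk score
#'
#' Probability that, of a randomly chosen comparable pair, the individual
#' with the shorter event-free survival received the higher predicted
#' risk.  Pairs are comparable when the shorter time ends in an event;
#' ties in the risk score count 1/2.  The confidence interval is Wald-type
#' from the analytic concordance variance.
#'
#' @param risk numeric vector of predicted risks (any monotone score).
#' @param time follow-up times in years.
#' @param event 0/1 event indicators.
#' @param conf confidence level.
#' @return list with `c_index`, `se`, `lower`, `upper`, `n`, `n_events`.
#' @export
c_index <- function(risk, time, event, conf = 0.95) {
  stopifnot(length(risk) == length(time), length(time) == length(event),
            length(risk) >= 2)
  if (sum(event) == 0)
    stop("C-index undefined: no events")
  fit <- survival::concordance(survival::Surv(time, event) ~ risk,
                               reverse = TRUE)
  se <- sqrt(fit$var)
  z <- qnorm(1 - (1 - conf) / 2)
  list(c_index = unname(fit$concordance), se = unname(se),
       lower = unname(fit$concordance - z * se),
       upper = unname(fit$concordance + z * se),
       n = length(risk), n_events = sum(event))
}

#' Qualitative discrimination band of a C-index
#'
#' Below 0.6: poor; 0.60 to 0.75 inclusive: possibly helpful; above 0.75:
#' clearly useful.
#'
#' @param c C-index value in `[0, 1]`.
#' @return one of `"poor"`, `"possibly_helpful"`, `"clearly_useful"`.
#' @export
classify_discrimination <- function(c) {
  stopifnot(length(c) == 1L, c >= 0, c <= 1)
  if (c < 0.6) "poor"
  else if (c <= 0.75) "possibly_helpful"
  else "clearly_useful"
}

#' Kaplan-Meier observed risk at a horizon
#'
#' Observed cumulative event probability `1 - S_KM(horizon)`, with a
#' Greenwood confidence interval on the log(-log) scale.  When no one
#' remains at risk at the horizon, the estimate is carried forward from
#' the last event time before it.  The KM-adjusted event count
#' `n * (1 - S_KM(horizon))` accounts for participants followed for less
#' than the horizon.
#'
#' @inheritParams c_index
#' @param horizon horizon in years (default 10).
#' @return list with `risk`, `lower`, `upper`, `events_adjusted`, `n`,
#'   `n_events` (raw events by the horizon).
#' @export
km_observed_risk <- function(time, event, horizon = 10, conf = 0.95) {
  tr <- truncate_followup(time, event, horizon)
  if (all(tr$time == 0))
    stop("no one under observation before the horizon")
  fit <- survival::survfit(survival::Surv(tr$time, tr$event) ~ 1,
                           conf.type = "log-log", conf.int = conf)
  s <- summary(fit, times = horizon, extend = TRUE)
  risk <- 1 - s$surv
  lo <- 1 - s$upper
  hi <- 1 - s$lower
  if (sum(tr$event) == 0) { risk <- 0; lo <- NA_real_; hi <- NA_real_ }
  list(risk = risk, lower = lo, upper = hi,
       events_adjusted = length(tr$time) * risk,
       n = length(tr$time), n_events = sum(tr$event))
}

# per-person expected cumulative hazard over observed follow-up, assuming
# the 10-year hazard accrues uniformly: H_i = -ln(1 - risk_i) * min(t,h)/h
expected_hazard <- function(risk, time, horizon) {
  if (any(risk <= 0 | risk >= 1))
    stop("predicted risks must lie strictly in (0, 1)")
  (-log1p(-risk)) * pmin(time, horizon) / horizon
}

#' Calibration-in-the-large and calibration slope (Poisson framework)
#'
#' Follows the Poisson modelling approach of Crowson and colleagues.
#' Each participant contributes an expected cumulative hazard
#' `H_i = -ln(1 - risk_i) * min(t_i, horizon)/horizon`.
#' Calibration-in-the-large is the intercept of a Poisson model of the
#' event indicator with `ln H_i` as offset (0 = perfect mean calibration;
#' negative = overestimation of risk).  The calibration slope is the
#' coefficient of the log predicted full-horizon hazard
#' `ln(-ln(1 - risk_i))` in a Poisson model whose offset is the log
#' exposure fraction `ln(min(t_i, horizon)/horizon)` (1 = perfect
#' spread); keeping the exposure in the offset rather than the covariate
#' is what makes the slope identifiable under censoring and early events.
#' Confidence intervals are Wald intervals from the model standard
#' errors.
#'
#' @inheritParams c_index
#' @param horizon risk horizon in years.
#' @return list with `citl`, `citl_lower`, `citl_upper`, `slope`,
#'   `slope_lower`, `slope_upper`, `n`, `n_events`.
#' @export
calibration_metrics <- function(risk, time, event, horizon = 10,
                                conf = 0.95) {
  tr <- truncate_followup(time, event, horizon)
  if (sum(tr$event) == 0) stop("calibration undefined: no events")
  H <- expected_hazard(risk, tr$time, horizon)
  if (all(H == 0)) stop("all expected hazards are zero")
  keep <- H > 0
  lnH <- log(H[keep])
  # split H into the full-horizon hazard (the model's prediction) and the
  # exposure fraction: the prediction is the slope covariate, the exposure
  # stays an offset.  Folding exposure into the covariate would make it
  # outcome-dependent (events have short follow-up) and destroy the slope.
  lnh <- log(-log1p(-risk[keep]))
  lnfrac <- log(pmin(tr$time[keep], horizon) / horizon)
  d <- tr$event[keep]
  z <- qnorm(1 - (1 - conf) / 2)
  m_citl <- glm(d ~ 1 + offset(lnH), family = poisson())
  citl <- unname(coef(m_citl)[1])
  citl_se <- sqrt(diag(vcov(m_citl)))[1]
  m_slope <- glm(d ~ lnh + offset(lnfrac), family = poisson())
  slope <- unname(coef(m_slope)["lnh"])
  slope_se <- sqrt(diag(vcov(m_slope)))["lnh"]
  list(citl = citl,
       citl_lower = citl - z * citl_se, citl_upper = citl + z * citl_se,
       slope = slope,
       slope_lower = unname(slope - z * slope_se),
       slope_upper = unname(slope + z * slope_se),
       n = sum(keep), n_events = sum(d))
}

# quantile grouping of a risk vector; ties go to the lower group; a
# degenerate (near-constant) vector collapses groups with a warning
risk_groups <- function(risk, n_groups = 5) {
  stopifnot(n_groups >= 2)
  breaks <- unique(quantile(risk, probs = seq(0, 1, length.out = n_groups + 1)))
  if (length(breaks) < n_groups + 1)
    warning("tied predicted risks collapse ", n_groups, " groups into ",
            max(1L, length(breaks) - 1L))
  if (length(breaks) < 2) return(factor(rep(1L, length(risk))))
  cut(risk, breaks = breaks, include.lowest = TRUE, labels = FALSE) |>
    factor()
}

#' Analysis-of-deviance goodness-of-fit test
#'
#' Compares the base Poisson calibration model (the log predicted hazard
#' as sole predictor, log exposure fraction as offset, as in
#' [calibration_metrics()]) against the same model augmented with
#' risk-quantile group indicators.  The deviance difference is chi-square with
#' `n_groups - 1` degrees of freedom under adequate fit; for quintiles the
#' 5% critical value is 9.5.
#'
#' @inheritParams calibration_metrics
#' @param n_groups number of risk-quantile groups (default 5).
#' @return list with `deviance`, `df`, `threshold` (the 5% critical
#'   value), `poor_fit` flag, `p_value` and the per-group (KM-adjusted)
#'   event counts.
#' @export
deviance_gof <- function(risk, time, event, n_groups = 5, horizon = 10) {
  tr <- truncate_followup(time, event, horizon)
  H <- expected_hazard(risk, tr$time, horizon)
  keep <- H > 0
  lnh <- log(-log1p(-risk[keep]))
  lnfrac <- log(pmin(tr$time[keep], horizon) / horizon)
  d <- tr$event[keep]
  grp <- risk_groups(risk[keep], n_groups)
  if (nlevels(grp) < 2)
    stop("cannot test fit: predicted risk groups are degenerate")
  person_time <- tapply(pmin(tr$time[keep], horizon), grp, sum)
  if (any(person_time == 0)) stop("a risk group has zero person-time")
  base <- glm(d ~ lnh + offset(lnfrac), family = poisson())
  full <- glm(d ~ lnh + grp + offset(lnfrac), family = poisson())
  dev <- base$deviance - full$deviance
  df <- nlevels(grp) - 1L
  thr <- gof_threshold(nlevels(grp))
  events_by_group <- vapply(levels(grp), function(g) {
    i <- grp == g
    km_observed_risk(tr$time[keep][i], d[i], horizon)$events_adjusted
  }, numeric(1))
  list(deviance = dev, df = df, threshold = thr, poor_fit = dev > thr,
       p_value = pchisq(dev, df, lower.tail = FALSE),
       events_by_group = events_by_group)
}

#' Deviance rejection threshold for a grouped goodness-of-fit test
#'
#' The chi-square 95% critical value at `n_groups - 1` degrees of
#' freedom, reported to one decimal place (9.5 for quintiles).
#'
#' @param n_groups number of groups.
#' @param alpha significance level.
#' @return numeric scalar.
#' @export
gof_threshold <- function(n_groups = 5, alpha = 0.05) {
  round(qchisq(1 - alpha, df = n_groups - 1), 1)
}

#' Are grouped event counts dense enough for the deviance test?
#'
#' `TRUE` when at least 80% of the groups have 5 or more (KM-adjusted)
#' events; used to warn when quantile groups are too sparse for the
#' chi-square approximation.
#'
#' @param events numeric vector of per-group event counts.
#' @param min_events minimum events per group (default 5).
#' @param min_prop minimum proportion of groups meeting it (default 0.8).
#' @return logical scalar.
#' @export
check_group_event_rule <- function(events, min_events = 5, min_prop = 0.8) {
  mean(events >= min_events) >= min_prop
}

#' Observed versus predicted risk by quantile of predicted risk
#'
#' The machine-readable twin of an observed/predicted calibration bar
#' plot: per risk-quantile group, the mean predicted risk and the
#' Kaplan-Meier observed risk at the horizon with its confidence
#' interval.
#'
#' @inheritParams deviance_gof
#' @return data frame with one row per group: `group`, `n`,
#'   `mean_predicted`, `observed`, `obs_lower`, `obs_upper`, `n_events`,
#'   `events_adjusted`.
#' @export
quintile_table <- function(risk, time, event, n_groups = 5, horizon = 10) {
  tr <- truncate_followup(time, event, horizon)
  grp <- risk_groups(risk, n_groups)
  rows <- lapply(levels(grp), function(g) {
    i <- grp == g
    km <- km_observed_risk(tr$time[i], tr$event[i], horizon)
    data.frame(group = as.integer(g), n = sum(i),
               mean_predicted = mean(risk[i]),
               observed = km$risk, obs_lower = km$lower,
               obs_upper = km$upper, n_events = km$n_events,
               events_adjusted = km$events_adjusted)
  })
  do.call(rbind, rows)
}

#' Decision curve analysis
#'
#' Net benefit of treating individuals whose predicted risk meets a
#' threshold t:
#' `NB(t) = P(flagged & event) - P(flagged & no event) * t / (1 - t)`,
#' with the event probability among the flagged estimated by Kaplan-Meier
#' at the horizon.  Treat-all and treat-none reference strategies are
#' included; treat-none has net benefit 0 everywhere.
#'
#' @inheritParams c_index
#' @param thresholds probability thresholds strictly below 1; the default
#'   grid 0.01-0.30 covers the clinically relevant 5-20% window.
#' @param horizon risk horizon in years.
#' @return data frame: `threshold`, `net_benefit_model`,
#'   `net_benefit_treat_all`, `net_benefit_treat_none`.
#' @export
decision_curve <- function(risk, time, event,
                           thresholds = seq(0.01, 0.30, by = 0.01),
                           horizon = 10) {
  stopifnot(all(thresholds > 0), all(thresholds < 1))
  tr <- truncate_followup(time, event, horizon)
  p_all <- km_observed_risk(tr$time, tr$event, horizon)$risk
  nb <- vapply(thresholds, function(t) {
    w <- t / (1 - t)
    flagged <- risk >= t
    p_flag <- mean(flagged)
    if (!any(flagged)) return(c(model = 0, all = p_all - (1 - p_all) * w))
    p_ev <- km_observed_risk(tr$time[flagged], tr$event[flagged],
                             horizon)$risk
    c(model = p_flag * p_ev - p_flag * (1 - p_ev) * w,
      all = p_all - (1 - p_all) * w)
  }, c(model = 0, all = 0))
  data.frame(threshold = thresholds,
             net_benefit_model = nb["model", ],
             net_benefit_treat_all = nb["all", ],
             net_benefit_treat_none = 0)
}

#' Full evaluation report for one risk vector
#'
#' Bundles discrimination, calibration, goodness-of-fit, the quantile
#' observed/predicted table and KM-adjusted event counts into a single
#' report.
#'
#' @inheritParams deviance_gof
#' @return object of class `cvd_eval`: a list with elements `c_index`,
#'   `discrimination_band`, `calibration`, `gof`, `quintiles`,
#'   `n_observed_events_adj`, `n_predicted_events`, `n`, plus
#'   `group_event_rule_ok`.
#' @export
evaluate_model <- function(risk, time, event, n_groups = 5, horizon = 10) {
  ci <- c_index(risk, time, event)
  cal <- calibration_metrics(risk, time, event, horizon)
  gof <- deviance_gof(risk, time, event, n_groups, horizon)
  qt <- quintile_table(risk, time, event, n_groups, horizon)
  km <- km_observed_risk(time, event, horizon)
  structure(list(
    c_index = ci,
    discrimination_band = classify_discrimination(ci$c_index),
    calibration = cal,
    gof = gof,
    quintiles = qt,
    group_event_rule_ok = check_group_event_rule(qt$events_adjusted),
    n_observed_events_adj = km$events_adjusted,
    n_predicted_events = sum(risk),
    n = length(risk)), class = "cvd_eval")
}

#' @export
print.cvd_eval <- function(x, ...) {
  cat(sprintf("10-year risk model evaluation (n = %d)\n", x$n))
  cat(sprintf("  C-index: %.3f (%.3f, %.3f) [%s]\n",
              x$c_index$c_index, x$c_index$lower, x$c_index$upper,
              x$discrimination_band))
  cat(sprintf("  Calibration-in-the-large: %.3f (%.3f, %.3f)\n",
              x$calibration$citl, x$calibration$citl_lower,
              x$calibration$citl_upper))
  cat(sprintf("  Calibration slope: %.3f (%.3f, %.3f)\n",
              x$calibration$slope, x$calibration$slope_lower,
              x$calibration$slope_upper))
  cat(sprintf("  Deviance GOF: %.1f on %d df (threshold %.1f)%s\n",
              x$gof$deviance, x$gof$df, x$gof$threshold,
              if (x$gof$poor_fit) " -- poor fit" else ""))
  cat(sprintf("  Observed events (KM-adjusted): %.1f; predicted: %.1f\n",
              x$n_observed_events_adj, x$n_predicted_events))
  invisible(x)
}
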