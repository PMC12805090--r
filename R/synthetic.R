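# Synthetic multi-ethnic cohorts.
#
# The generator emulates the statistical structure the analysis assumes:
# two cohort templates (a younger development-style cohort and an older
# validation-style cohort), correlated continuous risk factors, sex- and
# ethnicity-structured prevalences, and an outcome model in which the true
# 10-year event probability is a controllable cloglog distortion of a
# chosen engine's prediction.  Event times are exponential within the
# horizon (memoryless), so only the 10-year cumulative risk - the quantity
# every downstream statistic consumes - is pinned down; censoring is
# administrative and independent.

#' Generator configuration for a synthetic cohort
#'
#' Templates: `"mec1"` - development-style cohort, mean age 45.4 (SD
#' 12.8), 43% male, ethnicity 47/26/27% Chinese/Malay/Indian, mean
#' follow-up about 12 years; `"seed"` - validation-style cohort, mean age
#' 58.1 (SD 10.2), 48% male, 35/33/32%, mean follow-up about 10.6 years;
#' `"custom"` starts from the development template.  Any field can be
#' overridden through `...`.  Risk-factor dispersions and correlations
#' (age-SBP 0.4, age-TC 0.2, TC-HDL 0.2) are plausible fabrications, not
#' estimates from any cohort, and are fully overridable.
#'
#' @param template cohort template.
#' @param n number of participants.
#' @param seed default random seed carried in the config (can be
#'   overridden at generation time).
#' @param ... named overrides of any config field.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(template = c("mec1", "seed", "custom"),
                             n = 1000, seed = 1L, ...) {
  template <- match.arg(template)
  base <- list(
    n = n, seed = seed, template = template,
    age_mean = 45.4, age_sd = 12.8, age_range = c(21, 80),
    p_male = 0.43,
    ethnicity = c(Chinese = 0.47, Malay = 0.26, Indian = 0.27),
    sbp_mean = 124, sbp_sd = 17,
    tc_mean = 5.4, tc_sd = 1.0,
    hdl_mean = 1.45, hdl_sd = 0.32,
    male_sbp_shift = 4, male_hdl_shift = -0.25,
    cor_age_sbp = 0.4, cor_age_tc = 0.2, cor_tc_hdl = 0.2,
    p_smoker = c(male = 0.32, female = 0.04),
    p_bp_treatment = 0.12,
    p_dm_dx = 0.06,
    fg_mean = 5.3, fg_sd = 1.0, fg_dm_shift = 3.0,
    hba1c_mean = 5.6, hba1c_sd = 0.55, hba1c_dm_shift = 1.5,
    p_prevalent_cvd = 0.03,
    outcome = list(model = "pce_w", scale1 = 0, scale2 = 1),
    censoring = c(9.3, 14.5))
  if (template == "seed")
    base <- modifyList(base, list(
      age_mean = 58.1, age_sd = 10.2, age_range = c(40, 80),
      p_male = 0.48,
      ethnicity = c(Chinese = 0.35, Malay = 0.33, Indian = 0.32),
      sbp_mean = 136, sbp_sd = 19,
      tc_mean = 5.5, tc_sd = 1.05,
      hdl_mean = 1.42, hdl_sd = 0.32,
      p_smoker = c(male = 0.28, female = 0.05),
      p_bp_treatment = 0.30, p_dm_dx = 0.16,
      fg_mean = 5.6, hba1c_mean = 5.8,
      p_prevalent_cvd = 0.06,
      censoring = c(7.4, 13.8)))
  cfg <- modifyList(base, list(...))
  stopifnot(cfg$n >= 1,
            abs(sum(cfg$ethnicity) - 1) < 1e-8,
            cfg$p_male >= 0, cfg$p_male <= 1,
            cfg$age_range[1] < cfg$age_range[2],
            cfg$censoring[1] <= cfg$censoring[2])
  structure(cfg, class = "generator_config")
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  p <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(p, mean, sd)
}

trunc_norm_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma; b <- (hi - mu) / sigma
  z <- pnorm(b) - pnorm(a)
  m1 <- mu + sigma * (dnorm(a) - dnorm(b)) / z
  v <- sigma^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / z -
                    ((dnorm(a) - dnorm(b)) / z)^2)
  c(mean = m1, sd = sqrt(v))
}

# parent-normal parameters whose truncation to [lo, hi] has the target
# mean and sd, so template moments hold after truncation
solve_trunc_norm <- function(target_mean, target_sd, lo, hi) {
  obj <- function(par) {
    m <- trunc_norm_moments(par[1], exp(par[2]), lo, hi)
    (m[1] - target_mean)^2 + (m[2] - target_sd)^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  c(mean = fit$par[1], sd = exp(fit$par[2]))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

gen_covariates_impl <- function(cfg) {
  n <- cfg$n
  sex <- ifelse(runif(n) < cfg$p_male, "male", "female")
  ethnicity <- sample(names(cfg$ethnicity), n, replace = TRUE,
                      prob = cfg$ethnicity)
  if (cfg$age_sd > 0) {
    parent <- solve_trunc_norm(cfg$age_mean, cfg$age_sd,
                               cfg$age_range[1], cfg$age_range[2])
    age <- rtruncnorm1(n, parent["mean"], parent["sd"],
                       cfg$age_range[1], cfg$age_range[2])
    z_age <- (age - cfg$age_mean) / cfg$age_sd
  } else {
    age <- rep(cfg$age_mean, n)
    z_age <- rep(0, n)
  }
  # (SBP, TC, HDL) | age from the joint standard-normal correlation
  # structure: age-SBP, age-TC, TC-HDL nonzero, all else zero
  s21 <- c(cfg$cor_age_sbp, cfg$cor_age_tc, 0)
  S22 <- rbind(c(1, 0, 0),
               c(0, 1, cfg$cor_tc_hdl),
               c(0, cfg$cor_tc_hdl, 1))
  cond_cov <- S22 - tcrossprod(s21)
  ev <- eigen(cond_cov, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-10)) stop("invalid correlation matrix")
  L <- chol(cond_cov + diag(1e-12, 3))
  z <- outer(z_age, s21) + matrix(rnorm(3 * n), n, 3) %*% L
  sbp <- cfg$sbp_mean + cfg$male_sbp_shift * (sex == "male") +
    cfg$sbp_sd * z[, 1]
  tc <- cfg$tc_mean + cfg$tc_sd * z[, 2]
  hdl <- cfg$hdl_mean + cfg$male_hdl_shift * (sex == "male") +
    cfg$hdl_sd * z[, 3]
  sbp <- clamp(sbp, 90, 240)
  tc <- clamp(tc, 2.8, 10)
  hdl <- clamp(hdl, 0.55, 3)
  hdl <- pmin(hdl, tc - 0.8)
  smoker <- runif(n) < cfg$p_smoker[sex]
  bp_trt <- runif(n) < cfg$p_bp_treatment
  dm_dx <- runif(n) < cfg$p_dm_dx
  fg <- pmax(3, rnorm(n, cfg$fg_mean + cfg$fg_dm_shift * dm_dx, cfg$fg_sd))
  hba1c <- pmax(3.5, rnorm(n, cfg$hba1c_mean + cfg$hba1c_dm_shift * dm_dx,
                           cfg$hba1c_sd))
  df <- data.frame(
    id = sprintf("P%06d", seq_len(n)),
    age = age, sex = sex, ethnicity = ethnicity,
    systolic_bp = sbp, on_bp_treatment = bp_trt,
    total_chol = tc, hdl_chol = hdl, current_smoker = smoker,
    physician_dx_diabetes = dm_dx,
    fasting_glucose = fg, random_glucose = NA_real_, hba1c = hba1c,
    diabetes = NA, prevalent_cvd = runif(n) < cfg$p_prevalent_cvd,
    follow_up_years = NA_real_, event_code = NA_character_,
    event_fatal = NA, event_time_years = NA_real_,
    stringsAsFactors = FALSE)
  resolve_diabetes(df)
}

gen_outcomes_impl <- function(cohort, cfg, horizon = 10) {
  coefsets <- load_coefficient_sets(cfg$outcome$model)
  p <- predict_risk(cohort, coefsets)$risk_10y
  p <- clamp(p, 1e-10, 1 - 1e-10)
  p_true <- cloglog_rescale(p, cfg$outcome$scale1, cfg$outcome$scale2)
  n <- nrow(cohort)
  event <- runif(n) < p_true
  lambda <- -log1p(-p_true) / horizon
  t_event <- rep(NA_real_, n)
  if (any(event)) {
    u <- runif(sum(event))
    le <- lambda[event]
    # inverse CDF of an exponential conditioned on T <= horizon
    t_event[event] <- -log1p(-u * (-expm1(-le * horizon))) / le
  }
  censor <- runif(n, cfg$censoring[1], cfg$censoring[2])
  observed_event <- event & t_event <= censor
  time <- ifelse(observed_event, t_event, censor)
  cohort$follow_up_years <- time
  cohort$event_code <- ifelse(observed_event, "I21", NA_character_)
  cohort$event_fatal <- ifelse(observed_event, FALSE, NA)
  cohort$event_time_years <- ifelse(observed_event, t_event, NA_real_)
  attr(cohort, "true_risk_10y") <- p_true
  cohort
}

#' Generate synthetic cohort covariates
#'
#' Seeded and reproducible: the same seed always yields the same table.
#' Ages are truncated to the template window; SBP, total and HDL
#' cholesterol are drawn conditionally on age from the configured
#' correlation structure; binary factors follow the configured
#' prevalences; the `diabetes` column is derived from the generated
#' physician-diagnosis and laboratory fields through [derive_diabetes()].
#' Follow-up and event columns are left missing until
#' [generate_outcomes()].
#'
#' @param config a [generator_config()].
#' @param seed random seed (defaults to the one in the config).
#' @return cohort data frame.
#' @export
generate_covariates <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(seed)
  gen_covariates_impl(config)
}

#' Attach simulated outcomes to a cohort
#'
#' The true 10-year event probability of each participant is the
#' configured engine's prediction pushed through the configured cloglog
#' distortion (`scale1`, `scale2`); event indicators are Bernoulli in
#' that probability, event times exponential conditioned to fall inside
#' the horizon, and censoring administrative (uniform over the configured
#' interval), drawn independently.  Events occurring after an earlier
#' censoring time are observed as censorings.  The vector of true risks
#' is attached as `attr(., "true_risk_10y")`.
#'
#' @param cohort covariate table from [generate_covariates()].
#' @param config a [generator_config()].
#' @param seed random seed.
#' @param horizon risk horizon in years.
#' @return cohort with `follow_up_years`, `event_code`, `event_fatal`,
#'   `event_time_years` filled in (events are coded as non-fatal
#'   myocardial infarction, `I21`, which qualifies for all three shipped
#'   endpoints).
#' @export
generate_outcomes <- function(cohort, config, seed = config$seed + 1L,
                              horizon = 10) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(seed)
  gen_outcomes_impl(cohort, config, horizon)
}

#' Generate a complete synthetic cohort (covariates + outcomes)
#'
#' @inheritParams generate_covariates
#' @return cohort data frame with outcomes and a `true_risk_10y`
#'   attribute.
#' @export
generate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(seed)
  gen_outcomes_impl(gen_covariates_impl(config), config)
}

#' A 20-row deterministic cohort for hand-checkable tests
#'
#' Fixed, printed-in-source table containing events, censored follow-up,
#' a fatal stroke, a non-endpoint event and tied risk scores; used by the
#' brute-force oracle tests (concordance, Kaplan-Meier, decision-curve
#' 2x2 tables).  A deterministic risk score with ties is attached as
#' `attr(., "risk")`.
#'
#' @return 20-row cohort data frame.
#' @export
fixture_small <- function() {
  df <- data.frame(
    id = sprintf("F%02d", 1:20),
    age = c(44, 52, 61, 47, 55, 63, 41, 58, 66, 50,
            45, 53, 62, 48, 57, 64, 42, 59, 67, 51),
    sex = rep(c("male", "female"), 10),
    ethnicity = rep(c("Chinese", "Malay", "Indian", "Chinese", "Malay"), 4),
    systolic_bp = c(118, 135, 150, 122, 140, 155, 115, 138, 160, 128,
                    120, 133, 148, 125, 142, 152, 117, 136, 158, 130),
    on_bp_treatment = rep(c(FALSE, FALSE, TRUE, FALSE, TRUE), 4),
    total_chol = c(5.2, 5.8, 6.4, 5.0, 6.0, 6.6, 4.8, 5.9, 6.8, 5.4,
                   5.1, 5.7, 6.3, 5.2, 6.1, 6.5, 4.9, 5.8, 6.7, 5.5),
    hdl_chol = c(1.3, 1.5, 1.1, 1.4, 1.2, 1.0, 1.6, 1.3, 0.9, 1.4,
                 1.2, 1.5, 1.1, 1.3, 1.2, 1.0, 1.6, 1.4, 0.9, 1.3),
    current_smoker = rep(c(TRUE, FALSE, FALSE, FALSE, TRUE), 4),
    physician_dx_diabetes = rep(c(FALSE, FALSE, TRUE, FALSE, FALSE), 4),
    fasting_glucose = c(5.1, 5.4, 8.2, 5.0, 5.6, 8.5, 4.9, 5.3, 8.0, 5.2,
                        5.0, 5.5, 8.3, 5.1, 5.7, 8.1, 4.8, 5.4, 8.4, 5.3),
    random_glucose = NA_real_,
    hba1c = c(5.5, 5.6, 7.2, 5.4, 5.7, 7.5, 5.3, 5.6, 7.1, 5.5,
              5.4, 5.7, 7.3, 5.5, 5.8, 7.2, 5.2, 5.6, 7.4, 5.6),
    diabetes = rep(c(FALSE, FALSE, TRUE, FALSE, FALSE), 4),
    prevalent_cvd = FALSE,
    follow_up_years = c(12.0, 3.5, 8.2, 11.0, 6.4, 2.1, 12.5, 9.8, 4.7,
                        10.9, 12.2, 5.5, 7.9, 11.4, 6.4, 3.0, 12.8, 9.1,
                        5.2, 10.3),
    event_code = c(NA, "I21", NA, NA, "I63", "I21", NA, NA, "I21", NA,
                   NA, "I63.9", NA, NA, "I10", "I21", NA, NA, "I21", NA),
    event_fatal = c(NA, FALSE, NA, NA, TRUE, FALSE, NA, NA, FALSE, NA,
                    NA, FALSE, NA, NA, FALSE, FALSE, NA, NA, TRUE, NA),
    event_time_years = c(NA, 3.5, NA, NA, 6.4, 2.1, NA, NA, 4.7, NA,
                         NA, 5.5, NA, NA, 6.4, 3.0, NA, NA, 5.2, NA),
    stringsAsFactors = FALSE)
  attr(df, "risk") <- c(0.04, 0.18, 0.22, 0.05, 0.18, 0.30, 0.03, 0.12,
                        0.35, 0.07, 0.04, 0.15, 0.20, 0.06, 0.16, 0.28,
                        0.03, 0.11, 0.33, 0.08)
  df
}
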