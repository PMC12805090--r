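# coefficient set with no terms: every participant gets risk 1 - S0
flat_engine <- function(s0 = 0.92, sex = "male")
  coefficient_set("flat", list(sex = sex),
                  list(chol = "mmol/L", sbp = "mmHg"), list(),
                  mean_lp = 0, baseline_survival_10y = s0)

test_that("band summaries compute expected (KM) and predicted (mean-profile) risk", {
  chd <- default_endpoints()$CHD
  coh <- resolve_diabetes(fixture_small())
  coh$sex <- "male"; coh$ethnicity <- "Chinese"
  coh$age <- rep(c(47, 52), each = 10)
  bands <- age_bands(45, 54, width = 5)
  # a zero-coefficient engine predicts 1 - S0 in every band
  s <- band_summaries(coh, flat_engine(0.92), chd, bands)
  expect_equal(s$predicted_risk_10y, rep(1 - 0.92, 2))
  # expected side equals the hand product-limit within each band
  for (b in 1:2) {
    i <- coh$age >= s$age_lo[b] & coh$age < s$age_hi[b]
    oc <- survival_outcomes(coh[i, ], chd)
    expect_equal(s$expected_risk_10y[b],
                 brute_force_km_risk(oc$time, oc$event, 10))
  }
  expect_equal(s$n, c(10L, 10L))
})

test_that("band predicted risk is the engine at the hand-averaged profile", {
  cs <- load_coefficient_sets("pce_w")$male
  chd <- default_endpoints()$CHD
  two <- resolve_diabetes(fixture_small()[c(1, 9), ])
  two$sex <- "male"; two$ethnicity <- "Malay"; two$age <- c(51, 53)
  s <- band_summaries(two, cs, chd, age_bands(50, 54), predicted = "mean_profile")
  prof <- two[1, ]
  for (cl in c("age", "systolic_bp", "total_chol", "hdl_chol"))
    prof[[cl]] <- mean(two[[cl]])
  for (cl in c("current_smoker", "on_bp_treatment", "diabetes"))
    prof[[cl]] <- mean(as.numeric(two[[cl]]))
  expect_equal(s$predicted_risk_10y,
               risk_from_lp(linear_predictor(prof, cs), cs))
  # a band of identical participants predicts the individual risk
  same <- two[c(1, 1), ]
  s2 <- band_summaries(same, cs, chd, age_bands(50, 54))
  expect_equal(s2$predicted_risk_10y,
               risk_from_lp(linear_predictor(two[1, ], cs), cs))
  # mean-of-risks alternative averages the individual predictions
  s3 <- band_summaries(two, cs, chd, age_bands(50, 54),
                       predicted = "mean_risk")
  expect_equal(s3$predicted_risk_10y,
               mean(predict_risk(two, cs)$risk_10y))
})

analytic_summaries <- function(a, b, pred = c(0.02, 0.05, 0.09, 0.14, 0.2)) {
  data.frame(sex = "male", ethnicity = "Chinese",
             age_lo = seq(40, by = 5, length.out = length(pred)),
             age_hi = seq(45, by = 5, length.out = length(pred)),
             n = 1000L, n_events = 50L,
             expected_risk_10y = cloglog_rescale(pred, a, b),
             predicted_risk_10y = pred)
}

test_that("factor derivation recovers an exact cloglog line", {
  # expected == predicted in every band: identity factors
  f0 <- derive_rescaling_factors(analytic_summaries(0, 1))
  expect_equal(f0$scale1, 0, tolerance = 1e-10)
  expect_equal(f0$scale2, 1, tolerance = 1e-10)
  # a known affine distortion is recovered to at least 6 decimals
  f <- derive_rescaling_factors(analytic_summaries(0.4, 1.3))
  expect_equal(f$scale1, 0.4, tolerance = 1e-7)
  expect_equal(f$scale2, 1.3, tolerance = 1e-7)
  # halving every expected hazard shifts only the intercept, by -ln 2
  fh <- derive_rescaling_factors(analytic_summaries(-log(2), 1))
  expect_equal(fh$scale1, -log(2), tolerance = 1e-7)
  expect_equal(fh$scale2, 1, tolerance = 1e-7)
  expect_equal(fh$n_bands, 5L)
})

test_that("factor derivation drops unusable bands and flags bad fits", {
  s <- analytic_summaries(0, 1)
  s$n[1] <- 10L          # below the minimum band size
  s$n_events[2] <- 0L    # no events
  f <- derive_rescaling_factors(s)
  expect_equal(f$n_bands, 3L)
  expect_error(derive_rescaling_factors(s[1:3, ]), "underdetermined")
  dec <- analytic_summaries(0, 1)
  dec$expected_risk_10y <- rev(dec$expected_risk_10y)  # decreasing line
  expect_warning(derive_rescaling_factors(dec), "non-positive")
})

test_that("recalibration is the shared cloglog transform and keeps ranking", {
  set.seed(3)
  p <- runif(500, 0.005, 0.6)
  expect_equal(apply_recalibration(p, list(scale1 = 0, scale2 = 1)), p)
  expect_equal(round(apply_recalibration(0.1, list(scale1 = log(2),
                                                   scale2 = 1)), 4), 0.19)
  expect_identical(
    apply_recalibration(p, list(scale1 = -0.3, scale2 = 0.8)),
    cloglog_rescale(p, -0.3, 0.8))
  # per-stratum dispatch
  f <- structure(data.frame(sex = c("male", "female"),
                            ethnicity = c("Chinese", "Chinese"),
                            scale1 = c(0, log(2)), scale2 = c(1, 1)),
                 class = c("rescaling_factors", "data.frame"))
  sex <- rep(c("male", "female"), 250)
  out <- apply_recalibration(p, f, sex = sex,
                             ethnicity = rep("Chinese", 500))
  expect_equal(out[sex == "male"], p[sex == "male"])
  expect_equal(out[sex == "female"],
               cloglog_rescale(p[sex == "female"], log(2), 1))
  expect_error(apply_recalibration(p, f, sex = rep("male", 500),
                                   ethnicity = rep("Indian", 500)),
               "no rescaling factors")
})

test_that("recalibration leaves the concordance index exactly unchanged", {
  d <- make_eval_cohort(n = 1500, seed = 42)
  before <- c_index(d$risk, d$time, d$event)$c_index
  rec <- apply_recalibration(d$risk, list(scale1 = log(2), scale2 = 1.2))
  after <- c_index(rec, d$time, d$event)$c_index
  expect_identical(before, after)
  # quantile group membership is preserved too
  g1 <- cut(d$risk, quantile(d$risk, seq(0, 1, 0.2)), include.lowest = TRUE,
            labels = FALSE)
  g2 <- cut(rec, quantile(rec, seq(0, 1, 0.2)), include.lowest = TRUE,
            labels = FALSE)
  expect_identical(g1, g2)
})

test_that("the derivation recovers a known distortion when bands are homogeneous", {
  # with age as the only varying risk factor, band members share one true
  # risk, so band aggregation commutes with the cloglog map and the
  # estimator is unbiased; residual error is Kaplan-Meier band noise
  sets <- load_coefficient_sets("pce_w")
  ep <- default_endpoints()$ASCVD
  rec <- t(vapply(1:3, function(k) {
    cfg <- generator_config(
      "custom", n = 50000, seed = k,
      age_mean = 58, age_sd = 11, age_range = c(40, 80), p_male = 1,
      ethnicity = c(Chinese = 1, Malay = 0, Indian = 0),
      sbp_sd = 0, tc_sd = 0, hdl_sd = 0,
      cor_age_sbp = 0, cor_age_tc = 0, cor_tc_hdl = 0,
      p_smoker = c(male = 0, female = 0), p_bp_treatment = 0, p_dm_dx = 0,
      fg_mean = 5, fg_sd = 0, hba1c_sd = 0,
      outcome = list(model = "pce_w", scale1 = log(2), scale2 = 1.2))
    coh <- filter_eligible(generate_cohort(cfg), "pce")
    f <- derive_rescaling_factors(
      band_summaries(coh, sets, ep, age_bands(40, 79)))
    c(f$scale1, f$scale2)
  }, numeric(2)))
  expect_lt(abs(mean(rec[, 1]) - log(2)), 0.05)
  expect_lt(abs(mean(rec[, 2]) - 1.2), 0.05)
})

test_that("rescaling factors survive a JSON round trip", {
  f <- derive_rescaling_factors(analytic_summaries(0.2, 0.9))
  path <- withr::local_tempfile(fileext = ".json")
  write_rescaling_factors(f, path)
  back <- read_rescaling_factors(path)
  expect_equal(back$scale1, f$scale1)
  expect_equal(back$scale2, f$scale2)
})
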