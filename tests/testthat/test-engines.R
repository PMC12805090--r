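toy_participant <- function(...) {
  base <- data.frame(id = "t1", age = 50, sex = "female",
                     ethnicity = "Chinese", systolic_bp = 130,
                     on_bp_treatment = FALSE, total_chol = 5.5,
                     hdl_chol = 1.3, current_smoker = FALSE,
                     diabetes = FALSE, stringsAsFactors = FALSE)
  over <- list(...)
  base[names(over)] <- over
  base
}

test_that("linear predictor is the coefficient-weighted sum of transforms", {
  zero <- coefficient_set("zero", list(sex = "female"),
                          list(chol = "mmol/L", sbp = "mmHg"),
                          terms = list(), mean_lp = 0,
                          baseline_survival_10y = 0.9)
  expect_equal(linear_predictor(toy_participant(), zero), 0)

  one_term <- coefficient_set("t", list(sex = "female"),
                              list(chol = "mmol/L", sbp = "mmHg"),
                              list(list(name = "age", transform = "identity",
                                        coef = 0.1)),
                              mean_lp = 0, baseline_survival_10y = 0.9)
  expect_equal(linear_predictor(toy_participant(), one_term), 5.0)
  ln_term <- coefficient_set("t", list(sex = "female"),
                             list(chol = "mmol/L", sbp = "mmHg"),
                             list(list(name = "age", transform = "ln",
                                       coef = 1)),
                             mean_lp = 0, baseline_survival_10y = 0.9)
  expect_error(linear_predictor(toy_participant(age = -1), ln_term),
               "non-positive")
  unknown <- coefficient_set("t", list(sex = "female"),
                             list(chol = "mmol/L", sbp = "mmHg"),
                             list(list(name = "waist", transform = "ln",
                                       coef = 1)),
                             mean_lp = 0, baseline_survival_10y = 0.9)
  expect_error(linear_predictor(toy_participant(), unknown),
               "unresolvable")
})

test_that("packaged PCE-W female profile matches a term-by-term hand sum", {
  cs <- load_coefficient_sets("pce_w")$female
  p <- toy_participant(age = 60, total_chol = 6.1, hdl_chol = 1.3,
                       systolic_bp = 140, on_bp_treatment = TRUE,
                       current_smoker = TRUE, diabetes = TRUE)
  tc <- 6.1 * 38.67; hdl <- 1.3 * 38.67
  hand <- -29.799 * log(60) + 4.884 * log(60)^2 +
    13.540 * log(tc) - 3.114 * log(60) * log(tc) +
    -13.578 * log(hdl) + 3.149 * log(60) * log(hdl) +
    2.019 * log(140) +                      # treated SBP
    7.574 - 1.665 * log(60) +               # current smoker
    0.661                                   # diabetes
  expect_equal(linear_predictor(p, cs), hand, tolerance = 1e-12)
  # reference profile of the publication: 55y, TC 213 mg/dL, HDL 50,
  # SBP 120 untreated, non-smoker, no diabetes -> 2.1% (women), 5.3% (men)
  ref <- toy_participant(age = 55, total_chol = 213 / 38.67,
                         hdl_chol = 50 / 38.67, systolic_bp = 120)
  expect_lt(abs(100 * risk_from_lp(linear_predictor(ref, cs), cs) - 2.1),
            0.15)
  csm <- load_coefficient_sets("pce_w")$male
  expect_lt(abs(100 * risk_from_lp(linear_predictor(ref, csm), csm) - 5.3),
            0.15)
})

test_that("risk formula obeys its algebraic identities and monotonicity", {
  cs <- coefficient_set("t", list(sex = "male"),
                        list(chol = "mmol/L", sbp = "mmHg"), list(),
                        mean_lp = 1.7, baseline_survival_10y = 0.95)
  expect_equal(risk_from_lp(1.7, cs), 1 - 0.95)
  expect_equal(risk_from_lp(1.7 + log(2), cs), 1 - 0.95^2)
  set.seed(11)
  lp <- sort(rnorm(50))
  expect_true(all(diff(risk_from_lp(lp, cs)) > 0))
  expect_true(all(risk_from_lp(rnorm(100, 0, 5), cs) >= 0 &
                    risk_from_lp(rnorm(100, 0, 5), cs) <= 1))
})

test_that("cloglog rescaling matches hand arithmetic and preserves ranking", {
  expect_equal(cloglog_rescale(0.1, 0, 1), 0.1)
  expect_equal(cloglog_rescale(0.1, log(2), 1), 1 - exp(-2 * (-log(0.9))))
  expect_equal(round(cloglog_rescale(0.1, log(2), 1), 4), 0.19)
  expect_error(cloglog_rescale(0, 0, 1), "strictly inside")
  expect_error(cloglog_rescale(1, 0, 1), "strictly inside")
  set.seed(12)
  p <- runif(200, 0.001, 0.6)
  for (s in list(c(-0.5, 0.75), c(log(2), 1.2), c(0.3, 0.5)))
    expect_identical(order(cloglog_rescale(p, s[1], s[2])), order(p))
  f <- load_score2_rescaling()
  expect_equal(score2_region_rescale(0.1, list(scale1 = 0, scale2 = 1)), 0.1)
  expect_identical(order(score2_region_rescale(p, f$male)), order(p))
})

test_that("baseline-survival localisation uses the stratum Kaplan-Meier", {
  base <- load_coefficient_sets("frs_atp3")
  chd <- default_endpoints()$CHD
  mk <- function(n, fu, code = NA_character_, et = NA_real_) {
    df <- fixture_small()[rep(1, n), ]
    df$id <- sprintf("S%03d", seq_len(n))
    df$sex <- "male"; df$ethnicity <- "Chinese"
    df$follow_up_years <- fu
    df$event_code <- code; df$event_fatal <- FALSE; df$event_time_years <- et
    df
  }
  # zero events, complete 10-year follow-up: S0 = 1, risks all zero
  loc <- sg_frs_localize(base["male"], mk(40, 12), spec = chd)
  expect_equal(loc$male_Chinese$baseline_survival_10y, 1.0)
  expect_equal(predict_risk(mk(5, 12), loc)$risk_10y, rep(0, 5))
  # 10% events within the horizon, no censoring: S0 = 0.90 exactly
  coh <- mk(100, 12)
  coh$event_code[1:10] <- "I21"
  coh$event_time_years[1:10] <- seq(0.5, 9.5, by = 1)
  coh$follow_up_years[1:10] <- coh$event_time_years[1:10]
  loc <- sg_frs_localize(base["male"], coh, spec = chd)
  expect_equal(loc$male_Chinese$baseline_survival_10y, 0.90)
  # censored stratum: equals the hand product-limit computation
  coh2 <- mk(10, c(2, 4, 4, 5, 6, 7, 8, 9, 11, 12))
  coh2$event_code[c(2, 5, 8)] <- "I21"
  coh2$event_time_years[c(2, 5, 8)] <- c(4, 6, 9)
  loc2 <- sg_frs_localize(base["male"], coh2, spec = chd)
  oc <- survival_outcomes(coh2, chd)
  expect_equal(1 - loc2$male_Chinese$baseline_survival_10y,
               brute_force_km_risk(oc$time, oc$event, 10))
  # coefficients are untouched, so within-stratum ranking cannot change
  expect_identical(loc2$male_Chinese$terms, base$male$terms)
})

test_that("batch prediction is deterministic and stratified correctly", {
  empty <- fixture_small()[0, ]
  expect_equal(nrow(predict_risk(empty, load_coefficient_sets("pce_w"))), 0)
  coh <- resolve_diabetes(fixture_small())
  pw <- predict_risk(coh, load_coefficient_sets("pce_w"))
  pa <- predict_risk(coh, load_coefficient_sets("pce_aa"))
  expect_equal(nrow(pw), nrow(pa))
  expect_false(all(pw$risk_10y == pa$risk_10y))
  dup <- coh[c(1, 1), ]
  expect_equal(predict_risk(dup, load_coefficient_sets("pce_w"))$risk_10y,
               rep(pw$risk_10y[1], 2))
  expect_identical(pw$risk_10y,
                   predict_risk(coh, load_coefficient_sets("pce_w"))$risk_10y)
  expect_true(all(pw$risk_10y >= 0 & pw$risk_10y <= 1))
})

test_that("risk increases in systolic blood pressure when its loading is positive", {
  for (m in c("pce_w", "score2")) {
    cs <- load_coefficient_sets(m)$male
    sbps <- seq(100, 200, by = 10)
    p <- toy_participant(sex = "male")[rep(1, length(sbps)), ]
    p$systolic_bp <- sbps
    expect_true(all(diff(risk_from_lp(linear_predictor(p, cs), cs)) > 0))
  }
})

test_that("packaged coefficient files verify against their checksums", {
  expect_true(verify_coefficients())
  cs <- load_coefficient_sets("pce_w")$female
  path <- withr::local_tempfile(fileext = ".json")
  write_coefficient_set(cs, path)
  back <- read_coefficient_set(path)
  expect_equal(back$terms, cs$terms)
  expect_equal(back$mean_lp, cs$mean_lp)
  expect_equal(back$baseline_survival_10y, cs$baseline_survival_10y)
})
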