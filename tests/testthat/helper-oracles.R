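# Independent oracles used by the tests: deliberately naive O(n^2) /
# product-limit implementations, kept free of any package internals.

# Harrell concordance by pair enumeration: the shorter time must end in an
# event (an event is treated as preceding a censoring at the same time);
# ties in the risk score count 1/2.
brute_force_c <- function(risk, time, event) {
  n <- length(risk)
  conc <- disc <- ties <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (time[i] == time[j]) {
      if (event[i] + event[j] != 1) next
      short <- if (event[i] == 1) i else j
    } else {
      short <- if (time[i] < time[j]) i else j
      if (event[short] != 1) next
    }
    long <- if (short == i) j else i
    if (risk[short] > risk[long]) conc <- conc + 1
    else if (risk[short] < risk[long]) disc <- disc + 1
    else ties <- ties + 1
  }
  (conc + 0.5 * ties) / (conc + disc + ties)
}

# Kaplan-Meier cumulative event probability at a horizon by the explicit
# product-limit formula (censored subjects at an event time remain at risk)
brute_force_km_risk <- function(time, event, horizon = 10) {
  event[time > horizon] <- 0
  time <- pmin(time, horizon)
  s <- 1
  for (t in sort(unique(time[event == 1]))) {
    if (t > horizon) break
    d <- sum(time == t & event == 1)
    r <- sum(time >= t)
    s <- s * (1 - d / r)
  }
  1 - s
}

# random censored survival dataset generator for oracle comparisons
random_survival_data <- function(n, tie_times = TRUE, tie_risks = TRUE) {
  time <- if (tie_times) sample(1:15, n, replace = TRUE) else
    round(runif(n, 0.1, 15), 3)
  risk <- if (tie_risks) round(runif(n, 0.01, 0.5), 2) else
    runif(n, 0.01, 0.5)
  event <- rbinom(n, 1, 0.4)
  if (sum(event) == 0) event[sample.int(n, 1)] <- 1L
  list(risk = risk, time = time, event = event)
}

# one evaluable mid-sized synthetic cohort with PCE-W risks, shared by
# several evaluation tests
make_eval_cohort <- function(n = 4000, seed = 101, template = "mec1",
                             scale1 = 0, scale2 = 1) {
  cfg <- generator_config(template, n = n, seed = seed,
                          outcome = list(model = "pce_w",
                                         scale1 = scale1, scale2 = scale2))
  coh <- generate_cohort(cfg)
  coh <- filter_eligible(coh, "pce")
  risk <- predict_risk(coh, load_coefficient_sets("pce_w"))$risk_10y
  oc <- survival_outcomes(coh, default_endpoints()$ASCVD)
  list(cohort = coh, risk = risk, time = oc$time, event = oc$event)
}
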