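# shared fixtures: everything is generated in code, no stored data

# a fast, fully valid two-strategy model for engine-level tests
quick_model <- function(scenario = "B", horizon_weeks = 260,
                        ngs_mode = "flat") {
  raw <- make_fixture_config(scenario, survival = "plausible",
                             ngs_mode = ngs_mode)
  raw$settings$horizon_weeks <- horizon_weeks
  ce_model(raw)
}

# a table of valid parameter sets per family, used in grid/property tests
family_param_table <- function() {
  list(
    exponential = list(params = c(rate = 0.12)),
    weibull = list(params = c(shape = 1.6, scale = 8)),
    gamma = list(params = c(shape = 2.1689, rate = 0.1485)),
    lognormal = list(params = c(meanlog = 1.8, sdlog = 0.7)),
    loglogistic = list(params = c(shape = 2.3, scale = 7)),
    gompertz = list(params = c(shape = 0.068, rate = 0.0142)),
    generalized_gamma = list(params = c(mu = 1.9, sigma = 0.6, Q = 0.8)),
    rp_spline = list(params = c(gamma0 = -2.2, gamma1 = 1.4,
                                gamma2 = 0.05, gamma3 = 0.02),
                     knots = log(c(2, 5, 9, 18))),
    mixture_cure = list(params = c(theta = 0.15, shape = 1.7, scale = 6),
                        base_family = "weibull"),
    nonmixture_cure = list(params = c(theta = 0.2, meanlog = 1.2,
                                      sdlog = 0.6),
                           base_family = "lognormal")
  )
}

make_family_dist <- function(fam, spec = family_param_table()[[fam]]) {
  surv_dist(fam, spec$params, knots = spec$knots,
            base_family = spec$base_family)
}

# random but valid strategy config (smooth families only, so all trace
# invariants are mathematically guaranteed)
random_strategy <- function() {
  fam <- sample(c("exponential", "weibull", "gompertz", "gamma"), 2,
                replace = TRUE)
  mk <- function(f, slow) {
    switch(f,
      exponential = surv_dist("exponential",
                              c(rate = runif(1, 0.03, 0.3) * slow)),
      weibull = surv_dist("weibull", c(shape = runif(1, 0.8, 2.5),
                                       scale = runif(1, 3, 20) / slow)),
      gamma = surv_dist("gamma", c(shape = runif(1, 0.8, 3),
                                   rate = runif(1, 0.05, 0.3) * slow)),
      gompertz = surv_dist("gompertz", c(shape = runif(1, 0.01, 0.1),
                                         rate = runif(1, 0.01, 0.1) * slow))
    )
  }
  strategy_config(
    name = "random",
    pfs_model = mk(fam[1], slow = 1.5),   # progression faster than death
    os_model = mk(fam[2], slow = 1),
    weekly_drug_cost = runif(1, 100, 3000),
    p_subsequent_active = runif(1),
    subsequent_mix = data.frame(label = c("a", "b"),
                                proportion = c(0.6, 0.4),
                                monthly_cost = runif(2, 500, 12000)),
    subsequent_duration_months = runif(1, 1, 8),
    supportive_care_cost_day = runif(1, 50, 300),
    followup_cost_week = runif(1, 50, 250),
    terminal_cost = runif(1, 10000, 50000),
    ngs = if (runif(1) < 0.5) {
      list(test_cost = 5800, prevalence = runif(1, 0.05, 0.9),
           mode = sample(c("flat", "per_screened"), 1))
    } else NULL
  )
}

run_outcome_for_hr <- function(m, hr) {
  run_model(apply_param(m, "hr_pfs", hr))$result$inhb
}

expect_valid_trace <- function(trace) {
  expect_true(max(abs(trace$p_pfd + trace$p_pd + trace$p_dead - 1)) < 1e-9)
  expect_true(all(trace$p_pfd >= -1e-12 & trace$p_pd >= -1e-12 &
                    trace$p_dead >= -1e-12))
  expect_false(is.unsorted(trace$p_dead))
  tt <- trace_totals(trace)
  expect_equal(tt$total_cost, sum(trace$cost))
  expect_equal(tt$total_qalys, sum(trace$qaly))
}
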