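test_that("adjusted_survival is an identity at hr = 1 with own = ref", {
  d <- surv_dist("weibull", c(shape = 1.5, scale = 10))
  t <- seq(0, 48, by = 1.5)
  expect_equal(adjusted_survival(d, d, hr = 1, cutoff = 18, t),
               survival_at(d, t))
})

test_that("adjusted_survival is continuous at the cutoff", {
  own <- surv_dist("gompertz", c(shape = 0.068, rate = 0.0142))
  ref <- surv_dist("gamma", c(shape = 2.1689, rate = 0.1485))
  eps <- 1e-9
  s <- adjusted_survival(own, ref, hr = 0.64, cutoff = 24,
                         c(24 - eps, 24, 24 + eps))
  expect_lt(max(abs(s - s[2])), 1e-6)
  expect_equal(s[2], survival_at(own, 24))
})

test_that("adjusted_survival matches the exponential closed form", {
  # oracle: S(18) * exp(-hr * rate * (t - 18)) for an exponential tail
  own <- surv_dist("weibull", c(shape = 1.3, scale = 12))
  ref <- surv_dist("exponential", c(rate = 0.1))
  got <- adjusted_survival(own, ref, hr = 0.34, cutoff = 18, t = 24)
  want <- survival_at(own, 18) * exp(-0.34 * 0.1 * 6)
  expect_equal(got, want, tolerance = 1e-10)
  # exhausted reference curve is an error at the operation level
  dead <- surv_dist("exponential", c(rate = 100))
  expect_error(adjusted_survival(own, dead, 0.5, 18, 24), "undefined")
})

test_that("state memberships partition to one for random configs", {
  set.seed(42)
  settings <- model_settings(horizon_weeks = 156)
  for (r in 1:3) {
    tr <- build_trace(random_strategy(), settings)
    expect_valid_trace(tr)
  }
})

test_that("degenerate settings reduce QALYs to the OS area", {
  os <- surv_dist("exponential", c(rate = 0.08))
  st <- strategy_config("bare", pfs_model = os, os_model = os)
  settings <- model_settings(horizon_weeks = 260, annual_discount = 0,
                             u_pfd = 1, u_pd = 1)
  tr <- build_trace(st, settings)
  tt <- trace_totals(tr)
  expect_equal(tt$total_qalys, tt$total_lys)
  wpm <- 365.25 / 84
  auc <- sum(survival_at(os, seq_len(260) / wpm)) / 52.1775
  expect_equal(tt$total_lys, auc, tolerance = 1e-12)
  expect_equal(tt$total_cost, 0)
})

test_that("exponential mean survival is recovered at a long horizon", {
  r_year <- 0.5  # per year
  wpy <- 52.1775
  os <- surv_dist("exponential", c(rate = r_year / wpy), "weeks")
  # express the curve in months for the engine
  wpm <- 365.25 / 84
  os_m <- surv_dist("exponential", c(rate = r_year / wpy * wpm))
  st <- strategy_config("bare", pfs_model = os_m, os_model = os_m)
  horizon <- ceiling(40 / r_year * wpy)
  settings <- model_settings(horizon_weeks = horizon, annual_discount = 0,
                             u_pfd = 1, u_pd = 1)
  tt <- trace_totals(build_trace(st, settings))
  expect_equal(tt$total_lys, 1 / r_year, tolerance = 0.01)
})

test_that("screening cost is additive and drug cost is monotone", {
  m <- quick_model("B", horizon_weeks = 156)
  raw <- m$raw
  with_ngs <- trace_totals(run_model(ce_model(raw))$traces[[2]])
  raw_no <- raw; raw_no$ngs <- NULL
  without <- trace_totals(run_model(ce_model(raw_no))$traces[[2]])
  expect_equal(with_ngs$total_cost - without$total_cost,
               screening_cost(5800, raw$ngs$prevalence, raw$ngs$mode))

  cheaper <- trace_totals(
    run_model(apply_param(m, "cost_olaparib_day", 100))$traces[[2]])
  dearer <- trace_totals(
    run_model(apply_param(m, "cost_olaparib_day", 300))$traces[[2]])
  expect_lt(cheaper$total_cost, dearer$total_cost)
})

test_that("identical arms with zero discount give exactly zero deltas", {
  os <- surv_dist("gamma", c(shape = 2, rate = 0.12))
  pfs <- surv_dist("weibull", c(shape = 1.4, scale = 5))
  mk <- function() strategy_config("same", pfs_model = pfs, os_model = os,
                                   weekly_drug_cost = 500,
                                   followup_cost_week = 146,
                                   terminal_cost = 36403)
  settings <- model_settings(horizon_weeks = 200, annual_discount = 0)
  r <- compare_traces(build_trace(mk(), settings),
                      build_trace(mk(), settings), wtp = 150000)
  expect_identical(r$delta_cost, 0)
  expect_identical(r$delta_effect, 0)
})

test_that("halving the cycle length barely moves smooth totals", {
  os <- surv_dist("exponential", c(rate = 0.05))
  pfs <- surv_dist("exponential", c(rate = 0.12))
  st <- strategy_config("sm", pfs_model = pfs, os_model = os,
                        weekly_drug_cost = 1000,
                        supportive_care_cost_day = 190,
                        followup_cost_week = 146, terminal_cost = 36403,
                        p_subsequent_active = 0.5,
                        subsequent_mix = data.frame(
                          label = "x", proportion = 1,
                          monthly_cost = 5000),
                        subsequent_duration_months = 4)
  t1 <- trace_totals(build_trace(st, model_settings(horizon_weeks = 520)))
  t2 <- trace_totals(build_trace(st, model_settings(
    cycle_length_weeks = 0.5, horizon_weeks = 520)))
  expect_lt(abs(t1$total_cost - t2$total_cost) / t1$total_cost, 0.01)
  expect_lt(abs(t1$total_qalys - t2$total_qalys) / t1$total_qalys, 0.01)
})

test_that("nns and screening_cost follow the one-decimal convention", {
  expect_equal(nns(0.18), 5.6)
  expect_equal(nns(1), 1)
  expect_equal(nns(0.28), 3.6)
  expect_error(nns(0), "prevalence")
  expect_equal(screening_cost(5800, 0.18, "flat"), 5800)
  expect_equal(screening_cost(5800, 1, "per_screened"), 5800)
  expect_equal(screening_cost(5800, 0.18, "per_screened"), 5800 * 5.6)
  expect_error(screening_cost(5800, 0, "flat"), "prevalence")
})

test_that("adverse events hit cost and QALYs once, in the first cycle", {
  os <- surv_dist("exponential", c(rate = 0.05))
  pfs <- surv_dist("exponential", c(rate = 0.1))
  ae <- data.frame(label = c("anemia", "fatigue"),
                   probability = c(0.2, 0.1), cost = c(145, 858),
                   disutility = c(0.16, 0.16), duration_weeks = c(4, 2))
  mk <- function(a) strategy_config("ae", pfs_model = pfs, os_model = os,
                                    ae_events = a)
  settings <- model_settings(horizon_weeks = 104, annual_discount = 0)
  with_ae <- build_trace(mk(ae), settings)
  without <- build_trace(mk(NULL), settings)
  expect_equal(trace_totals(with_ae)$total_cost,
               sum(ae$probability * ae$cost))
  dq <- trace_totals(without)$total_qalys -
    trace_totals(with_ae)$total_qalys
  expect_equal(dq, sum(ae$probability * 0.16 * ae$duration_weeks) /
                 52.1775)
  # only cycle 1 differs
  expect_equal(with_ae$qaly[-2], without$qaly[-2])
})

test_that("strategy_config validates its inputs", {
  os <- surv_dist("exponential", c(rate = 0.05))
  expect_error(strategy_config("x", os, os,
                               subsequent_mix = data.frame(
                                 label = "a", proportion = 0.7,
                                 monthly_cost = 10)), "sum to 1")
  expect_error(strategy_config("x", os, os, p_subsequent_active = 1.2))
  expect_error(strategy_config("x", os, os, weekly_drug_cost = -5))
  expect_error(strategy_config("x", os, os,
                               ngs = list(test_cost = 5800,
                                          prevalence = 0, mode = "flat")))
})
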