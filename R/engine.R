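#' Model settings for the partitioned survival engine
#'
#' Global settings shared by both strategies: cycle structure, discounting,
#' state utilities and the willingness-to-pay threshold.
#'
#' @param cycle_length_weeks Cycle length in weeks (default 1).
#' @param horizon_weeks Time horizon in weeks (default 520, i.e. 10 years).
#' @param annual_discount Annual discount rate for costs and QALYs
#'   (default 0.03).
#' @param u_pfd,u_pd State utilities for progression-free and progressed
#'   disease (defaults 0.76 and 0.37).
#' @param wtp Willingness-to-pay threshold in $ per QALY (default 150000).
#' @param half_cycle Apply a half-cycle correction (average of start- and
#'   end-of-cycle membership)? Default `FALSE`.
#' @return A `model_settings` object.
#' @export
model_settings <- function(cycle_length_weeks = 1, horizon_weeks = 520,
                           annual_discount = 0.03, u_pfd = 0.76,
                           u_pd = 0.37, wtp = 150000,
                           half_cycle = FALSE) {
  stopifnot(cycle_length_weeks > 0, horizon_weeks >= cycle_length_weeks,
            annual_discount >= 0, u_pfd >= 0, u_pfd <= 1,
            u_pd >= 0, u_pd <= 1, wtp > 0)
  structure(list(cycle_length_weeks = cycle_length_weeks,
                 horizon_weeks = horizon_weeks,
                 annual_discount = annual_discount,
                 u_pfd = u_pfd, u_pd = u_pd, wtp = wtp,
                 half_cycle = half_cycle,
                 weeks_per_year = 52.1775,
                 weeks_per_month = 365.25 / 84),
            class = "model_settings")
}

#' Strategy configuration for one arm
#'
#' Holds everything strategy-specific: the fitted PFS/OS models, optional
#' hazard-ratio tail extrapolation against a reference arm, drug and
#' health-state costs, adverse-event burden, and (for the test-directed
#' arm) the genomic screening cost block.
#'
#' @param name Strategy label.
#' @param pfs_model,os_model [surv_dist()] objects on the months scale.
#' @param pfs_reference,os_reference Reference-arm [surv_dist()] objects,
#'   used with `hr_pfs`/`hr_os` beyond the `cutoffs` to carry the tail
#'   forward under proportional hazards; `NULL` disables extrapolation.
#' @param hr_pfs,hr_os Length-3 numeric `c(est, low, high)` hazard ratios
#'   (point estimate and 95% CI), or `NULL`.
#' @param cutoffs List `list(pfs = 18, os = 24)` in months: beyond these
#'   observed-data limits the arm's own curve is replaced by the
#'   HR-scaled reference tail.
#' @param weekly_drug_cost First-line drug acquisition cost, $/week,
#'   accrued for the whole time in the progression-free state.
#' @param price_discount Contract-price discount fraction applied to the
#'   drug acquisition cost (default 0.15).
#' @param drug_cost_is_discounted If `TRUE`, `weekly_drug_cost` is already
#'   net of the contract discount and `price_discount` is not re-applied.
#' @param p_subsequent_active Proportion of progressors receiving active
#'   subsequent therapy (the rest receive supportive care).
#' @param subsequent_mix Data frame `label, proportion, monthly_cost`
#'   describing the active subsequent-therapy regimen mix; proportions
#'   must sum to 1.
#' @param subsequent_duration_months Duration of active subsequent
#'   therapy, months.
#' @param supportive_care_cost_day Supportive care cost, $/day.
#' @param followup_cost_week Follow-up cost, $/week, accrued while alive.
#' @param terminal_cost One-off end-of-life cost per death, $.
#' @param ae_events Data frame `label, probability, cost, disutility,
#'   duration_weeks`; adverse events are applied once, in the first
#'   cycle, with duration-weighted disutility.
#' @param ngs `NULL`, or `list(test_cost, prevalence, mode)` with mode
#'   `"flat"` (cost per treated patient) or `"per_screened"` (cost scaled
#'   by the number needed to screen, see [nns()]).
#' @return A `strategy_config` object.
#' @export
strategy_config <- function(name, pfs_model, os_model,
                            pfs_reference = NULL, os_reference = NULL,
                            hr_pfs = NULL, hr_os = NULL,
                            cutoffs = NULL,
                            weekly_drug_cost = 0,
                            price_discount = 0.15,
                            drug_cost_is_discounted = FALSE,
                            p_subsequent_active = 0,
                            subsequent_mix = NULL,
                            subsequent_duration_months = 0,
                            supportive_care_cost_day = 0,
                            followup_cost_week = 0,
                            terminal_cost = 0,
                            ae_events = NULL,
                            ngs = NULL) {
  stopifnot(inherits(pfs_model, "surv_dist"), inherits(os_model, "surv_dist"))
  stopifnot(weekly_drug_cost >= 0, supportive_care_cost_day >= 0,
            followup_cost_week >= 0, terminal_cost >= 0,
            price_discount >= 0, price_discount < 1,
            p_subsequent_active >= 0, p_subsequent_active <= 1,
            subsequent_duration_months >= 0)
  if (!is.null(cutoffs)) {
    stopifnot(is.list(cutoffs), all(unlist(cutoffs) > 0))
  }
  for (hr in list(hr_pfs, hr_os)) {
    if (!is.null(hr)) stopifnot(length(hr) == 3, all(hr > 0),
                                hr[2] <= hr[1], hr[1] <= hr[3])
  }
  if (!is.null(subsequent_mix)) {
    stopifnot(is.data.frame(subsequent_mix),
              all(c("proportion", "monthly_cost") %in%
                    names(subsequent_mix)))
    if (nrow(subsequent_mix) &&
        abs(sum(subsequent_mix$proportion) - 1) > 1e-9) {
      stop("subsequent_mix proportions must sum to 1", call. = FALSE)
    }
    stopifnot(all(subsequent_mix$monthly_cost >= 0))
  }
  if (!is.null(ae_events)) {
    stopifnot(is.data.frame(ae_events),
              all(c("probability", "cost", "disutility",
                    "duration_weeks") %in% names(ae_events)),
              all(ae_events$probability >= 0 & ae_events$probability <= 1),
              all(ae_events$cost >= 0), all(ae_events$duration_weeks >= 0))
  }
  if (!is.null(ngs)) {
    stopifnot(is.list(ngs), ngs$test_cost >= 0,
              ngs$prevalence > 0, ngs$prevalence <= 1,
              ngs$mode %in% c("flat", "per_screened"))
  }
  structure(list(
    name = name, pfs_model = pfs_model, os_model = os_model,
    pfs_reference = pfs_reference, os_reference = os_reference,
    hr_pfs = hr_pfs, hr_os = hr_os, cutoffs = cutoffs,
    weekly_drug_cost = weekly_drug_cost,
    price_discount = price_discount,
    drug_cost_is_discounted = drug_cost_is_discounted,
    p_subsequent_active = p_subsequent_active,
    subsequent_mix = subsequent_mix,
    subsequent_duration_months = subsequent_duration_months,
    supportive_care_cost_day = supportive_care_cost_day,
    followup_cost_week = followup_cost_week,
    terminal_cost = terminal_cost,
    ae_events = ae_events, ngs = ngs
  ), class = "strategy_config")
}

#' Hazard-ratio tail extrapolation of a survival curve
#'
#' Up to `cutoff` the arm's own fitted curve is used; beyond it the
#' conditional tail of the reference curve is carried forward under
#' proportional hazards with hazard ratio `hr`:
#' `S(t) = S_own(cutoff) * (S_ref(t) / S_ref(cutoff))^hr`.
#' Continuous at the cutoff by construction.
#'
#' @param own,reference [surv_dist()] objects (same time unit).
#' @param hr Hazard ratio (> 0) of `own` relative to `reference`.
#' @param cutoff Extrapolation cutoff (same time unit as the models).
#' @param t Times at which to evaluate.
#' @return Survival probabilities.
#' @export
adjusted_survival <- function(own, reference, hr, cutoff, t) {
  stopifnot(hr > 0, cutoff > 0, all(t >= 0))
  s_ref_cut <- survival_at(reference, cutoff)
  if (s_ref_cut <= 0) {
    stop("reference survival is 0 at the cutoff; extrapolation undefined",
         call. = FALSE)
  }
  s_own_cut <- survival_at(own, cutoff)
  out <- survival_at(own, pmin(t, cutoff))
  tail <- t > cutoff
  if (any(tail)) {
    out[tail] <- s_own_cut *
      (survival_at(reference, t[tail]) / s_ref_cut)^hr
  }
  out
}

# strategy-level survival on the months scale, applying HR tail
# extrapolation when configured
strategy_survival <- function(strategy, endpoint = c("pfs", "os"),
                              t_months) {
  endpoint <- match.arg(endpoint)
  own <- strategy[[paste0(endpoint, "_model")]]
  ref <- strategy[[paste0(endpoint, "_reference")]]
  hr <- strategy[[paste0("hr_", endpoint)]]
  cut <- strategy$cutoffs[[endpoint]]
  if (!is.null(ref) && !is.null(hr) && !is.null(cut)) {
    if (survival_at(ref, cut) <= 0) {
      # reference curve already exhausted at the cutoff: no tail left to
      # carry forward, fall back to the arm's own fitted curve
      warning(sprintf(
        "%s: reference survival is 0 at the %s cutoff; using own curve",
        strategy$name, endpoint), call. = FALSE)
      survival_at(own, t_months)
    } else {
      adjusted_survival(own, ref, hr[1], cut, t_months)
    }
  } else {
    survival_at(own, t_months)
  }
}

#' Number needed to screen
#'
#' Reciprocal of the biomarker prevalence, reported to one decimal: the
#' expected number of patients screened per eligible (alteration-positive)
#' patient identified.
#'
#' @param prevalence Alteration prevalence in (0, 1\].
#' @return Number needed to screen, rounded to one decimal.
#' @export
nns <- function(prevalence) {
  if (any(prevalence <= 0 | prevalence > 1)) {
    stop("`prevalence` must lie in (0, 1]", call. = FALSE)
  }
  round(1 / prevalence, 1)
}

#' Genomic screening cost per treated patient
#'
#' In `"flat"` mode the test cost is charged once per treated patient. In
#' `"per_screened"` mode the cost is scaled by the number needed to screen
#' so that treated patients also carry the cost of testing the
#' alteration-negative patients who were screened to find them.
#'
#' @param test_cost Cost of one test, $.
#' @param prevalence Alteration prevalence in (0, 1\].
#' @param mode `"flat"` or `"per_screened"`.
#' @return Screening cost in $ per treated patient.
#' @export
screening_cost <- function(test_cost, prevalence,
                           mode = c("flat", "per_screened")) {
  mode <- match.arg(mode)
  stopifnot(test_cost >= 0)
  if (prevalence <= 0 || prevalence > 1) {
    stop("`prevalence` must lie in (0, 1]", call. = FALSE)
  }
  switch(mode, flat = test_cost,
         per_screened = test_cost * nns(prevalence))
}

#' Run the partitioned survival engine for one strategy
#'
#' Builds the per-cycle trace: state occupancy is read directly off the
#' PFS and OS curves (progression-free = `min(S_pfs, S_os)`, progressed =
#' `S_os - p_pfd`, dead = `1 - S_os`), and discounted cost and QALY
#' accruals are accumulated per one-week cycle.
#'
#' Cost structure per cycle: drug acquisition (net of the contract-price
#' discount) and follow-up in the progression-free state; for new
#' progressors a lump subsequent-therapy cost (regimen-mix monthly cost
#' times duration, scaled by the proportion receiving active therapy);
#' per-cycle supportive care for the progressed fraction not on active
#' therapy plus follow-up; a one-off terminal-care cost per new death;
#' adverse-event costs in the first cycle; and the genomic screening cost
#' at time zero when an `ngs` block is configured.
#'
#' @param strategy A [strategy_config()].
#' @param settings A [model_settings()].
#' @return A data frame of class `psm_trace` with one row per cycle
#'   (cycle 0 carries the screening cost) and columns `cycle`,
#'   `time_weeks`, `p_pfd`, `p_pd`, `p_dead`, `cost`, `qaly`. Totals are
#'   available through [trace_totals()].
#' @export
build_trace <- function(strategy, settings) {
  stopifnot(inherits(strategy, "strategy_config"),
            inherits(settings, "model_settings"))
  cl <- settings$cycle_length_weeks
  weeks <- seq(cl, settings$horizon_weeks, by = cl)
  wpm <- settings$weeks_per_month
  wpy <- settings$weeks_per_year
  t_months <- weeks / wpm

  s_os <- strategy_survival(strategy, "os", t_months)
  s_pfs <- strategy_survival(strategy, "pfs", t_months)
  p_pfd <- pmin(s_pfs, s_os)
  p_alive <- s_os
  p_pd <- p_alive - p_pfd
  p_dead <- 1 - p_alive

  if (settings$half_cycle) {
    avg <- function(x, x0) (c(x0, x[-length(x)]) + x) / 2
    a_pfd <- avg(p_pfd, 1); a_pd <- avg(p_pd, 0); a_alive <- avg(p_alive, 1)
  } else {
    a_pfd <- p_pfd; a_pd <- p_pd; a_alive <- p_alive
  }

  df <- (1 + settings$annual_discount)^(-weeks / wpy)
  ly_frac <- cl / wpy

  # QALYs
  qaly <- (a_pfd * settings$u_pfd + a_pd * settings$u_pd) * ly_frac * df
  ae <- strategy$ae_events
  if (!is.null(ae) && nrow(ae)) {
    qaly[1] <- qaly[1] -
      sum(ae$probability * ae$disutility * ae$duration_weeks / wpy) * df[1]
  }

  # costs
  drug_week <- strategy$weekly_drug_cost *
    (if (strategy$drug_cost_is_discounted) 1 else
      (1 - strategy$price_discount))
  cost_pfd <- a_pfd * (drug_week + strategy$followup_cost_week) * cl * df

  new_prog <- pmax(0, diff(c(1, p_pfd)))
  mix_month <- if (is.null(strategy$subsequent_mix) ||
                   !nrow(strategy$subsequent_mix)) 0 else
    sum(strategy$subsequent_mix$proportion *
          strategy$subsequent_mix$monthly_cost)
  lump_subsequent <- strategy$p_subsequent_active * mix_month *
    strategy$subsequent_duration_months
  cost_pd <- (new_prog * lump_subsequent +
                a_pd * (1 - strategy$p_subsequent_active) *
                  strategy$supportive_care_cost_day * 7 * cl +
                a_pd * strategy$followup_cost_week * cl) * df

  new_dead <- pmax(0, diff(c(0, p_dead)))
  cost_term <- new_dead * strategy$terminal_cost * df

  cost_ae <- numeric(length(weeks))
  if (!is.null(ae) && nrow(ae)) {
    cost_ae[1] <- sum(ae$probability * ae$cost) * df[1]
  }

  cost_ngs <- if (!is.null(strategy$ngs)) {
    screening_cost(strategy$ngs$test_cost, strategy$ngs$prevalence,
                   strategy$ngs$mode)
  } else 0

  cost <- cost_pfd + cost_pd + cost_term + cost_ae

  trace <- data.frame(
    cycle = c(0, seq_along(weeks)),
    time_weeks = c(0, weeks),
    p_pfd = c(1, p_pfd), p_pd = c(0, p_pd), p_dead = c(0, p_dead),
    cost = c(cost_ngs, cost), qaly = c(0, qaly)
  )
  class(trace) <- c("psm_trace", "data.frame")
  attr(trace, "totals") <- list(
    total_cost = cost_ngs + sum(cost),
    total_qalys = sum(qaly),
    total_lys = sum(a_alive * ly_frac * df),
    cost_pfd = cost_ngs + sum(cost_pfd) + sum(cost_ae)
  )
  attr(trace, "strategy") <- strategy$name
  trace
}

#' Totals of a partitioned-survival trace
#'
#' @param trace A `psm_trace` from [build_trace()].
#' @return List with `total_cost`, `total_qalys`, `total_lys` (discounted)
#'   and `cost_pfd` (cost accrued in the progression-free state, including
#'   adverse-event and screening costs).
#' @export
trace_totals <- function(trace) {
  stopifnot(inherits(trace, "psm_trace"))
  attr(trace, "totals")
}

#' Export a trace to CSV
#'
#' @param trace A `psm_trace`.
#' @param path Output CSV path.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "psm_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
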