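#' Incremental cost-effectiveness outputs
#'
#' Computes the incremental cost-effectiveness ratio (ICER), incremental
#' net health benefit `INHB = dE - dC / lambda` (QALYs) and incremental
#' net monetary benefit `INMB = dE * lambda - dC` ($) for an intervention
#' (arm 1) against a comparator (arm 0), with standard dominance
#' labelling: "dominant" when the intervention is cheaper and more
#' effective, "dominated" when costlier and less effective. An ICER is
#' reported only when the increments lie in quadrants I or III of the
#' cost-effectiveness plane; elsewhere a ratio is not meaningful.
#'
#' @param delta_cost Incremental cost `dC = cost_1 - cost_0`, $.
#' @param delta_effect Incremental effectiveness `dE = effect_1 -
#'   effect_0`, QALYs.
#' @param wtp Willingness-to-pay threshold `lambda`, $/QALY.
#' @param cost_0,cost_1,effect_0,effect_1 Optional arm-level totals,
#'   carried through for reporting.
#' @return A `ce_result`: list with `delta_cost`, `delta_effect`, `icer`
#'   (numeric, `NA` when undefined), `icer_label` (`"dominant"`,
#'   `"dominated"`, `"undefined"` or the formatted ratio), `inhb`, `inmb`,
#'   `wtp` and `cost_effective` (`inmb > 0`).
#' @examples
#' evaluate_ce(delta_cost = -6950, delta_effect = 0.068, wtp = 150000)
#' @export
evaluate_ce <- function(delta_cost, delta_effect, wtp,
                        cost_0 = NA_real_, cost_1 = NA_real_,
                        effect_0 = NA_real_, effect_1 = NA_real_) {
  stopifnot(wtp > 0)
  if (!is.na(cost_0) && !is.na(cost_1)) {
    stopifnot(abs((cost_1 - cost_0) - delta_cost) < 1e-6)
  }
  inhb <- delta_effect - delta_cost / wtp
  inmb <- delta_effect * wtp - delta_cost
  if (delta_effect > 0 && delta_cost < 0) {
    icer <- NA_real_; label <- "dominant"
  } else if (delta_effect < 0 && delta_cost > 0) {
    icer <- NA_real_; label <- "dominated"
  } else if (delta_effect == 0) {
    icer <- if (delta_cost == 0) 0 else NA_real_
    label <- if (delta_cost == 0) "0" else "undefined"
  } else {
    icer <- delta_cost / delta_effect
    label <- format(round(icer), big.mark = ",", scientific = FALSE)
  }
  structure(list(
    cost_0 = cost_0, cost_1 = cost_1,
    effect_0 = effect_0, effect_1 = effect_1,
    delta_cost = delta_cost, delta_effect = delta_effect,
    icer = icer, icer_label = label, inhb = inhb, inmb = inmb,
    wtp = wtp, cost_effective = inmb > 0
  ), class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat("<ce_result>\n")
  cat(sprintf("  dC = $%s, dE = %.3f QALY\n",
              format(round(x$delta_cost), big.mark = ","), x$delta_effect))
  cat(sprintf("  ICER: %s  INHB: %.3f QALY  INMB: $%s (lambda = %s)\n",
              x$icer_label, x$inhb,
              format(round(x$inmb), big.mark = ","),
              format(x$wtp, big.mark = ",")))
  cat(sprintf("  cost-effective at lambda: %s\n", x$cost_effective))
  invisible(x)
}

#' Compare two strategy traces
#'
#' Convenience wrapper: pulls totals from two [build_trace()] results
#' (comparator first) and calls [evaluate_ce()].
#'
#' @param trace_0 Comparator trace (e.g. standard care).
#' @param trace_1 Intervention trace.
#' @param wtp Willingness-to-pay threshold, $/QALY.
#' @return A `ce_result` with arm-level totals attached.
#' @export
compare_traces <- function(trace_0, trace_1, wtp) {
  t0 <- trace_totals(trace_0)
  t1 <- trace_totals(trace_1)
  evaluate_ce(delta_cost = t1$total_cost - t0$total_cost,
              delta_effect = t1$total_qalys - t0$total_qalys,
              wtp = wtp,
              cost_0 = t0$total_cost, cost_1 = t1$total_cost,
              effect_0 = t0$total_qalys, effect_1 = t1$total_qalys)
}

#' Format a cost-effectiveness summary table
#'
#' Rounds a model run to reporting precision: costs to whole dollars,
#' life-years/QALYs and INHB to three decimals.
#'
#' @param run A model run from [run_model()].
#' @return Data frame with one row per strategy plus incremental columns
#'   on the intervention row.
#' @export
ce_summary <- function(run) {
  tt0 <- trace_totals(run$traces[[1]])
  tt1 <- trace_totals(run$traces[[2]])
  r <- run$result
  data.frame(
    strategy = c(attr(run$traces[[1]], "strategy"),
                 attr(run$traces[[2]], "strategy")),
    total_cost = round(c(tt0$total_cost, tt1$total_cost)),
    cost_pfd = round(c(tt0$cost_pfd, tt1$cost_pfd)),
    lys = round(c(tt0$total_lys, tt1$total_lys), 3),
    qalys = round(c(tt0$total_qalys, tt1$total_qalys), 3),
    icer = c(NA, r$icer_label),
    inhb = c(NA, round(r$inhb, 3)),
    inmb = c(NA, round(r$inmb))
  )
}
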