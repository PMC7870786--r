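#' Simulation scenario for synthetic arm-level time-to-event data
#'
#' Describes one simulated trial arm: the progression-time distribution,
#' the post-progression residual survival distribution (overall survival
#' is progression time plus an independent post-progression residual, so
#' PFS <= OS holds for every virtual patient by construction), the arm
#' size and the administrative censoring (follow-up) time.
#'
#' @param pfs_dist [surv_dist()] for time to progression.
#' @param post_progression_dist [surv_dist()] for residual survival after
#'   progression (same time unit).
#' @param n Number of virtual patients.
#' @param followup Administrative censoring time (same unit as the
#'   distributions).
#' @return A `sim_scenario` object.
#' @export
sim_scenario <- function(pfs_dist, post_progression_dist, n, followup) {
  stopifnot(inherits(pfs_dist, "surv_dist"),
            inherits(post_progression_dist, "surv_dist"),
            n >= 1, followup >= 0)
  structure(list(pfs_dist = pfs_dist,
                 post_progression_dist = post_progression_dist,
                 n = as.integer(n), followup = followup),
            class = "sim_scenario")
}

#' Simulate individual-patient data for one arm
#'
#' Inverse-transform sampling from the scenario's distributions:
#' `T_pfs = S_pfs^{-1}(U1)`, `T_os = T_pfs + S_post^{-1}(U2)`, both
#' administratively censored at the follow-up time. Cured patients
#' (infinite sampled times under defective distributions) are censored at
#' follow-up.
#'
#' @param scenario A [sim_scenario()].
#' @param seed Integer seed; the same seed reproduces the same dataset.
#' @return List with elements `pfs` and `os`, each a `time`/`event` data
#'   frame of length `n`.
#' @export
simulate_ipd <- function(scenario, seed) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  n <- scenario$n
  fu <- scenario$followup
  t_pfs <- quantile_at(scenario$pfs_dist, stats::runif(n))
  t_res <- quantile_at(scenario$post_progression_dist, stats::runif(n))
  t_os <- t_pfs + t_res
  if (fu == 0) {
    warning("follow-up time 0: all records censored at 0", call. = FALSE)
  }
  mk <- function(t) data.frame(time = pmin(t, fu),
                               event = as.integer(t <= fu & is.finite(t)))
  list(pfs = mk(t_pfs), os = mk(t_os))
}

#' Emulate curve digitization of simulated data
#'
#' Computes the exact Kaplan-Meier estimator of the IPD, samples it on a
#' regular time grid and emits a numbers-at-risk table at the requested
#' interval, mimicking what digitizing a published figure produces.
#'
#' @param ipd `time`/`event` data frame.
#' @param grid Time step of the digitization grid.
#' @param risk_interval Spacing of the numbers-at-risk table.
#' @param jitter Standard deviation of optional digitization noise added
#'   to the sampled survival values (default 0 = exact); noisy values are
#'   clamped to \[0, 1\] and re-monotonized.
#' @param seed Seed used only when `jitter > 0`.
#' @param include_total_events Attach the true event total to the output
#'   (off by default: published figures do not always report it).
#' @return A [digitized_km()] object.
#' @export
digitize_km <- function(ipd, grid, risk_interval, jitter = 0, seed = 1,
                        include_total_events = FALSE) {
  check_ipd(ipd)
  if (nrow(ipd) == 0) stop("empty IPD", call. = FALSE)
  km <- km_estimate(ipd)
  t_max <- max(ipd$time)
  t_grid <- unique(c(0, seq(grid, t_max, by = grid), t_max))
  s_grid <- km_at(km, t_grid)
  if (jitter > 0) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
    s_grid <- s_grid + stats::rnorm(length(s_grid), 0, jitter)
    s_grid[1] <- 1
    s_grid <- pmin(pmax(s_grid, 0), 1)
    s_grid <- rev(cummax(rev(s_grid)))  # restore monotonicity
    s_grid <- cummin(s_grid)
  }
  t_risk <- seq(0, t_max, by = risk_interval)
  n_risk <- vapply(t_risk, function(t) sum(ipd$time >= t), integer(1))
  digitized_km(points = data.frame(time = t_grid, survival = s_grid),
               risk_table = data.frame(time = t_risk, n_risk = n_risk),
               total_events = if (include_total_events) sum(ipd$event)
                              else NULL)
}
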