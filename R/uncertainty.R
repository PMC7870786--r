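#' Derive beta distribution parameters from a mean and range
#'
#' Method-of-moments rule used for probability/utility inputs: the range
#' is read as a 95% interval, `sd = (high - low) / 3.92`, and
#' `alpha = m * m (1 - m) / sd^2`, `beta = (1 - m) * m (1 - m) / sd^2`.
#' Note the total `m (1 - m) / sd^2` deliberately omits the usual `- 1`
#' correction; this is the convention the package's reference input table
#' was built with and it reproduces its printed (alpha, beta) pairs.
#'
#' @param mean Mean proportion in (0, 1).
#' @param low,high Range bounds (read as a 95% interval) within (0, 1).
#' @return Named vector `c(alpha, beta)`.
#' @examples
#' derive_beta(0.37, 0.33, 0.41)  # alpha 207.1, beta 352.6
#' @export
derive_beta <- function(mean, low, high) {
  if (mean <= 0 || mean >= 1) stop("`mean` must lie in (0, 1)",
                                   call. = FALSE)
  stopifnot(low < high, low >= 0, high <= 1)
  sd <- (high - low) / 3.92
  total <- mean * (1 - mean) / sd^2
  c(alpha = mean * total, beta = (1 - mean) * total)
}

#' Derive log-normal parameters for a hazard ratio
#'
#' `meanlog = log(point)`; `sdlog = log(high / low) / 3.92` from the 95%
#' confidence interval. Printed log-sd values in secondary sources are
#' sometimes inconsistent with any CI-based derivation; pass such values
#' as explicit `dist_params` overrides in [param_spec()] instead.
#'
#' @param point Point estimate (> 0).
#' @param low,high 95% confidence limits (> 0), `low <= point <= high`.
#' @return Named vector `c(meanlog, sdlog)`.
#' @examples
#' derive_lognormal(0.34, 0.25, 0.47)
#' @export
derive_lognormal <- function(point, low, high) {
  if (point <= 0 || low <= 0 || high <= 0) {
    stop("hazard-ratio inputs must be positive", call. = FALSE)
  }
  stopifnot(low <= point, point <= high)
  c(meanlog = log(point), sdlog = log(high / low) / 3.92)
}

#' Derive gamma distribution parameters for a cost
#'
#' Method of moments on the scale parameterization: `sd = (high - low) /
#' 3.92`, `shape = mean^2 / sd^2`, `scale = sd^2 / mean`, so the implied
#' mean is `shape * scale`. Printed `(alpha, beta)` pairs can be passed
#' as overrides in [param_spec()] and are interpreted as (shape, scale)
#' with mean `alpha * beta`.
#'
#' @param mean Mean cost (> 0).
#' @param low,high Range bounds, `low < high`.
#' @return Named vector `c(shape, scale)`.
#' @export
derive_gamma <- function(mean, low, high) {
  if (mean <= 0) stop("`mean` must be positive", call. = FALSE)
  stopifnot(low < high)
  sd <- (high - low) / 3.92
  c(shape = mean^2 / sd^2, scale = sd^2 / mean)
}

#' Sensitivity-analysis parameter specification
#'
#' Couples a model input (by [apply_param()] name) with its base value,
#' one-way range and PSA sampling distribution. Distribution parameters
#' are derived from the range by the package's derivation rules
#' ([derive_beta()], [derive_gamma()], [derive_lognormal()]) unless
#' overridden.
#'
#' @param name Parameter name understood by [apply_param()].
#' @param base Base-case value.
#' @param low,high One-way range; defaults to a 25% change from base.
#' @param dist `"beta"`, `"gamma"`, `"lognormal"` or `"fixed"`.
#' @param dist_params Optional named overrides: `c(alpha, beta)`,
#'   `c(shape, scale)` or `c(meanlog, sdlog)`.
#' @return A `param_spec` object.
#' @export
param_spec <- function(name, base, low = NULL, high = NULL,
                       dist = c("beta", "gamma", "lognormal", "fixed"),
                       dist_params = NULL) {
  dist <- match.arg(dist)
  if (is.null(low)) low <- base * 0.75
  if (is.null(high)) high <- base * 1.25
  stopifnot(low <= base, base <= high)
  if (is.null(dist_params) && dist != "fixed") {
    dist_params <- switch(dist,
      beta = derive_beta(base, low, high),
      gamma = derive_gamma(base, low, high),
      lognormal = derive_lognormal(base, low, high)
    )
  }
  structure(list(name = name, base = base, low = low, high = high,
                 dist = dist, dist_params = dist_params),
            class = "param_spec")
}

draw_spec <- function(spec, n) {
  dp <- spec$dist_params
  switch(spec$dist,
    fixed = rep(spec$base, n),
    beta = stats::rbeta(n, dp[["alpha"]], dp[["beta"]]),
    gamma = stats::rgamma(n, shape = dp[["shape"]], scale = dp[["scale"]]),
    lognormal = stats::rlnorm(n, dp[["meanlog"]], dp[["sdlog"]])
  )
}

#' Default sensitivity-analysis specification set
#'
#' Builds the [param_spec()] list matching the published input table for
#' a fixture configuration: beta for proportions and utilities, gamma for
#' costs, log-normal for the hazard ratios, fixed for the first-line
#' intervention drug price (varied only in one-way analysis, over half to
#' full price).
#'
#' @param raw Raw configuration (see [make_fixture_config()]).
#' @return List of `param_spec` objects.
#' @export
default_param_specs <- function(raw) {
  hr <- raw$hr
  cst <- raw$costs
  list(
    param_spec("hr_pfs", hr$pfs[["est"]], hr$pfs[["low"]],
               hr$pfs[["high"]], dist = "lognormal"),
    param_spec("hr_os", hr$os[["est"]], hr$os[["low"]], hr$os[["high"]],
               dist = "lognormal"),
    param_spec("u_pfd", 0.76, 0.65, 0.87, dist = "beta"),
    param_spec("u_pd", 0.37, 0.33, 0.41, dist = "beta"),
    param_spec("p_subsequent_soc", raw$p_subsequent$soc, 0.476, 0.793,
               dist = "beta",
               dist_params = c(alpha = 5.9, beta = 3.4)),
    param_spec("p_subsequent_olaparib", raw$p_subsequent$olaparib,
               0.264, 0.44, dist = "beta",
               dist_params = c(alpha = 10.4, beta = 19.1)),
    param_spec("cost_olaparib_day", cst$olaparib_day,
               cst$olaparib_day / 2, cst$olaparib_day, dist = "fixed"),
    param_spec("cost_enzalutamide_week", cst$enzalutamide_week,
               2304, 2814, dist = "gamma",
               dist_params = c(shape = 50176, scale = 0.051)),
    param_spec("cost_abiraterone_week", cst$abiraterone_week,
               2156, 2634, dist = "gamma",
               dist_params = c(shape = 46961, scale = 0.051)),
    param_spec("cost_supportive_day", cst$supportive_day, 142, 237,
               dist = "gamma"),
    param_spec("cost_terminal", cst$terminal, 27117, 45689,
               dist = "gamma",
               dist_params = c(shape = 142757, scale = 0.255)),
    param_spec("cost_followup_week", cst$followup_week, 109, 182,
               dist = "gamma"),
    param_spec("ngs_test_cost", raw$ngs$test_cost, NULL, NULL,
               dist = "gamma")
  )
}

run_outcome <- function(model, outcome) {
  r <- run_model(model)$result
  switch(outcome, inhb = r$inhb, icer = r$icer, inmb = r$inmb)
}

#' One-way (tornado) sensitivity analysis
#'
#' Re-runs the model with each parameter at its low and high bound, all
#' others held at base, and reports the outcome span per parameter sorted
#' by magnitude (the tornado ordering).
#'
#' @param model A [ce_model()].
#' @param specs List of [param_spec()] objects.
#' @param outcome `"inhb"` (default) or `"icer"`.
#' @return Data frame `parameter, low, high, outcome_base, outcome_low,
#'   outcome_high, span`, sorted by `abs(span)` descending. A parameter
#'   whose extreme run fails is kept as a row of `NA`s.
#' @export
one_way <- function(model, specs, outcome = c("inhb", "icer")) {
  outcome <- match.arg(outcome)
  stopifnot(length(specs) > 0)
  base_val <- run_outcome(model, outcome)
  rows <- lapply(specs, function(sp) {
    vals <- vapply(c(sp$low, sp$high), function(v) {
      out <- try(run_outcome(apply_param(model, sp$name, v), outcome),
                 silent = TRUE)
      if (inherits(out, "try-error") || length(out) != 1) NA_real_
      else out
    }, numeric(1))
    data.frame(parameter = sp$name, low = sp$low, high = sp$high,
               outcome_base = base_val, outcome_low = vals[1],
               outcome_high = vals[2],
               span = abs(vals[2] - vals[1]))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$span, out$parameter), ]
  rownames(out) <- NULL
  out
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo simulation: all specified parameters are drawn jointly and
#' independently from their distributions, the model is re-run per
#' iteration, and per-iteration incremental results are returned. Draws
#' outside a parameter's valid support (e.g. a utility above 1) are
#' redrawn; the redraw count is recorded.
#'
#' @param model A [ce_model()].
#' @param specs List of [param_spec()] objects.
#' @param n_iter Number of iterations (default 10000).
#' @param seed Integer seed; all randomness flows from it.
#' @return A data frame of class `psa_samples` with columns `iteration`,
#'   `delta_cost`, `delta_effect`, `inhb`, `inmb`. Attributes: `draws`
#'   (the parameter draw matrix), `seed`, `redraws`, `wtp`.
#' @export
psa <- function(model, specs, n_iter = 10000, seed) {
  stopifnot(length(specs) > 0, n_iter >= 1)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  nm <- vapply(specs, `[[`, character(1), "name")
  draws <- matrix(NA_real_, n_iter, length(specs),
                  dimnames = list(NULL, nm))
  redraws <- 0L
  for (j in seq_along(specs)) {
    x <- draw_spec(specs[[j]], n_iter)
    bad <- invalid_draws(nm[j], x)
    while (any(bad)) {
      redraws <- redraws + sum(bad)
      x[bad] <- draw_spec(specs[[j]], sum(bad))
      bad <- invalid_draws(nm[j], x)
    }
    draws[, j] <- x
  }
  wtp <- model$settings$wtp
  dc <- de <- numeric(n_iter)
  for (i in seq_len(n_iter)) {
    m <- model
    for (j in seq_along(specs)) m <- apply_param(m, nm[j], draws[i, j])
    r <- run_model(m)$result
    dc[i] <- r$delta_cost
    de[i] <- r$delta_effect
  }
  out <- data.frame(iteration = seq_len(n_iter), delta_cost = dc,
                    delta_effect = de, inhb = de - dc / wtp,
                    inmb = de * wtp - dc)
  class(out) <- c("psa_samples", "data.frame")
  attr(out, "draws") <- draws
  attr(out, "seed") <- seed
  attr(out, "redraws") <- redraws
  attr(out, "wtp") <- wtp
  out
}

invalid_draws <- function(name, x) {
  if (startsWith(name, "u_") || startsWith(name, "p_") ||
      startsWith(name, "disutility")) {
    x < 0 | x > 1
  } else if (name == "ngs_prevalence") {
    x <= 0 | x > 1
  } else {
    x < 0
  }
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA iterations in
#' which the intervention has positive incremental net monetary benefit.
#'
#' @param samples A `psa_samples` data frame from [psa()].
#' @param wtp_grid Vector of willingness-to-pay values (default $0 to
#'   $300,000 in $5,000 steps).
#' @return Data frame `wtp, prob_ce`.
#' @export
ceac <- function(samples, wtp_grid = seq(0, 300000, by = 5000)) {
  stopifnot(nrow(samples) > 0)
  if (length(wtp_grid) == 0) stop("`wtp_grid` is empty", call. = FALSE)
  prob <- vapply(wtp_grid, function(l) {
    mean(samples$delta_effect * l - samples$delta_cost > 0)
  }, numeric(1))
  data.frame(wtp = wtp_grid, prob_ce = prob)
}

#' Subgroup analysis by PFS hazard ratio
#'
#' Deterministic incremental net health benefit at the subgroup's PFS
#' hazard-ratio point estimate and confidence limits, plus a PSA-based
#' probability of cost-effectiveness at the configured threshold with
#' the PFS hazard ratio resampled from the subgroup's distribution (all
#' other parameters resampled from `specs`).
#'
#' @param model A [ce_model()].
#' @param hr_pfs_point Subgroup PFS hazard-ratio point estimate.
#' @param hr_pfs_range Length-2 vector `c(low, high)`.
#' @param specs Specs for the other parameters; defaults to
#'   [default_param_specs()] with the PFS hazard ratio replaced.
#' @param n_iter PSA iterations (default 1000).
#' @param seed Integer seed.
#' @return List with `inhb_point`, `inhb_range` (at the HR limits; note a
#'   lower HR gives the higher INHB), and `prob_ce`.
#' @export
subgroup <- function(model, hr_pfs_point, hr_pfs_range, specs = NULL,
                     n_iter = 1000, seed) {
  stopifnot(length(hr_pfs_range) == 2,
            hr_pfs_range[1] <= hr_pfs_point,
            hr_pfs_point <= hr_pfs_range[2])
  at_hr <- function(v) run_outcome(apply_param(model, "hr_pfs", v), "inhb")
  inhb_point <- at_hr(hr_pfs_point)
  inhb_range <- c(at_hr(hr_pfs_range[2]), at_hr(hr_pfs_range[1]))
  if (is.null(specs)) specs <- default_param_specs(model$raw)
  nm <- vapply(specs, `[[`, character(1), "name")
  hr_spec <- param_spec("hr_pfs", hr_pfs_point, hr_pfs_range[1],
                        hr_pfs_range[2], dist = "lognormal")
  specs <- c(list(hr_spec), specs[nm != "hr_pfs"])
  s <- psa(model, specs, n_iter = n_iter, seed = seed)
  list(inhb_point = inhb_point,
       inhb_range = sort(inhb_range),
       prob_ce = mean(s$inmb > 0))
}

#' Export PSA or tornado results with a run sidecar
#'
#' Writes the table as CSV plus a JSON sidecar recording the seed and a
#' hash of the configuration, so runs are traceable.
#'
#' @param x Data frame to export.
#' @param path CSV output path.
#' @param seed Seed used (or `NA`).
#' @param config_hash Configuration hash from [config_hash()] (or `NA`).
#' @export
write_analysis_csv <- function(x, path, seed = NA, config_hash = NA) {
  utils::write.csv(x, path, row.names = FALSE)
  jsonlite::write_json(
    list(seed = seed, config_hash = config_hash,
         rows = nrow(x), written = format(Sys.time(), tz = "UTC")),
    paste0(path, ".json"), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Hash of a model configuration
#'
#' MD5 of the canonical JSON serialization; changes iff the configuration
#' changes.
#'
#' @param raw Raw configuration list.
#' @return Character MD5 hash.
#' @export
config_hash <- function(raw) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_model_config(raw, tmp)
  unname(tools::md5sum(tmp))
}
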