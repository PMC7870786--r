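#' Maximum-likelihood fitting of parametric survival models
#'
#' Fits a parametric family to right-censored time-to-event data by
#' maximizing the usual censored log-likelihood
#' `sum(events) log f(t_i) + sum(censored) log S(t_i)`.
#' Optimization runs on unconstrained transforms (log for positive
#' parameters, logit for the cure fraction) with a deterministic
#' multi-start ladder to guard against the multimodality cure models are
#' prone to.
#'
#' @param family One of [surv_families()].
#' @param ipd A data frame with columns `time` (> 0) and `event`
#'   (1 = event, 0 = censored), e.g. from [reconstruct_ipd()] or
#'   [simulate_ipd()].
#' @param init Optional named vector of starting values on the natural
#'   scale; defaults are derived from the data.
#' @param base_family Base family for cure models (default `"weibull"`).
#' @param knots Knots on the log-time scale for `rp_spline`; default is
#'   boundary knots at the extreme uncensored log times plus internal
#'   knots at the 33rd/67th centiles of uncensored log event times.
#' @param n_starts Number of multi-start offsets (default 5).
#' @param time_unit Time unit recorded on the fitted distribution.
#' @return A `fit_result` object: list with `distribution` (a
#'   [surv_dist()]), `loglik`, `n_params`, `aic = 2*n_params - 2*loglik`,
#'   and `converged`.
#' @examples
#' set.seed(1)
#' t <- rexp(300, 0.2); c <- runif(300, 0, 12)
#' ipd <- data.frame(time = pmin(t, c), event = as.integer(t <= c))
#' fit_mle("exponential", ipd)
#' @export
fit_mle <- function(family, ipd, init = NULL, base_family = "weibull",
                    knots = NULL, n_starts = 5,
                    time_unit = c("months", "weeks")) {
  family <- match.arg(family, surv_families())
  time_unit <- match.arg(time_unit)
  check_ipd(ipd)
  if (sum(ipd$event) < 1) {
    stop("no events in `ipd`: model is not identifiable", call. = FALSE)
  }
  time <- ipd$time
  event <- ipd$event
  if (family == "rp_spline" && is.null(knots)) {
    knots <- default_rp_knots(time, event)
  }
  spec <- family_fit_spec(family, time, event, base_family, knots)
  start <- if (is.null(init)) spec$init else {
    stopifnot(all(spec$names %in% names(init)))
    unname(init[spec$names])
  }
  nll <- function(par_t) {
    par <- spec$untransform(par_t)
    d <- try(suppressWarnings(
      surv_dist(family, stats::setNames(par, spec$names),
                time_unit = time_unit, knots = knots,
                base_family = if (spec$is_cure) base_family else NULL)
    ), silent = TRUE)
    if (inherits(d, "try-error")) return(1e10)
    f <- suppressWarnings(density_at(d, time))
    s <- suppressWarnings(survival_at(d, time))
    f[is.na(f)] <- 0
    s[is.na(s)] <- 0
    ll <- sum(ifelse(event == 1, log(pmax(f, 1e-300)),
                     log(pmax(s, 1e-300))))
    if (!is.finite(ll)) 1e10 else -ll
  }

  # deterministic multi-start: additive offsets on the transformed scale
  offsets <- c(0, -0.5, 0.5, -1, 1, -2, 2)[seq_len(max(1, n_starts))]
  best <- NULL
  start_t <- spec$transform(start)
  for (off in offsets) {
    o <- try(stats::optim(start_t + off, nll, method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-10)),
             silent = TRUE)
    if (inherits(o, "try-error")) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) {
    stop("optimization failed for every start", call. = FALSE)
  }
  par <- spec$untransform(best$par)
  dist <- surv_dist(family, stats::setNames(par, spec$names),
                    time_unit = time_unit, knots = knots,
                    base_family = if (spec$is_cure) base_family else NULL)
  loglik <- -best$value
  k <- length(par)
  structure(
    list(distribution = dist, loglik = loglik, n_params = k,
         aic = 2 * k - 2 * loglik,
         converged = best$convergence == 0 && is.finite(loglik) &&
           best$value < 1e9),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s: loglik %.3f, k = %d, AIC %.3f, %s\n",
              x$distribution$family, x$loglik, x$n_params, x$aic,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

check_ipd <- function(ipd) {
  if (!is.data.frame(ipd) || !all(c("time", "event") %in% names(ipd))) {
    stop("`ipd` must be a data frame with columns time and event",
         call. = FALSE)
  }
  if (nrow(ipd) == 0) stop("`ipd` is empty", call. = FALSE)
  if (any(ipd$time < 0)) stop("`ipd$time` must be >= 0", call. = FALSE)
  if (!all(ipd$event %in% c(0, 1))) {
    stop("`ipd$event` must be 0/1", call. = FALSE)
  }
  invisible(ipd)
}

default_rp_knots <- function(time, event) {
  lt <- log(time[event == 1 & time > 0])
  if (length(unique(lt)) < 4) {
    stop("too few distinct event times to place spline knots", call. = FALSE)
  }
  as.numeric(c(min(lt),
               stats::quantile(lt, c(1 / 3, 2 / 3), names = FALSE),
               max(lt)))
}

# per-family fit specification: parameter names, transform pair and a
# moment-style initializer from the observed data
family_fit_spec <- function(family, time, event, base_family, knots) {
  tpos <- pmax(time, min(time[time > 0]) / 2)
  mean_t <- mean(tpos)
  rate0 <- sum(event) / sum(time)
  med0 <- stats::median(tpos)
  is_cure <- family %in% c("mixture_cure", "nonmixture_cure")
  base <- if (is_cure) base_family else family
  b <- switch(base,
    exponential = list(names = "rate", init = rate0, tf = "log"),
    weibull = list(names = c("shape", "scale"), init = c(1, 1 / rate0),
                   tf = c("log", "log")),
    gamma = list(names = c("shape", "rate"), init = c(1, rate0),
                 tf = c("log", "log")),
    lognormal = list(names = c("meanlog", "sdlog"),
                     init = c(mean(log(tpos)), stats::sd(log(tpos))),
                     tf = c("id", "log")),
    loglogistic = list(names = c("shape", "scale"), init = c(1, med0),
                       tf = c("log", "log")),
    gompertz = list(names = c("shape", "rate"), init = c(0.001, rate0),
                    tf = c("id", "log")),
    generalized_gamma = list(
      names = c("mu", "sigma", "Q"),
      init = c(mean(log(tpos)), max(stats::sd(log(tpos)), 0.2), 0.5),
      tf = c("id", "log", "id")),
    rp_spline = {
      K <- length(knots)
      list(names = paste0("gamma", 0:(K - 1)),
           init = c(log(rate0), 1, rep(0, K - 2)),
           tf = rep("id", K))
    },
    stop("unsupported family: ", base)
  )
  if (is_cure) {
    b$names <- c("theta", b$names)
    b$init <- c(0.1, b$init)
    b$tf <- c("logit", b$tf)
  }
  tf <- b$tf
  list(
    names = b$names,
    init = b$init,
    is_cure = is_cure,
    transform = function(x) {
      ifelse(tf == "log", log(x),
             ifelse(tf == "logit", stats::qlogis(pmin(pmax(x, 1e-6),
                                                      1 - 1e-6)), x))
    },
    untransform = function(x) {
      ifelse(tf == "log", exp(x),
             ifelse(tf == "logit", stats::plogis(x), x))
    }
  )
}

#' Select the best fit by AIC
#'
#' Returns the converged fit with the lowest AIC. Ties are broken in
#' favour of fewer parameters, then by position in the input list.
#'
#' @param fits A list of `fit_result` objects from [fit_mle()].
#' @return The selected `fit_result`.
#' @export
select_best <- function(fits) {
  if (length(fits) == 0) stop("no fits supplied", call. = FALSE)
  stopifnot(all(vapply(fits, inherits, logical(1), "fit_result")))
  conv <- Filter(function(f) isTRUE(f$converged), fits)
  if (length(conv) == 0) stop("no converged fits to select from",
                              call. = FALSE)
  aic <- vapply(conv, `[[`, numeric(1), "aic")
  k <- vapply(conv, `[[`, numeric(1), "n_params")
  ord <- order(aic, k, seq_along(conv))
  conv[[ord[1]]]
}

#' Fit several families and pick the AIC-best one
#'
#' Convenience wrapper running [fit_mle()] for each requested family and
#' selecting with [select_best()]. Families whose optimization errors out
#' are dropped with a warning.
#'
#' @inheritParams fit_mle
#' @param families Character vector of families to try.
#' @return List with `best` (a `fit_result`) and `fits` (all results).
#' @export
fit_and_select <- function(ipd, families = c("exponential", "weibull",
                                             "gamma", "lognormal",
                                             "loglogistic", "gompertz"),
                           ...) {
  fits <- list()
  for (fam in families) {
    f <- try(fit_mle(fam, ipd, ...), silent = TRUE)
    if (inherits(f, "try-error")) {
      warning("fit failed for family ", fam, call. = FALSE)
      next
    }
    fits[[fam]] <- f
  }
  list(best = select_best(fits), fits = fits)
}

#' Read or write individual-patient data CSV
#'
#' The package's IPD exchange format: CSV with columns `time`, `event`
#' (1 = event, 0 = censored) and optionally `arm`.
#'
#' @param ipd Data frame with `time`/`event` (and optionally `arm`).
#' @param path CSV file path.
#' @return `read_ipd()` returns the data frame; `write_ipd()` returns
#'   `path` invisibly.
#' @export
write_ipd <- function(ipd, path) {
  check_ipd(ipd)
  utils::write.csv(ipd, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ipd
#' @export
read_ipd <- function(path) {
  ipd <- utils::read.csv(path)
  check_ipd(ipd)
  ipd
}
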