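#' Digitized Kaplan-Meier curve container
#'
#' Bundles digitized curve coordinates with the published numbers-at-risk
#' table, the inputs required by [reconstruct_ipd()].
#'
#' @param points Data frame with columns `time` and `survival`; must start
#'   at (0, 1), with survival non-increasing in \[0, 1\].
#' @param risk_table Data frame with columns `time` and `n_risk`;
#'   `n_risk` non-increasing, first entry is the arm size. If `NULL`,
#'   reconstruction assumes administrative censoring only at the end of
#'   follow-up (a warning is issued).
#' @param total_events Optional integer: the published total event count,
#'   used to rescale reconstructed event counts.
#' @return A `digitized_km` object.
#' @export
digitized_km <- function(points, risk_table = NULL, total_events = NULL) {
  stopifnot(is.data.frame(points),
            all(c("time", "survival") %in% names(points)))
  points <- points[order(points$time), c("time", "survival")]
  if (points$time[1] != 0 || abs(points$survival[1] - 1) > 1e-9) {
    stop("digitized curve must start at (time = 0, survival = 1)",
         call. = FALSE)
  }
  if (any(points$survival < -1e-9 | points$survival > 1 + 1e-9)) {
    stop("survival probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (is.unsorted(rev(points$survival))) {
    stop("survival probabilities must be non-increasing in time",
         call. = FALSE)
  }
  if (!is.null(risk_table)) {
    stopifnot(is.data.frame(risk_table),
              all(c("time", "n_risk") %in% names(risk_table)))
    risk_table <- risk_table[order(risk_table$time), c("time", "n_risk")]
    if (is.unsorted(rev(risk_table$n_risk))) {
      stop("numbers at risk must be non-increasing", call. = FALSE)
    }
    if (any(risk_table$n_risk < 0)) {
      stop("numbers at risk must be non-negative", call. = FALSE)
    }
  }
  structure(list(points = points, risk_table = risk_table,
                 total_events = total_events),
            class = "digitized_km")
}

#' @export
print.digitized_km <- function(x, ...) {
  cat(sprintf("<digitized_km> %d curve points over [0, %g]",
              nrow(x$points), max(x$points$time)))
  if (!is.null(x$risk_table)) {
    cat(sprintf("; risk table with %d entries (n0 = %d)",
                nrow(x$risk_table), x$risk_table$n_risk[1]))
  }
  cat("\n")
  invisible(x)
}

#' Reconstruct pseudo individual-patient data from a digitized KM curve
#'
#' Implements the Guyot-style iterative algorithm: within each interval
#' between consecutive numbers-at-risk, the number of censored patients is
#' solved so that the reconstructed risk set matches the published one,
#' assuming censoring is spread uniformly across the interval; event
#' counts at each digitized step are then chosen to match the digitized
#' survival drops. Reconstructed event times sit at the digitized step
#' times and censor times are spaced evenly within intervals, so the
#' procedure is fully deterministic.
#'
#' @param km A [digitized_km()] object (with a risk table for best
#'   fidelity; without one, all censoring is assumed administrative at the
#'   last follow-up time).
#' @param n Arm size when no risk table is supplied.
#' @return A data frame of class `pseudo_ipd` with columns `time` and
#'   `event` (1 = event, 0 = censored), with as many rows as the initial
#'   number at risk.
#' @references Guyot et al. (2012), BMC Medical Research Methodology 12:9.
#' @export
reconstruct_ipd <- function(km, n = NULL) {
  stopifnot(inherits(km, "digitized_km"))
  pts <- km$points
  if (nrow(pts) < 2) stop("need at least two digitized points",
                          call. = FALSE)
  if (is.null(km$risk_table)) {
    if (is.null(n)) {
      stop("supply `n` when the digitized curve has no risk table",
           call. = FALSE)
    }
    warning("no risk table: assuming administrative censoring at the ",
            "final follow-up time only", call. = FALSE)
    risk <- data.frame(time = 0, n_risk = n)
  } else {
    risk <- km$risk_table
  }

  t_s <- pts$time
  s <- pts$survival
  n_t <- length(t_s)
  t_risk <- risk$time
  n_risk <- risk$n_risk
  n_int <- length(t_risk)

  # digitized index range [lower_i, upper_i] covered by risk interval i
  lower <- vapply(seq_len(n_int), function(i) {
    which(t_s >= t_risk[i])[1]
  }, integer(1))
  upper <- vapply(seq_len(n_int), function(i) {
    if (i < n_int) max(which(t_s < t_risk[i + 1])) else n_t
  }, integer(1))

  d <- integer(n_t)        # events at each digitized time
  cen <- integer(n_t)      # censorings allotted to each digitized gap
  n_hat <- integer(n_t + 1)
  n_hat[lower[1]] <- n_risk[1]
  km_hat <- numeric(n_t)
  last_surv <- 1
  last_idx <- 0

  solve_interval <- function(i, n_cen_i, d, cen, n_hat, km_hat,
                             last_surv, last_idx) {
    lo <- lower[i]; up <- upper[i]
    cen[lo:up] <- 0L
    if (n_cen_i > 0) {
      # censor times spread uniformly over the interval, then binned to
      # the digitized grid (attached to the following step time)
      t_end <- if (i < n_int) t_risk[i + 1] else max(t_s[up], t_risk[i])
      ct <- t_risk[i] + (seq_len(n_cen_i) - 0.5) / n_cen_i *
        (t_end - t_risk[i])
      bin <- findInterval(ct, t_s[lo:up], left.open = TRUE) + lo
      bin <- pmin(bin, up)
      tb <- tabulate(bin - lo + 1, nbins = up - lo + 1)
      cen[lo:up] <- tb
    }
    for (k in lo:up) {
      prev_s <- if (k == 1) 1 else last_surv
      if (n_hat[k] > 0 && prev_s > 0) {
        d[k] <- round(n_hat[k] * (1 - s[k] / prev_s))
        d[k] <- max(0L, min(d[k], n_hat[k]))
      } else {
        d[k] <- 0L
      }
      km_hat[k] <- if (n_hat[k] > 0) prev_s * (1 - d[k] / n_hat[k]) else prev_s
      last_surv <- km_hat[k]
      n_hat[k + 1] <- n_hat[k] - d[k] - cen[k]
      if (n_hat[k + 1] < 0) {
        # infeasible allotment; clamp and push the deficit forward
        cen[k] <- cen[k] + n_hat[k + 1]
        n_hat[k + 1] <- 0L
      }
    }
    list(d = d, cen = cen, n_hat = n_hat, km_hat = km_hat,
         last_surv = last_surv)
  }

  for (i in seq_len(n_int)) {
    lo <- lower[i]; up <- upper[i]
    if (i < n_int) {
      # initial guess for censorings in the interval from the KM identity
      s_lo <- if (lo == 1) 1 else s[lo - 1]
      guess <- round(n_hat[lo] * s[up] / max(s_lo, 1e-12)) - n_risk[i + 1]
      n_cen_i <- max(0L, as.integer(guess))
      repeat {
        res <- solve_interval(i, n_cen_i, d, cen, n_hat, km_hat,
                              last_surv, last_idx)
        mismatch <- res$n_hat[lower[i + 1]] - n_risk[i + 1]
        if (mismatch == 0 || (mismatch < 0 && n_cen_i == 0)) break
        n_cen_i <- n_cen_i + mismatch
        if (n_cen_i < 0) n_cen_i <- 0L
        if (n_cen_i > n_hat[lo]) { n_cen_i <- n_hat[lo];
          res <- solve_interval(i, n_cen_i, d, cen, n_hat, km_hat,
                                last_surv, last_idx)
          break }
      }
    } else {
      # final interval: no later risk number to match; assume censoring
      # only at the end of follow-up
      res <- solve_interval(i, 0L, d, cen, n_hat, km_hat,
                            last_surv, last_idx)
    }
    d <- res$d; cen <- res$cen; n_hat <- res$n_hat
    km_hat <- res$km_hat; last_surv <- res$last_surv
  }

  # optional rescale of events to a published total (largest-drop first)
  if (!is.null(km$total_events)) {
    diff_ev <- km$total_events - sum(d)
    if (diff_ev != 0) {
      idx <- order(d, decreasing = diff_ev < 0)
      i <- 1
      while (diff_ev != 0 && i <= length(idx)) {
        k <- idx[i]
        step <- sign(diff_ev)
        if (d[k] + step >= 0) {
          d[k] <- d[k] + step
          diff_ev <- diff_ev - step
        }
        i <- if (i == length(idx)) 1 else i + 1
      }
    }
  }

  # remaining patients censored at end of follow-up
  n_end <- n_risk[1] - sum(d) - sum(cen)
  t_max <- max(t_s)

  times <- c(rep(t_s, d), censor_times(t_s, cen, t_risk, n_int, lower,
                                       upper),
             rep(t_max, max(0L, n_end)))
  events <- c(rep(1L, sum(d)), rep(0L, sum(cen) + max(0L, n_end)))
  out <- data.frame(time = times, event = events)
  out <- out[order(out$time, -out$event), ]
  rownames(out) <- NULL
  class(out) <- c("pseudo_ipd", "data.frame")
  attr(out, "n") <- n_risk[1]
  out
}

# reproduce the deterministic uniform censor-time placement used while
# solving, so the emitted records match the counts exactly
censor_times <- function(t_s, cen, t_risk, n_int, lower, upper) {
  out <- numeric(0)
  for (k in seq_along(cen)) {
    if (cen[k] == 0) next
    t_hi <- t_s[k]
    t_lo <- if (k == 1) 0 else t_s[k - 1]
    out <- c(out, t_lo + (seq_len(cen[k]) - 0.5) / cen[k] * (t_hi - t_lo))
  }
  out
}

#' Kaplan-Meier estimate of reconstructed or simulated IPD
#'
#' Thin wrapper around [survival::survfit()] returning a tidy step
#' function, used for round-trip fidelity checks.
#'
#' @param ipd Data frame with `time` and `event` columns.
#' @return Data frame with columns `time` and `survival` (step values
#'   immediately after each event time), including the (0, 1) origin.
#' @export
km_estimate <- function(ipd) {
  check_ipd(ipd)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = ipd)
  data.frame(time = c(0, fit$time), survival = c(1, fit$surv))
}

#' Evaluate a KM step function at arbitrary times
#'
#' @param km Data frame with `time` and `survival` columns (a step
#'   function, right-continuous).
#' @param t Times at which to evaluate.
#' @return Survival probabilities at `t`.
#' @export
km_at <- function(km, t) {
  idx <- findInterval(t, km$time)
  ifelse(idx == 0, 1, km$survival[pmax(idx, 1)])
}

#' Read a digitized KM curve from CSV files
#'
#' @param points_path CSV with columns `time,survival`.
#' @param risk_path Optional CSV with columns `time,n_risk`.
#' @param total_events Optional published event total.
#' @return A [digitized_km()] object.
#' @export
read_digitized_km <- function(points_path, risk_path = NULL,
                              total_events = NULL) {
  pts <- utils::read.csv(points_path)
  risk <- if (!is.null(risk_path)) utils::read.csv(risk_path) else NULL
  digitized_km(pts, risk, total_events)
}

#' @rdname read_digitized_km
#' @param km A [digitized_km()] object.
#' @param points_path,risk_path Output CSV paths.
#' @export
write_digitized_km <- function(km, points_path, risk_path = NULL) {
  stopifnot(inherits(km, "digitized_km"))
  utils::write.csv(km$points, points_path, row.names = FALSE)
  if (!is.null(risk_path) && !is.null(km$risk_table)) {
    utils::write.csv(km$risk_table, risk_path, row.names = FALSE)
  }
  invisible(points_path)
}
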