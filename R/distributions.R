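#' Parametric survival distributions
#'
#' A `surv_dist` object bundles a parametric survival family with its named
#' parameters and its time unit. It is the basic currency of the package:
#' fitted extrapolation models, strategy configurations and the synthetic
#' data generator all exchange `surv_dist` objects.
#'
#' Supported families and their parameters:
#' \describe{
#'   \item{exponential}{`rate` (> 0); constant hazard.}
#'   \item{weibull}{`shape`, `scale` (> 0), the [stats::pweibull()]
#'     convention. `rate = 1/scale` is accepted as an alias.}
#'   \item{gamma}{`shape`, `rate` (> 0), the [stats::pgamma()] convention.}
#'   \item{lognormal}{`meanlog`, `sdlog` (> 0).}
#'   \item{loglogistic}{`shape`, `scale` (> 0); survival
#'     `1 / (1 + (t/scale)^shape)`; the median equals `scale`.}
#'   \item{gompertz}{`shape` (any real), `rate` (> 0); hazard
#'     `rate * exp(shape * t)`. A negative shape yields a defective
#'     distribution with survivor plateau `exp(rate/shape)`.}
#'   \item{generalized_gamma}{`mu`, `sigma` (> 0), `Q` (any real), the
#'     stable (Prentice-style) log-time parameterization; `Q = 0` is
#'     log-normal, `Q = 1` is Weibull, `Q = sigma` is gamma.}
#'   \item{rp_spline}{Royston-Parmar flexible parametric model:
#'     `gamma0..gammaK` coefficients of a restricted cubic spline in
#'     log time modelling the log cumulative hazard. Requires `knots`
#'     (ordered, on the log-time scale, boundary knots included;
#'     `length(knots) == number of coefficients`).}
#'   \item{mixture_cure}{`theta` in \[0, 1\] plus the parameters of
#'     `base_family`; `S(t) = theta + (1 - theta) * S_base(t)`.}
#'   \item{nonmixture_cure}{`theta` in \[0, 1\] plus `base_family`
#'     parameters; `S(t) = theta^(1 - S_base(t))`.}
#' }
#'
#' @param family Character scalar, one of [surv_families()].
#' @param params Named numeric vector of parameters (see Details).
#' @param time_unit `"months"` (default) or `"weeks"`; purely descriptive
#'   metadata used by the engine when converting to model cycles.
#' @param knots Ordered numeric vector of knots on the log-time scale
#'   (`rp_spline` only).
#' @param base_family Base family for cure models (any non-cure family).
#' @param scale_on_log If `TRUE`, parameters named `scale` (and a cure
#'   model's base `scale`) are interpreted as natural logarithms of the
#'   time-scale value and exponentiated at construction. Published
#'   log-logistic/cure "scale" values are sometimes reported on the log
#'   scale without saying so; this switch makes both readings available.
#' @return An object of class `surv_dist`.
#' @examples
#' d <- surv_dist("gamma", c(shape = 2.1689, rate = 0.1485))
#' survival_at(d, c(0, 6, 12))
#' hazard_at(d, 6)
#' @export
surv_dist <- function(family, params, time_unit = c("months", "weeks"),
                      knots = NULL, base_family = NULL,
                      scale_on_log = FALSE) {
  family <- match.arg(family, surv_families())
  time_unit <- match.arg(time_unit)
  params <- unlist(params)
  if (is.null(names(params)) || any(!nzchar(names(params)))) {
    stop("`params` must be a fully named numeric vector", call. = FALSE)
  }
  storage.mode(params) <- "double"
  if (isTRUE(scale_on_log) && "scale" %in% names(params)) {
    params[["scale"]] <- exp(params[["scale"]])
  }
  if (family %in% c("mixture_cure", "nonmixture_cure")) {
    if (is.null(base_family)) {
      stop("cure models require `base_family`", call. = FALSE)
    }
    base_family <- match.arg(base_family, setdiff(
      surv_families(), c("mixture_cure", "nonmixture_cure", "rp_spline")
    ))
  } else if (!is.null(base_family)) {
    stop("`base_family` is only meaningful for cure models", call. = FALSE)
  }
  obj <- structure(
    list(family = family, params = params, time_unit = time_unit,
         knots = knots, base_family = base_family),
    class = "surv_dist"
  )
  validate_surv_dist(obj)
  obj
}

#' Supported survival families
#' @return Character vector of family names accepted by [surv_dist()].
#' @export
surv_families <- function() {
  c("exponential", "weibull", "gamma", "lognormal", "loglogistic",
    "gompertz", "generalized_gamma", "rp_spline",
    "mixture_cure", "nonmixture_cure")
}

# parameter-domain validation; kept strict so downstream engine code can
# assume a valid object
validate_surv_dist <- function(d) {
  p <- d$params
  need <- function(nms) {
    missing <- setdiff(nms, names(p))
    if (length(missing)) {
      stop(sprintf("%s family requires parameter(s): %s", d$family,
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  pos <- function(nms) {
    for (nm in intersect(nms, names(p))) {
      if (!is.finite(p[[nm]]) || p[[nm]] <= 0) {
        stop(sprintf("parameter `%s` must be finite and > 0 (got %s)",
                     nm, format(p[[nm]])), call. = FALSE)
      }
    }
  }
  base <- if (is.null(d$base_family)) d$family else d$base_family
  if (d$family %in% c("mixture_cure", "nonmixture_cure")) {
    need("theta")
    th <- p[["theta"]]
    if (!is.finite(th) || th < 0 || th > 1) {
      stop("cure fraction `theta` must lie in [0, 1]", call. = FALSE)
    }
  }
  switch(base,
    exponential = { need("rate"); pos("rate") },
    weibull = {
      if ("rate" %in% names(p) && !"scale" %in% names(p)) {
        # alias accepted at validation time; converted lazily in eval
        pos("rate")
      } else {
        need(c("shape", "scale")); pos(c("shape", "scale"))
      }
      pos("shape")
    },
    gamma = { need(c("shape", "rate")); pos(c("shape", "rate")) },
    lognormal = { need(c("meanlog", "sdlog")); pos("sdlog") },
    loglogistic = { need(c("shape", "scale")); pos(c("shape", "scale")) },
    gompertz = {
      need(c("shape", "rate")); pos("rate")
      if (!is.finite(p[["shape"]])) stop("gompertz `shape` must be finite",
                                         call. = FALSE)
    },
    generalized_gamma = { need(c("mu", "sigma", "Q")); pos("sigma") },
    rp_spline = {
      gam <- spline_coefs(p)
      if (length(gam) < 2) {
        stop("rp_spline needs at least gamma0 and gamma1", call. = FALSE)
      }
      if (is.null(d$knots)) stop("rp_spline requires `knots`", call. = FALSE)
      if (length(d$knots) != length(gam)) {
        stop(sprintf(
          "rp_spline with %d coefficients requires %d knots (boundary + internal), got %d",
          length(gam), length(gam), length(d$knots)), call. = FALSE)
      }
      if (is.unsorted(d$knots, strictly = TRUE)) {
        stop("rp_spline `knots` must be strictly increasing", call. = FALSE)
      }
    }
  )
  invisible(d)
}

spline_coefs <- function(params) {
  nm <- grep("^gamma[0-9]+$", names(params), value = TRUE)
  idx <- as.integer(sub("gamma", "", nm))
  unname(params[nm[order(idx)]])
}

#' @export
print.surv_dist <- function(x, ...) {
  fam <- x$family
  if (!is.null(x$base_family)) fam <- paste0(fam, "[", x$base_family, "]")
  cat(sprintf("<surv_dist> %s (%s)\n", fam, x$time_unit))
  print(x$params)
  if (!is.null(x$knots)) cat("knots (log time):",
                             paste(signif(x$knots, 4), collapse = ", "), "\n")
  invisible(x)
}

# restricted cubic spline basis of Royston & Parmar: for knots
# k1 < ... < kK (boundary included) the basis in x = log(t) is
# 1, x, v_1(x), ..., v_{K-2}(x) with
# v_j(x) = (x - k_{j+1})_+^3 - lam_j (x - k1)_+^3 - (1 - lam_j)(x - kK)_+^3
rcs_basis <- function(x, knots, deriv = FALSE) {
  K <- length(knots)
  kmin <- knots[1]; kmax <- knots[K]
  out <- matrix(0, length(x), K)
  if (deriv) {
    out[, 1] <- 0
    out[, 2] <- 1
  } else {
    out[, 1] <- 1
    out[, 2] <- x
  }
  if (K > 2) {
    cube <- function(u) ifelse(u > 0, u^3, 0)
    dcube <- function(u) ifelse(u > 0, 3 * u^2, 0)
    f <- if (deriv) dcube else cube
    for (j in seq_len(K - 2)) {
      kj <- knots[j + 1]
      lam <- (kmax - kj) / (kmax - kmin)
      out[, j + 2] <- f(x - kj) - lam * f(x - kmin) - (1 - lam) * f(x - kmax)
    }
  }
  out
}

# log cumulative hazard s(x) of an rp_spline model and its x-derivative
rp_logcumhaz <- function(d, t, deriv = FALSE) {
  gam <- spline_coefs(d$params)
  x <- log(t)
  drop(rcs_basis(x, d$knots, deriv = deriv) %*% gam)
}

weibull_scale <- function(p) {
  if ("scale" %in% names(p)) p[["scale"]] else 1 / p[["rate"]]
}

base_dist <- function(d) {
  surv_dist(d$base_family,
            d$params[setdiff(names(d$params), "theta")],
            time_unit = d$time_unit)
}

#' Survival function of a parametric model
#'
#' Evaluates `S(t)`, the probability of remaining event-free at time `t`,
#' for any supported family. Vectorized over `t`.
#'
#' @param dist A [surv_dist()] object.
#' @param t Numeric vector of non-negative times (in `dist$time_unit`).
#' @return Numeric vector of survival probabilities in \[0, 1\].
#' @seealso [hazard_at()], [quantile_at()]
#' @export
survival_at <- function(dist, t) {
  stopifnot(inherits(dist, "surv_dist"))
  if (any(!is.finite(t) & !is.infinite(t)) || any(t < 0, na.rm = TRUE)) {
    stop("`t` must be non-negative", call. = FALSE)
  }
  p <- dist$params
  s <- switch(dist$family,
    exponential = exp(-p[["rate"]] * t),
    weibull = stats::pweibull(t, p[["shape"]], weibull_scale(p),
                              lower.tail = FALSE),
    gamma = stats::pgamma(t, p[["shape"]], rate = p[["rate"]],
                          lower.tail = FALSE),
    lognormal = stats::plnorm(t, p[["meanlog"]], p[["sdlog"]],
                              lower.tail = FALSE),
    loglogistic = 1 / (1 + (t / p[["scale"]])^p[["shape"]]),
    gompertz = {
      a <- p[["shape"]]; b <- p[["rate"]]
      if (abs(a) < 1e-12) exp(-b * t) else exp(-b / a * (exp(a * t) - 1))
    },
    generalized_gamma = gengamma_surv(t, p[["mu"]], p[["sigma"]], p[["Q"]]),
    rp_spline = {
      out <- numeric(length(t))
      posi <- t > 0 & is.finite(t)
      out[t == 0] <- 1
      out[is.infinite(t)] <- 0
      out[posi] <- exp(-exp(rp_logcumhaz(dist, t[posi])))
      out
    },
    mixture_cure = {
      th <- p[["theta"]]
      th + (1 - th) * survival_at(base_dist(dist), t)
    },
    nonmixture_cure = {
      th <- p[["theta"]]
      sb <- survival_at(base_dist(dist), t)
      if (th == 0) ifelse(sb == 1, 1, 0) else th^(1 - sb)
    }
  )
  pmin(pmax(s, 0), 1)
}

gengamma_surv <- function(t, mu, sigma, Q) {
  out <- numeric(length(t))
  out[t == 0] <- 1
  out[is.infinite(t)] <- 0
  posi <- t > 0 & is.finite(t)
  tt <- t[posi]
  if (abs(Q) < 1e-9) {
    out[posi] <- stats::plnorm(tt, mu, sigma, lower.tail = FALSE)
  } else {
    w <- (log(tt) - mu) / sigma
    u <- exp(Q * w) / Q^2
    out[posi] <- if (Q > 0) {
      stats::pgamma(u, 1 / Q^2, lower.tail = FALSE)
    } else {
      stats::pgamma(u, 1 / Q^2, lower.tail = TRUE)
    }
  }
  out
}

gengamma_dens <- function(t, mu, sigma, Q) {
  if (abs(Q) < 1e-9) return(stats::dlnorm(t, mu, sigma))
  w <- (log(t) - mu) / sigma
  q2 <- 1 / Q^2
  exp(log(abs(Q)) + q2 * log(q2) + q2 * (Q * w - exp(Q * w)) -
        log(sigma) - log(t) - lgamma(q2))
}

#' Density function of a parametric survival model
#'
#' @inheritParams survival_at
#' @param t Numeric vector of positive times.
#' @return Numeric vector of density values `f(t)`.
#' @export
density_at <- function(dist, t) {
  stopifnot(inherits(dist, "surv_dist"))
  p <- dist$params
  switch(dist$family,
    exponential = stats::dexp(t, p[["rate"]]),
    weibull = stats::dweibull(t, p[["shape"]], weibull_scale(p)),
    gamma = stats::dgamma(t, p[["shape"]], rate = p[["rate"]]),
    lognormal = stats::dlnorm(t, p[["meanlog"]], p[["sdlog"]]),
    loglogistic = {
      a <- p[["shape"]]; s <- p[["scale"]]
      (a / s) * (t / s)^(a - 1) / (1 + (t / s)^a)^2
    },
    gompertz = {
      a <- p[["shape"]]; b <- p[["rate"]]
      b * exp(a * t) * survival_at(dist, t)
    },
    generalized_gamma = gengamma_dens(t, p[["mu"]], p[["sigma"]], p[["Q"]]),
    rp_spline = {
      s <- rp_logcumhaz(dist, t)
      ds <- rp_logcumhaz(dist, t, deriv = TRUE)
      pmax(ds / t * exp(s), 0) * exp(-exp(s))
    },
    mixture_cure = (1 - p[["theta"]]) * density_at(base_dist(dist), t),
    nonmixture_cure = {
      th <- p[["theta"]]
      if (th == 0) return(density_at(base_dist(dist), t))
      -log(th) * density_at(base_dist(dist), t) * survival_at(dist, t)
    }
  )
}

#' Hazard function of a parametric survival model
#'
#' Returns `h(t) = f(t) / S(t)`. Consistent with [survival_at()] through
#' `S(t) = exp(-integral of h)`.
#'
#' @inheritParams survival_at
#' @param t Numeric vector of strictly positive times with `S(t) > 0`.
#' @return Numeric vector of hazard rates.
#' @export
hazard_at <- function(dist, t) {
  stopifnot(inherits(dist, "surv_dist"))
  if (any(t <= 0)) stop("hazard is defined for t > 0", call. = FALSE)
  s <- survival_at(dist, t)
  if (any(s == 0)) {
    stop("hazard undefined where S(t) = 0", call. = FALSE)
  }
  density_at(dist, t) / s
}

#' Quantile (inverse survival) function
#'
#' Solves `S(t) = s` for `t`. For defective distributions (cure models,
#' negative-shape Gompertz) the result is `Inf` when `s` is below the
#' survivor plateau. Used by the synthetic-data generator for
#' inverse-transform sampling.
#'
#' @inheritParams survival_at
#' @param s Numeric vector of target survival probabilities in (0, 1\].
#' @return Numeric vector of times.
#' @export
quantile_at <- function(dist, s) {
  stopifnot(inherits(dist, "surv_dist"))
  if (any(s <= 0 | s > 1)) stop("`s` must lie in (0, 1]", call. = FALSE)
  p <- dist$params
  switch(dist$family,
    exponential = -log(s) / p[["rate"]],
    weibull = stats::qweibull(s, p[["shape"]], weibull_scale(p),
                              lower.tail = FALSE),
    gamma = stats::qgamma(s, p[["shape"]], rate = p[["rate"]],
                          lower.tail = FALSE),
    lognormal = stats::qlnorm(s, p[["meanlog"]], p[["sdlog"]],
                              lower.tail = FALSE),
    loglogistic = p[["scale"]] * (1 / s - 1)^(1 / p[["shape"]]),
    gompertz = {
      a <- p[["shape"]]; b <- p[["rate"]]
      if (abs(a) < 1e-12) {
        -log(s) / b
      } else {
        arg <- 1 - a * log(s) / b
        ifelse(arg <= 0, Inf, log(arg) / a)
      }
    },
    mixture_cure = {
      th <- p[["theta"]]
      ifelse(s <= th, Inf,
             quantile_at(base_dist(dist), pmin((s - th) / (1 - th), 1)))
    },
    nonmixture_cure = {
      th <- p[["theta"]]
      if (th == 0) return(quantile_at(base_dist(dist), s))
      sb <- 1 - log(s) / log(th)
      ifelse(sb <= 0, Inf, quantile_at(base_dist(dist), pmin(sb, 1)))
    },
    # generalized gamma / rp_spline: numeric inversion
    vapply(s, function(si) invert_survival(dist, si), numeric(1))
  )
}

invert_survival <- function(dist, s, upper0 = 1) {
  if (s >= 1) return(0)
  upper <- upper0
  while (survival_at(dist, upper) > s && upper < 1e8) upper <- upper * 2
  if (survival_at(dist, upper) > s) return(Inf)
  stats::uniroot(function(t) survival_at(dist, t) - s,
                 lower = 0, upper = upper, tol = 1e-10)$root
}

#' Serialize / deserialize a fitted survival model
#'
#' Models are exchanged as JSON objects
#' `{family, params, time_unit, knots, base_family}`.
#'
#' @param dist A [surv_dist()] object.
#' @param path File path to write to / read from.
#' @return `read_surv_dist()` returns a [surv_dist()]; `write_surv_dist()`
#'   returns `path` invisibly.
#' @export
write_surv_dist <- function(dist, path) {
  stopifnot(inherits(dist, "surv_dist"))
  jsonlite::write_json(
    list(family = dist$family, params = as.list(dist$params),
         time_unit = dist$time_unit, knots = dist$knots,
         base_family = dist$base_family),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' @rdname write_surv_dist
#' @export
read_surv_dist <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  surv_dist(x$family, unlist(x$params), time_unit = x$time_unit,
            knots = x$knots, base_family = x$base_family)
}
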