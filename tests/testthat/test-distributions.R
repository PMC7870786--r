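test_that("every family has S(0) = 1 and non-increasing S on a grid", {
  grid <- seq(0, 60, length.out = 1000)
  for (fam in surv_families()) {
    d <- make_family_dist(fam)
    s <- survival_at(d, grid)
    expect_equal(s[1], 1, info = fam)
    expect_true(all(s >= 0 & s <= 1), info = fam)
    expect_false(is.unsorted(rev(s)), info = fam)
  }
})

test_that("mixture cure survival tends to the cure fraction", {
  d <- surv_dist("mixture_cure",
                 c(theta = 0.097, shape = 2.383, scale = 2.889),
                 base_family = "loglogistic")
  expect_equal(survival_at(d, 1e9), 0.097, tolerance = 1e-8)
  expect_equal(survival_at(d, 0), 1)
})

test_that("gamma survival matches quadrature of the density", {
  # independent oracle: numerical integration of dgamma over [t, Inf)
  d <- surv_dist("gamma", c(shape = 2.1689, rate = 0.1485))
  oracle <- stats::integrate(function(u) stats::dgamma(u, 2.1689,
                                                       rate = 0.1485),
                             12, Inf, rel.tol = 1e-12)$value
  expect_equal(survival_at(d, 12), oracle, tolerance = 1e-8)
})

test_that("hazards reduce to closed forms where they exist", {
  t <- c(0.5, 2, 7, 20)
  expect_equal(hazard_at(surv_dist("exponential", c(rate = 0.31)), t),
               rep(0.31, 4))
  expect_equal(hazard_at(surv_dist("weibull", c(shape = 1, scale = 4)), t),
               rep(0.25, 4))
  g <- surv_dist("gompertz", c(shape = 0.07, rate = 0.02))
  expect_equal(hazard_at(g, t), 0.02 * exp(0.07 * t))
})

test_that("gompertz hazard agrees with finite differences of -log S", {
  # oracle: central difference of the cumulative hazard
  g <- surv_dist("gompertz", c(shape = 0.06804, rate = 0.01423))
  h <- 1e-5
  for (t in c(1, 6, 18, 30)) {
    fd <- (-log(survival_at(g, t + h)) + log(survival_at(g, t - h))) /
      (2 * h)
    expect_equal(hazard_at(g, t), fd, tolerance = 1e-6)
  }
})

test_that("survival and hazard are mutually consistent across families", {
  # S(t) must equal exp(-integral of h) for every family
  set.seed(11)
  jitter_params <- function(p) p * exp(stats::runif(length(p), -0.2, 0.2))
  for (fam in surv_families()) {
    spec <- family_param_table()[[fam]]
    for (r in 1:3) {
      p <- spec$params
      # keep theta in (0,1), jitter the rest multiplicatively
      p[names(p) != "theta"] <- jitter_params(p[names(p) != "theta"])
      d <- try(surv_dist(fam, p, knots = spec$knots,
                         base_family = spec$base_family), silent = TRUE)
      if (inherits(d, "try-error")) next
      for (t in c(3, 12)) {
        ch <- stats::integrate(function(u) hazard_at(d, u), 1e-9, t,
                               rel.tol = 1e-10, subdivisions = 500L)$value
        expect_equal(survival_at(d, t), exp(-ch), tolerance = 1e-6,
                     info = paste(fam, "rep", r, "t", t))
      }
    }
  }
})

test_that("quantile_at inverts survival_at, including defective tails", {
  for (fam in setdiff(surv_families(), "rp_spline")) {
    d <- make_family_dist(fam)
    for (s in c(0.9, 0.5, 0.25)) {
      t <- quantile_at(d, s)
      if (is.finite(t)) {
        expect_equal(survival_at(d, t), s, tolerance = 1e-7, info = fam)
      }
    }
  }
  cure <- make_family_dist("mixture_cure")
  expect_identical(quantile_at(cure, 0.1), Inf)  # below the 0.15 plateau
})

test_that("invalid parameters and domains are rejected", {
  expect_error(surv_dist("gamma", c(shape = -1, rate = 0.1)), "> 0")
  expect_error(surv_dist("exponential", c(rate = 0)), "> 0")
  expect_error(surv_dist("mixture_cure", c(theta = 1.2, rate = 0.1),
                         base_family = "exponential"), "theta")
  expect_error(surv_dist("mixture_cure", c(theta = 0.5, rate = 0.1)),
               "base_family")
  expect_error(surv_dist("rp_spline", c(gamma0 = 1, gamma1 = 1)),
               "knots")
  expect_error(surv_dist("rp_spline",
                         c(gamma0 = 1, gamma1 = 1, gamma2 = 0.1),
                         knots = log(c(2, 8))), "knots")
  d <- surv_dist("exponential", c(rate = 0.2))
  expect_error(survival_at(d, -1), "non-negative")
  expect_error(hazard_at(d, 0), "t > 0")
})

test_that("scale_on_log reinterprets scale parameters", {
  d_nat <- surv_dist("loglogistic", c(shape = 2.383, scale = exp(2.889)))
  d_log <- surv_dist("loglogistic", c(shape = 2.383, scale = 2.889),
                     scale_on_log = TRUE)
  expect_equal(survival_at(d_log, c(5, 18)), survival_at(d_nat, c(5, 18)))
})

test_that("fitted-model JSON serialization round-trips", {
  d <- surv_dist("rp_spline",
                 c(gamma0 = -2.2, gamma1 = 1.4, gamma2 = 0.05,
                   gamma3 = 0.02),
                 knots = log(c(2, 5, 9, 18)))
  path <- withr::local_tempfile(fileext = ".json")
  write_surv_dist(d, path)
  d2 <- read_surv_dist(path)
  expect_equal(d2$family, d$family)
  expect_equal(d2$params, d$params)
  expect_equal(d2$knots, d$knots)
  t <- c(1, 6, 24)
  expect_equal(survival_at(d2, t), survival_at(d, t))
})
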