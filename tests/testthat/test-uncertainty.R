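test_that("beta derivation reproduces the published utility rows", {
  pd <- derive_beta(0.37, 0.33, 0.41)
  expect_equal(round(pd[["alpha"]], 1), 207.1)
  expect_equal(round(pd[["beta"]], 1), 352.6)
  pfd <- derive_beta(0.76, 0.65, 0.87)
  expect_equal(round(pfd[["alpha"]], 1), 44.0)
  expect_equal(round(pfd[["beta"]], 1), 13.9)
  sym <- derive_beta(0.5, 0.4, 0.6)
  expect_equal(sym[["alpha"]], sym[["beta"]])
  expect_error(derive_beta(1, 0.5, 0.9), "mean")
})

test_that("beta derivation round-trips mean and sd", {
  set.seed(3)
  for (i in 1:25) {
    m <- stats::runif(1, 0.1, 0.9)
    half <- stats::runif(1, 0.02, min(m, 1 - m) * 0.9)
    ab <- derive_beta(m, m - half, m + half)
    expect_equal(ab[["alpha"]] / sum(ab), m, tolerance = 1e-9)
    # the no "-1" convention: total equals m(1-m)/sd^2 exactly
    sd <- 2 * half / 3.92
    expect_equal(sum(ab), m * (1 - m) / sd^2, tolerance = 1e-9)
  }
})

test_that("lognormal derivation matches the published HR row", {
  ln <- derive_lognormal(0.34, 0.25, 0.47)
  expect_equal(round(ln[["meanlog"]], 3), -1.079)
  expect_equal(round(ln[["sdlog"]], 3), 0.161)
  expect_equal(derive_lognormal(1, 0.5, 2)[["meanlog"]], 0)
  expect_equal(exp(derive_lognormal(0.49, 0.38, 0.63)[["meanlog"]]), 0.49,
               tolerance = 1e-9)
  expect_error(derive_lognormal(-1, 0.5, 2), "positive")
})

test_that("gamma derivation: overrides and method of moments", {
  # published override pair reproduces the terminal-care mean
  expect_equal(round(142757 * 0.255), 36403)
  mm <- derive_gamma(1462, 1096, 1827)
  sd <- 731 / 3.92
  expect_equal(mm[["shape"]], (1462 / sd)^2)
  expect_equal(mm[["shape"]] * mm[["scale"]], 1462, tolerance = 1e-9)
  expect_error(derive_gamma(-5, 1, 2), "positive")
})

test_that("param_spec derives distribution parameters from ranges", {
  sp <- param_spec("u_pd", 0.37, 0.33, 0.41, dist = "beta")
  expect_equal(round(sp$dist_params[["alpha"]], 1), 207.1)
  sp2 <- param_spec("cost_terminal", 36403, dist = "gamma")
  expect_equal(sp2$low, 36403 * 0.75)  # default 25% range
  expect_equal(sp2$dist_params[["shape"]] * sp2$dist_params[["scale"]],
               36403, tolerance = 1e-9)
  fixed <- param_spec("cost_olaparib_day", 246.8, dist = "fixed")
  expect_null(fixed$dist_params)
})

test_that("one-way analysis orders parameters by span", {
  m <- quick_model("B", horizon_weeks = 156)
  specs <- list(
    param_spec("cost_olaparib_day", 246.8, 246.8 * 0.75, 246.8 * 1.25,
               dist = "fixed"),
    param_spec("u_pd", 0.37, 0.33, 0.41, dist = "beta"),
    param_spec("cost_terminal", 36403, 36403, 36403, dist = "fixed")
  )
  torn <- one_way(m, specs)
  expect_false(is.unsorted(rev(torn$span)))
  # degenerate range has exactly zero span
  expect_equal(torn$span[torn$parameter == "cost_terminal"], 0)
  # ordering invariant to spec order
  torn2 <- one_way(m, rev(specs))
  expect_equal(torn$parameter, torn2$parameter)
  # cheaper intervention drug means higher INHB
  row <- torn[torn$parameter == "cost_olaparib_day", ]
  expect_gte(row$outcome_low, row$outcome_high)
})

test_that("psa is reproducible and collapses when all specs are fixed", {
  m <- quick_model("B", horizon_weeks = 104)
  fixed_specs <- list(
    param_spec("u_pd", 0.37, dist = "fixed"),
    param_spec("cost_terminal", 36403, dist = "fixed")
  )
  s <- psa(m, fixed_specs, n_iter = 5, seed = 1)
  base <- run_model(m)$result
  expect_true(all(abs(s$delta_cost - base$delta_cost) < 1e-9))
  expect_true(all(abs(s$delta_effect - base$delta_effect) < 1e-9))

  specs <- default_param_specs(m$raw)
  s1 <- psa(m, specs, n_iter = 40, seed = 99)
  s2 <- psa(m, specs, n_iter = 40, seed = 99)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  expect_error(psa(m, specs, n_iter = 10), "seed")
})

test_that("psa draws respect supports and mean targets", {
  m <- quick_model("B", horizon_weeks = 26)
  specs <- list(param_spec("u_pd", 0.37, 0.33, 0.41, dist = "beta"))
  s <- psa(m, specs, n_iter = 10000, seed = 4)
  draws <- attr(s, "draws")[, "u_pd"]
  expect_true(all(draws > 0 & draws < 1))
  expect_lt(abs(mean(draws) - 0.37), 0.005)

  # a wide gamma on a utility exercises the redraw path
  bad <- list(param_spec("u_pfd", 0.9, 0.5, 1.4, dist = "gamma"))
  sb <- psa(m, bad, n_iter = 300, seed = 6)
  expect_gt(attr(sb, "redraws"), 0)
  expect_true(all(attr(sb, "draws")[, "u_pfd"] <= 1))
})

test_that("ceac behaves at the edges and steps at the ICER", {
  saving <- data.frame(iteration = 1:3, delta_cost = c(-10, -20, -5),
                       delta_effect = c(0.1, -0.1, 0.2))
  expect_equal(ceac(saving, 0)$prob_ce, 1)
  one <- data.frame(iteration = 1, delta_cost = 7500,
                    delta_effect = 0.05)  # ICER exactly 150000
  cv <- ceac(one, c(149999, 150000, 150001))
  expect_equal(cv$prob_ce, c(0, 0, 1))
  g <- ceac(saving)
  expect_true(all(g$prob_ce >= 0 & g$prob_ce <= 1))
  expect_error(ceac(saving, numeric(0)), "empty")
})

test_that("ceac is monotone in wtp when all samples gain QALYs", {
  set.seed(12)
  pos <- data.frame(iteration = 1:200,
                    delta_cost = stats::runif(200, -2e4, 4e4),
                    delta_effect = stats::runif(200, 0.001, 0.4))
  cv <- ceac(pos)
  expect_false(is.unsorted(cv$prob_ce))
})

test_that("subgroup analysis responds to the PFS hazard ratio", {
  m <- quick_model("B", horizon_weeks = 104)
  overall_hr <- m$raw$hr$pfs
  sg <- subgroup(m, overall_hr[["est"]],
                 c(overall_hr[["est"]], overall_hr[["est"]]),
                 n_iter = 30, seed = 2)
  expect_equal(sg$inhb_point, run_model(m)$result$inhb)
  expect_equal(diff(sg$inhb_range), 0)  # degenerate range collapses

  better <- run_outcome_for_hr(m, 0.3)
  worse <- run_outcome_for_hr(m, 0.9)
  expect_gte(better, worse)
})

test_that("analysis CSV export writes a seed/hash sidecar", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_analysis_csv(data.frame(a = 1:2), path, seed = 7,
                     config_hash = "abc")
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$seed, 7)
  expect_equal(side$config_hash, "abc")
  expect_equal(side$rows, 2)
})

test_that("config hash changes iff the configuration changes", {
  raw <- make_fixture_config("A")
  h1 <- config_hash(raw)
  expect_identical(h1, config_hash(raw))
  raw2 <- raw
  raw2$costs$olaparib_day <- 200
  expect_false(identical(h1, config_hash(raw2)))
})
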