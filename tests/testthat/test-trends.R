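fit_81 <- local({
  tab <- quick_table(seed = 91, n = 2000)
  fit_fixed_joinpoints(tab, taus = 1990)
})

test_that("segment slopes are the cumulative sums of the slope changes", {
  p <- fit_81$params
  expect_equal(segment_slope(fit_81, 0)[["slope"]], p$beta)
  expect_equal(segment_slope(fit_81, 1)[["slope"]], p$beta + p$deltas[1])
  expect_error(segment_slope(fit_81, 2), "between 0 and 1")
  # SE is the linear-combination form c' Sigma c
  J <- length(p$alphas)
  cvec <- c(rep(0, J), 1, 1)
  expect_equal(segment_slope(fit_81, 1)[["se"]],
               sqrt(drop(cvec %*% fit_81$cov %*% cvec)))
})

test_that("the hazard-side trend converts slopes to percent changes", {
  expect_equal(apc_from_slope(log(0.98)), -2)
  expect_equal(apc_from_slope(log(0.95)), -5)
  expect_equal(apc_from_slope(0), 0)
  a <- apc_d(fit_81)
  expect_equal(nrow(a), 2L)
  expect_equal(a$estimate, 100 * (exp(c(segment_slope(fit_81, 0)[["slope"]],
                                        segment_slope(fit_81, 1)[["slope"]])) - 1))
  expect_equal(a$ci_lo, a$estimate - 1.96 * a$se, tolerance = 1e-3)
  expect_true(all(a$direction %in% c("up", "down", "ns")))
  # a zero-slope fit gives APC_D centred at 0 and not significant
  flat_tab <- quick_table(seed = 92, beta = 0, deltas = numeric(),
                          taus = numeric(), n = 500)
  flat <- fit_fixed_joinpoints(flat_tab)
  a0 <- apc_d(flat)
  expect_lt(abs(a0$estimate), 3 * a0$se)
})

test_that("the averaged and telescoped AAC_S formulas agree exactly", {
  for (t in c(1, 5)) {
    for (seg in list(c(1981, 1990), c(1990, 2000), c(1984, 1997))) {
      a <- aac_s(fit_81, t, seg[1], seg[2])
      yrs <- seg[1]:seg[2]
      mean_diff <- mean(100 * diff(predict_cumulative_survival(
        fit_81$params, yrs, t)))
      expect_equal(a$estimate, mean_diff, tolerance = 1e-12)
    }
  }
  # default segments follow the joinpoint structure
  a <- aac_s(fit_81, 5)
  expect_equal(a$start_year, c(1981, 1990))
  expect_equal(a$end_year, c(1990, 2000))
  expect_error(aac_s(fit_81, 5, 1990, 1990), "single-year")
  expect_error(aac_s(fit_81, 99, 1981, 1990), "between 1 and")
})

test_that("zero slopes give a zero AAC_S at every follow-up time", {
  flat_tab <- quick_table(seed = 93, beta = 0, deltas = numeric(),
                          taus = numeric(), n = 500)
  fit <- fit_fixed_joinpoints(flat_tab)
  # force the slope to exactly zero: the measure must vanish identically
  fit$params$beta <- 0
  for (t in 1:5) {
    expect_equal(aac_s(fit, t, 1981, 2000)$estimate, 0, tolerance = 1e-12)
  }
})

test_that("analytic delta-method gradient matches finite differences", {
  for (t in c(1, 5)) {
    a_an <- aac_s(fit_81, t, 1990, 2000, se_method = "analytic")
    a_fd <- aac_s(fit_81, t, 1990, 2000, se_method = "numeric")
    expect_equal(a_an$estimate, a_fd$estimate, tolerance = 1e-12)
    expect_equal(a_an$se, a_fd$se, tolerance = 1e-6)
  }
})

test_that("survival and death-probability trends have opposite signs", {
  # across several fitted models: AAC_S(t) > 0 iff APC_D < 0, for every t
  for (seed in c(94, 95)) {
    tab <- quick_table(seed = seed, n = 2000,
                       beta = sample(c(-0.03, 0.01), 1))
    fit <- fit_fixed_joinpoints(tab, taus = 1990)
    a <- apc_d(fit)
    for (t in c(1, 3, 5)) {
      s <- aac_s(fit, t)
      expect_true(all(sign(s$estimate) == -sign(a$estimate)))
    }
    # APC_D is follow-up free; AAC_S(1) and AAC_S(5) differ
    expect_false(isTRUE(all.equal(aac_s(fit, 1)$estimate,
                                  aac_s(fit, 5)$estimate)))
  }
})

test_that("projection extends the last segment and flags extrapolation", {
  proj <- project_survival(fit_81, horizon = 5, t_values = c(1, 5),
                           warn_margin = 0)
  L <- max(fit_81$years)
  # continuity: in-sample values equal direct predictions, not projected
  ins <- proj[proj$year <= L & proj$t == 5 & proj$year <= L - 5, ]
  expect_equal(ins$survival,
               predict_cumulative_survival(fit_81$params, ins$year, 5),
               tolerance = 1e-12)
  expect_false(any(ins$projected))
  # beyond L everything is flagged and follows h(L) + k * slope
  beyond <- proj[proj$year > L & proj$t == 1, ]
  expect_true(all(beyond$projected))
  slope_last <- segment_slope(fit_81, 1)[["slope"]]
  h_ext <- hazard_offset(L, fit_81$params) + slope_last * (beyond$year - L)
  expect_equal(hazard_offset(beyond$year, fit_81$params), h_ext,
               tolerance = 1e-12)
  # recent diagnosis years with incomplete follow-up are flagged too
  cut_cfg <- quick_config(seed = 96, n = 300, data_cutoff_year = 1998)
  cfit <- fit_fixed_joinpoints(simulate_table(cut_cfg), taus = 1990)
  cproj <- project_survival(cfit, horizon = 0, t_values = 5, warn_margin = 0)
  expect_true(all(cproj$projected[cproj$year > 1993]))
  expect_false(any(cproj$projected[cproj$year <= 1993]))
  # a zero last slope projects a constant surface
  fitc <- fit_81
  fitc$params$beta <- 0
  fitc$params$deltas <- 0
  flatp <- project_survival(fitc, horizon = 4, t_values = 5, warn_margin = 0)
  expect_equal(diff(flatp$survival[flatp$year >= L]), rep(0, 4),
               tolerance = 1e-12)
  # caution when the last joinpoint sits close to the last data year
  tab <- quick_table(seed = 97, n = 1000, taus = 1996)
  late <- fit_fixed_joinpoints(simulate_table(quick_config(seed = 97, n = 1000,
                                                           taus = 1996)),
                               taus = 1996)
  expect_warning(project_survival(late, horizon = 2), "unstable")
})

test_that("plot datasets pass observed values through verbatim", {
  tab <- quick_table(seed = 98, n = 800)
  fit <- fit_fixed_joinpoints(tab, taus = 1990)
  obs <- observed_lifetable(tab)
  d <- plot_survival_by_year(fit, obs, t_values = c(1, 5))
  sub <- d[!is.na(d$survival_obs), ]
  idx <- match(paste(sub$year, sub$t), paste(obs$year, obs$interval))
  expect_equal(sub$survival_obs, obs$S_obs[idx])
  expect_equal(sub$se_obs, obs$se_S[idx])
  # death-probability panel: observed is 1 - interval net survival
  dp <- plot_death_prob_by_year(fit, obs, j_values = c(1, 5))
  sub <- dp[!is.na(dp$death_prob_obs), ]
  idx <- match(paste(sub$year, sub$j), paste(obs$year, obs$interval))
  expect_equal(sub$death_prob_obs, 1 - obs$r_int[idx])
  expect_error(plot_death_prob_by_year(fit, obs, j_values = integer()),
               "non-empty")
  # model-only when no observed data handed over
  d0 <- plot_survival_by_year(fit, NULL, t_values = 1)
  expect_true(all(is.na(d0$survival_obs)))
})

test_that("survival curves are monotone and consistent across displays", {
  curves <- plot_survival_curves(fit_81, years = c(1985, 1995))
  for (y in c(1985, 1995)) {
    s <- curves$survival[curves$year == y]
    expect_true(all(diff(s) < 0))
  }
  # improving survival: later diagnosis year lies uniformly above
  expect_true(all(curves$survival[curves$year == 1995] >
                    curves$survival[curves$year == 1985]))
  # transposed consistency with the survival-by-year dataset
  byyear <- plot_survival_by_year(fit_81, NULL, t_values = 1:5, horizon = 0)
  for (t in 1:5) {
    expect_equal(curves$survival[curves$year == 1995 & curves$t == t],
                 byyear$survival_model[byyear$year == 1995 & byyear$t == t])
  }
})

test_that("the trend report mirrors the segment structure", {
  tt <- trend_table(fit_81, t_values = c(1, 5))
  expect_equal(nrow(tt), 2L)
  expect_equal(tt$start_year, c(1981, 1990))
  a5 <- aac_s(fit_81, 5)
  expect_equal(tt$aac_s_5, a5$estimate)
  expect_equal(tt$apc_d, apc_d(fit_81)$estimate)
  expect_true(is.logical(tt$highlight))
})
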