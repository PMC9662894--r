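test_that("hazard offset evaluates the hinge formula", {
  # no joinpoints: h(x) = beta * (x - anchor)
  p0 <- jp_params(alphas = -1, beta = 0.04, anchor = 1990)
  expect_equal(hazard_offset(1990:1995, p0), 0.04 * (0:5))
  # null model
  pz <- jp_params(alphas = -1, beta = 0, anchor = 1990)
  expect_equal(hazard_offset(c(1980, 2005), pz), c(0, 0))
  # piecewise slopes +0.1 then -0.05 around the joinpoint
  p1 <- jp_params(alphas = -1, beta = 0.1, deltas = -0.15, taus = 2000,
                  anchor = 1990)
  expect_equal(hazard_offset(1995, p1), 0.5)
  expect_equal(hazard_offset(2005, p1), 1.5 - 0.75)
  expect_equal(diff(hazard_offset(c(1994, 1995), p1)), 0.1)
  expect_equal(diff(hazard_offset(c(2004, 2005), p1)), -0.05)
  # continuity at the joinpoint
  expect_equal(hazard_offset(2000 + 1e-9, p1), hazard_offset(2000, p1),
               tolerance = 1e-7)
})

test_that("interval survival inverts the complementary log-log link", {
  p <- jp_params(alphas = log(-log(c(0.9, 0.95))), beta = 0, anchor = 2000)
  expect_equal(predict_interval_survival(p, 2000, 1), 0.9)
  expect_equal(predict_interval_survival(p, 2000, 2), 0.95)
  expect_equal(conditional_death_prob(p, 2000, 1), 0.1)
  expect_error(predict_interval_survival(p, 2000, 3), "out of range")
  # proportional hazards: log s_j(x2) / log s_j(x1) = exp(h(x2) - h(x1))
  p2 <- jp_params(alphas = log(-log(c(0.8, 0.9))), beta = -0.03,
                  deltas = -0.02, taus = 1995, anchor = 1990)
  for (j in 1:2) {
    ratio <- log(predict_interval_survival(p2, 2005, j)) /
      log(predict_interval_survival(p2, 1992, j))
    expect_equal(ratio, exp(hazard_offset(2005, p2) - hazard_offset(1992, p2)),
                 tolerance = 1e-12)
  }
})

test_that("cumulative survival: product form equals power form", {
  set.seed(19)
  for (rep in 1:20) {
    J <- sample(2:8, 1)
    p <- jp_params(alphas = rnorm(J, -2, 0.7), beta = rnorm(1, 0, 0.03),
                   deltas = rnorm(1, 0, 0.05), taus = 1995, anchor = 1985)
    x <- sample(1980:2010, 1)
    t <- sample(J, 1)
    prod_form <- prod(predict_interval_survival(p, x, seq_len(t)))
    lam0 <- sum(exp(p$alphas[seq_len(t)]))
    power_form <- exp(-lam0 * exp(hazard_offset(x, p)))
    expect_equal(predict_cumulative_survival(p, x, t), prod_form,
                 tolerance = 1e-12)
    expect_equal(predict_cumulative_survival(p, x, t), power_form,
                 tolerance = 1e-12)
    # non-increasing in t
    St <- predict_cumulative_survival(p, x, seq_len(J))
    expect_true(all(diff(St) < 0))
    expect_equal(St[1], predict_interval_survival(p, x, 1))
  }
})

test_that("small-hazard approximation: death-probability ratio approaches exp(slope)", {
  b <- log(0.95)
  for (alpha in c(-3, -5, -8)) {
    p <- jp_params(alphas = alpha, beta = b, anchor = 2000)
    ratio <- conditional_death_prob(p, 2001, 1) / conditional_death_prob(p, 2000, 1)
    expect_equal(ratio, exp(b), tolerance = 10 * exp(alpha))
  }
  # monotone increasing in the offset
  p <- jp_params(alphas = -2, beta = 0.05, anchor = 2000)
  lam <- conditional_death_prob(p, 2000:2010, 1)
  expect_true(all(diff(lam) > 0))
})

test_that("log-likelihood is binomial-optimal cell-wise and mode-consistent", {
  # single cell: likelihood is maximized when fitted pi equals observed y
  cell <- survtable(data.frame(year = c(2000L, 2001L), interval = 1L,
                               n_at_risk = 100L, n_lost = 0L, n_died = 20L),
                    mode = "cause_specific")
  ll_at <- function(pi_target) {
    a <- log(-log(1 - pi_target))
    jp_loglik(jp_params(alphas = a, beta = 0, anchor = 2000), cell)
  }
  opt <- ll_at(0.2)
  for (pi in c(0.1, 0.15, 0.25, 0.4)) expect_lt(ll_at(pi), opt)
  expect_equal(as.numeric(opt),
               2 * 100 * (0.2 * log(0.2) + 0.8 * log(0.8)), tolerance = 1e-12)

  # relative mode with e = 1 coincides with cause-specific
  tab_cs <- quick_table(seed = 8, n = 500, mode = "cause_specific",
                        years = 1991:2000)
  d <- as.data.frame(tab_cs); d$e_exp <- 1
  tab_rel <- survtable(d, mode = "relative")
  p <- jp_params(alphas = log(-log(c(0.8, 0.88, 0.92, 0.94, 0.95))),
                 beta = -0.02, deltas = -0.08, taus = 1995, anchor = 1991)
  expect_equal(as.numeric(jp_loglik(p, tab_rel)),
               as.numeric(jp_loglik(p, tab_cs)), tolerance = 1e-12)
})

test_that("analytic likelihood derivatives match finite differences", {
  tab <- quick_table(seed = 21, n = 200, years = 1993:2000, J = 3)
  fit <- fit_fixed_joinpoints(tab, taus = 1996)
  ref <- fit$params
  f <- function(theta) as.numeric(jp_loglik(theta_to_params(theta, ref), tab))
  theta <- coef(fit) * 0.9 - 0.05   # off-optimum point
  p_off <- theta_to_params(theta, ref)
  cells <- joinsurv:::likelihood_cells(tab)
  X <- joinsurv:::jp_design(cells$x, cells$j, 3L, ref$taus, ref$anchor)
  eta <- drop(X %*% theta)
  d <- joinsurv:::loglik_derivs(eta, cells)
  expect_equal(drop(crossprod(X, d$u)), fd_gradient(f, theta),
               tolerance = 1e-5, ignore_attr = TRUE)
  expect_equal(crossprod(X, d$d2 * X), fd_hessian(f, theta),
               tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("IRLS satisfies the score equations and reproduces its loglik", {
  tab <- quick_table(seed = 31)
  fit <- fit_fixed_joinpoints(tab, taus = 1990)
  expect_true(fit$converged)
  expect_equal(as.numeric(jp_loglik(fit$params, tab)), fit$loglik,
               tolerance = 1e-8)
  cells <- joinsurv:::likelihood_cells(tab)
  X <- joinsurv:::jp_design(cells$x, cells$j, 5L, fit$params$taus,
                            fit$params$anchor)
  d <- joinsurv:::loglik_derivs(drop(X %*% coef(fit)), cells)
  score <- drop(crossprod(X, d$u))
  expect_lt(max(abs(score)) / (abs(fit$loglik) + 1), 1e-6)
  # covariance is symmetric positive definite (the Hessian behind it is
  # validated against finite differences in the derivatives test)
  expect_equal(fit$cov, t(fit$cov))
  expect_true(all(eigen(fit$cov, symmetric = TRUE)$values > 0))
})

test_that("flat truth at large n is recovered as a near-zero slope", {
  cfg <- sim_config(year_range = 1991:2000, J = 3, cohort_size = 1e5,
                    baseline_interval_survival = c(0.85, 0.92, 0.95),
                    beta = 0, deltas = numeric(), taus = numeric(), seed = 13)
  fit <- fit_fixed_joinpoints(simulate_table(cfg))
  sl <- segment_slope(fit, 0)
  expect_lt(abs(sl["slope"]), 0.01)
  expect_lt(abs(sl["slope"]) / sl["se"], 3)
})

test_that("a one-parameter-per-cell design reproduces the data exactly", {
  # J = 1, two diagnosis years: 2 cells, 2 free parameters (alpha, beta)
  tab <- survtable(data.frame(year = c(2000L, 2001L), interval = 1L,
                              n_at_risk = c(400L, 500L), n_lost = c(20L, 10L),
                              n_died = c(60L, 45L)), mode = "cause_specific")
  fit <- fit_fixed_joinpoints(tab)
  obs <- observed_lifetable(tab)
  fitted <- conditional_death_prob(fit$params, obs$year, obs$interval)
  expect_equal(fitted, obs$q_obs, tolerance = 1e-6)
})

test_that("fits are invariant to shifting the calendar labels", {
  tab <- quick_table(seed = 41, n = 1000)
  fit <- fit_fixed_joinpoints(tab, taus = 1990)
  shifted <- as.data.frame(tab)
  shifted$year <- shifted$year + 37L
  tabs <- survtable(shifted, mode = "relative")
  fit_s <- fit_fixed_joinpoints(tabs, taus = 1990 + 37)
  expect_equal(fit_s$loglik, fit$loglik, tolerance = 1e-10)
  expect_equal(fit_s$bic, fit$bic, tolerance = 1e-10)
  expect_equal(predict_cumulative_survival(fit_s$params, (1981:2000) + 37, 5),
               predict_cumulative_survival(fit$params, 1981:2000, 5),
               tolerance = 1e-10)
  expect_equal(apc_d(fit_s)$estimate, apc_d(fit)$estimate, tolerance = 1e-10)
  expect_equal(aac_s(fit_s, 5)$estimate, aac_s(fit, 5)$estimate,
               tolerance = 1e-10)
})

test_that("fitted survival stays in (0,1] even when observed relative survival exceeds 1", {
  # light excess mortality: many cells have r_obs > 1 by chance
  cfg <- sim_config(year_range = 1991:2005, J = 5, cohort_size = 400,
                    baseline_interval_survival = c(0.97, 0.985, 0.99, 0.99, 0.995),
                    beta = -0.01, deltas = numeric(), taus = numeric(),
                    expected_interval_survival = 0.96, seed = 17)
  tab <- simulate_table(cfg)
  obs <- observed_lifetable(tab)
  expect_true(any(obs$r_int > 1))   # the scenario exercises the bound
  fit <- fit_fixed_joinpoints(tab)
  S <- predict_cumulative_survival(fit$params, obs$year, obs$interval)
  expect_true(all(S > 0 & S <= 1))
})

test_that("degenerate designs are rejected with an informative error", {
  tab <- quick_table(seed = 51, n = 200)
  expect_error(fit_fixed_joinpoints(tab, taus = 1999.5),
               "fewer than two diagnosis years")
  expect_error(fit_fixed_joinpoints(tab, taus = 1981), "strictly inside")
  one_year <- select_cohort(tab, year_min = 1990, year_max = 1990)
  expect_error(fit_fixed_joinpoints(one_year), "two diagnosis years")
})
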