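#' Fit a joinpoint survival trend model to a grouped life table
#'
#' The main entry point: selects a cohort, runs the grid search over
#' joinpoint configurations with IRLS estimation at each candidate, picks
#' the final model by information criterion, and returns a fitted model
#' object carrying the full ladder, the selected fit and the observed
#' actuarial life table.
#'
#' @param data a [survtable()] (or data frame coercible to one via
#'   `survtable(data, mode)`).
#' @param max_joinpoints maximum number of joinpoints tested (0..5).
#' @param criterion `"bic"` (default) or `"aic"`.
#' @param strata_filter,year_min,year_max,max_followup cohort restriction,
#'   passed to [select_cohort()]; the restricted table must be a single
#'   cohort.
#' @param mode survival mode, used only when `data` is a bare data frame.
#' @param min_years_between,min_years_before_first,min_years_after_last
#'   grid-search spacing constraints, see [jp_constraints()].
#' @param control IRLS options, see [fit_fixed_joinpoints()].
#' @param progress print grid-search progress per K.
#' @return an object of class `joinsurv`: list with elements `fit` (the
#'   selected `jp_fit`), `ladder` (the `jp_ladder`), `observed` (the
#'   actuarial estimates from [observed_lifetable()]), `table` (the fitted
#'   [survtable()]), `criterion` and `call`.
#' @examples
#' cfg <- sim_config(year_range = 1985:2005, J = 5, cohort_size = 2000,
#'                   beta = -0.01, deltas = -0.05, taus = 1995, seed = 7)
#' tab <- simulate_table(cfg)
#' m <- jp_survfit(tab, max_joinpoints = 1)
#' print(m)
#' apc_d(m$fit)
#' @export
jp_survfit <- function(data, max_joinpoints = 0L,
                       criterion = c("bic", "aic"),
                       strata_filter = NULL, year_min = NULL, year_max = NULL,
                       max_followup = NULL,
                       mode = c("relative", "cause_specific", "overall"),
                       min_years_between = 2L, min_years_before_first = 3L,
                       min_years_after_last = 5L,
                       control = list(), progress = FALSE) {
  criterion <- match.arg(criterion)
  if (!inherits(data, "survtable")) data <- survtable(data, match.arg(mode))
  tab <- select_cohort(data, strata_filter, year_min, year_max, max_followup,
                       require_single_cohort = TRUE)
  cons <- jp_constraints(max_joinpoints, min_years_between,
                         min_years_before_first, min_years_after_last,
                         criterion)
  ladder <- grid_search(tab, cons, control, progress)
  fit <- select_model(ladder, criterion)
  structure(list(fit = fit, ladder = ladder,
                 observed = observed_lifetable(tab), table = tab,
                 criterion = criterion, call = match.call()),
            class = "joinsurv")
}

#' @export
print.joinsurv <- function(x, ...) {
  cat("Joinpoint survival trend model\n\n")
  print(x$fit)
  K <- length(x$fit$params$taus)
  if (K) {
    cat("Joinpoint year(s):", paste(x$fit$params$taus, collapse = ", "), "\n")
  }
  sl <- vapply(0:K, function(m) segment_slope(x$fit, m)["slope"], numeric(1))
  cat("Segment slopes (log-hazard per year):",
      paste(signif(sl, 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.joinsurv <- function(object, t_values = c(1, 5), ...) {
  structure(list(ladder = object$ladder$table,
                 criterion = object$criterion,
                 trends = trend_table(object$fit, t_values),
                 fit = object$fit),
            class = "summary.joinsurv")
}

#' @export
print.summary.joinsurv <- function(x, ...) {
  cat(sprintf("Model ladder (final model by %s):\n", toupper(x$criterion)))
  print(x$ladder, row.names = FALSE, digits = 6)
  cat("\nSegment trend measures (AAC_S in percentage points, APC_D in percent):\n")
  print(x$trends, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
coef.joinsurv <- function(object, ...) coef(object$fit)

#' @export
vcov.joinsurv <- function(object, ...) object$fit$cov

#' @export
logLik.joinsurv <- function(object, ...) logLik(object$fit)

#' Predict survival quantities from a fitted joinpoint model
#'
#' @param object a `joinsurv` model.
#' @param years diagnosis years (default the fitted years).
#' @param t follow-up times / intervals (default 1..J).
#' @param type `"cumulative"` for S(t | x), `"interval"` for the net
#'   interval survival s_j(x), `"death_prob"` for the conditional interval
#'   death probability 1 - s_j(x).
#' @param ... unused.
#' @return data frame with `year`, `t` (or `j`) and the requested quantity.
#' @export
predict.joinsurv <- function(object, years = NULL, t = NULL,
                           type = c("cumulative", "interval", "death_prob"),
                           ...) {
  type <- match.arg(type)
  p <- object$fit$params
  if (is.null(years)) years <- object$fit$years
  if (is.null(t)) t <- seq_along(p$alphas)
  grid <- expand.grid(year = years, t = t)
  grid$value <- switch(type,
    cumulative = predict_cumulative_survival(p, grid$year, grid$t),
    interval = predict_interval_survival(p, grid$year, grid$t),
    death_prob = conditional_death_prob(p, grid$year, grid$t))
  names(grid)[2] <- if (type == "cumulative") "t" else "j"
  names(grid)[3] <- switch(type, cumulative = "survival",
                           interval = "interval_survival",
                           death_prob = "death_prob")
  grid
}

#' Residuals of a fitted joinpoint survival model
#'
#' Per (year, interval) cell: observed death fraction minus fitted
#' all-cause interval death probability (`type = "response"`), optionally
#' standardized by the binomial standard deviation under the fit
#' (`type = "pearson"`). The attribute `"cells"` carries the year and
#' interval of each residual; systematic opposite-signed response
#' residuals in early vs late intervals across a calendar break indicate a
#' violation of the proportional-hazards assumption.
#'
#' @param object a `joinsurv` model.
#' @param type `"response"` or `"pearson"`.
#' @param ... unused.
#' @return numeric vector, one residual per table row, with attribute
#'   `"cells"` (data frame `year`, `interval`).
#' @export
residuals.joinsurv <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  cells <- likelihood_cells(object$table)
  eta <- object$fit$params$alphas[cells$j] +
    hazard_offset(cells$x, object$fit$params)
  pi <- fitted_pi(eta, cells$e)
  r <- cells$y - pi
  if (type == "pearson") r <- r / sqrt(pi * (1 - pi) / cells$n_eff)
  attr(r, "cells") <- data.frame(year = cells$x, interval = cells$j)
  r
}

#' Parametric-bootstrap tables from a fitted joinpoint model
#'
#' Draws new grouped survival tables from the fitted model: each diagnosis
#' year starts from its observed initial cohort size, losses use the
#' pooled observed loss rate, and deaths use the fitted interval death
#' probabilities; expected survival is carried over from the data.
#' Refitting these tables (at the selected joinpoints) gives parametric
#' bootstrap distributions for any derived quantity.
#'
#' @param object a `joinsurv` model.
#' @param nsim number of tables.
#' @param seed RNG seed (required; the caller's RNG state is untouched).
#' @param ... unused.
#' @return a list of `nsim` [survtable()] objects.
#' @export
simulate.joinsurv <- function(object, nsim = 1, seed, ...) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  tab <- object$table
  p <- object$fit$params
  first <- tab[tab$interval == 1L, ]
  sizes <- stats::setNames(first$n_at_risk, first$year)
  years <- sort(unique(tab$year))
  loss_rate <- sum(tab$n_lost) / sum(tab$n_at_risk)
  J <- max(tab$interval)
  e_lookup <- stats::setNames(tab$e_exp, paste(tab$year, tab$interval))
  cutoff <- if (any(tapply(tab$interval, tab$year, max) < J))
    max(tab$year + tab$interval) else NULL
  mode <- attr(tab, "mode")
  lapply(seq_len(nsim), function(i) {
    cfg <- sim_config(year_range = years, J = J,
                      cohort_size = as.integer(sizes[as.character(years)]),
                      baseline_interval_survival = exp(-exp(p$alphas)),
                      beta = p$beta, deltas = p$deltas, taus = p$taus,
                      expected_interval_survival = function(x, j) {
                        e <- e_lookup[paste(x, j)]
                        ifelse(is.na(e), 1, e)
                      },
                      loss_prob = loss_rate, mode = mode,
                      data_cutoff_year = cutoff, seed = seed + i - 1L)
    simulate_table(cfg)
  })
}

#' Plot a fitted joinpoint survival trend model
#'
#' Observed (points) and modeled (lines) t-year cumulative survival by
#' calendar year of diagnosis, with projections dashed and joinpoints
#' marked; base graphics.
#'
#' @param x a `joinsurv` model.
#' @param t_values follow-up times to draw (default `c(1, 5)` capped at J).
#' @param horizon projection horizon in years.
#' @param ... passed to [graphics::plot()].
#' @return the plotting dataset from [plot_survival_by_year()], invisibly.
#' @export
plot.joinsurv <- function(x, t_values = c(1, 5), horizon = 5, ...) {
  J <- length(x$fit$params$alphas)
  t_values <- t_values[t_values <= J]
  d <- plot_survival_by_year(x$fit, x$observed, t_values, horizon)
  graphics::plot(range(d$year), range(c(d$survival_model, d$survival_obs),
                                      na.rm = TRUE),
                 type = "n", xlab = "Year of diagnosis",
                 ylab = "Cumulative net survival", ...)
  cols <- seq_along(t_values)
  for (i in seq_along(t_values)) {
    di <- d[d$t == t_values[i], ]
    obs <- di[!di$projected, ]
    prj <- di[di$projected | c(diff(di$projected) != 0, FALSE), ]
    graphics::lines(obs$year, obs$survival_model, col = cols[i], lty = 1)
    if (nrow(prj)) graphics::lines(prj$year, prj$survival_model,
                                   col = cols[i], lty = 2)
    graphics::points(di$year, di$survival_obs, col = cols[i], pch = 16,
                     cex = 0.6)
  }
  if (length(x$fit$params$taus)) {
    graphics::abline(v = x$fit$params$taus, col = "grey60", lty = 3)
  }
  graphics::legend("bottomright", legend = paste0(t_values, "-year"),
                   col = cols, lty = 1, pch = 16, bty = "n")
  invisible(d)
}
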