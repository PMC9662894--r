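#' Slope of a joinpoint segment
#'
#' Segment m (m = 0..K, counting the joinpoints to its left) has slope
#' \eqn{\beta^* = \beta + \delta_1 + \dots + \delta_m} on the log-hazard
#' scale. The standard error is that of the linear combination
#' `c = (0...0, 1, 1...1, 0...0)` of the free parameters under the fit's
#' covariance.
#'
#' @param fit a `jp_fit` from [fit_fixed_joinpoints()].
#' @param segment segment index m, 0-based: 0 is the segment before the
#'   first joinpoint.
#' @return named numeric `c(slope, se)`.
#' @export
segment_slope <- function(fit, segment = 0L) {
  stopifnot(inherits(fit, "jp_fit"))
  K <- length(fit$params$taus)
  if (segment < 0 || segment > K) {
    stop("segment must be between 0 and ", K, call. = FALSE)
  }
  J <- length(fit$params$alphas)
  cvec <- c(rep(0, J), 1, rep(0, K))
  if (segment > 0) cvec[J + 1L + seq_len(segment)] <- 1
  slope <- fit$params$beta + sum(fit$params$deltas[seq_len(segment)])
  se <- sqrt(max(drop(cvec %*% fit$cov %*% cvec), 0))
  c(slope = slope, se = se)
}

#' Annual percent change implied by a log-hazard slope
#'
#' The scale conversion at the heart of the hazard-side trend measure:
#' a segment slope beta* on the log-hazard scale corresponds to an annual
#' percent change of `100 * (exp(beta*) - 1)` in the conditional
#' probability of cancer death, i.e. a year-over-year relative risk of
#' `exp(beta*)`.
#'
#' @param beta_star segment slope(s) on the log-hazard scale.
#' @return APC_D in percent.
#' @export
apc_from_slope <- function(beta_star) 100 * expm1(beta_star)

segment_bounds <- function(fit) {
  yrs <- range(fit$years)
  taus <- fit$params$taus
  data.frame(segment = 0:length(taus),
             start = c(yrs[1], taus), end = c(taus, yrs[2]))
}

trend_row <- function(measure, t, start, end, estimate, se, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  lo <- estimate - z * se
  hi <- estimate + z * se
  sig <- is.finite(lo) && is.finite(hi) && (lo > 0 || hi < 0)
  data.frame(measure = measure, t = t, start_year = start, end_year = end,
             estimate = estimate, se = se, ci_lo = lo, ci_hi = hi,
             significant = sig,
             direction = if (!sig) "ns" else if (estimate > 0) "up" else "down",
             stringsAsFactors = FALSE)
}

#' Annual percent change in the conditional probability of cancer death
#'
#' `APC_D = 100 (exp(beta*) - 1)` for the slope beta* of a joinpoint
#' segment: the year-over-year percent change in the hazard of cancer
#' death, so that APC_D = -2 corresponds to a 0.98 relative risk of dying
#' in a given interval for patients diagnosed one year later. APC_D does
#' not depend on time since diagnosis. The standard error is by the delta
#' method, `100 exp(beta*) se(beta*)`, with a 95% normal interval; the
#' direction is `"ns"` when the interval spans zero.
#'
#' @param fit a converged `jp_fit`.
#' @param segment segment index 0..K, or `NULL` (default) for all segments.
#' @return a data frame of trend estimates, one row per segment, with
#'   columns `measure`, `t` (NA: APC_D is follow-up free), `start_year`,
#'   `end_year`, `estimate` (percent), `se`, `ci_lo`, `ci_hi`,
#'   `significant`, `direction`.
#' @export
apc_d <- function(fit, segment = NULL) {
  stopifnot(inherits(fit, "jp_fit"))
  segs <- segment_bounds(fit)
  if (!is.null(segment)) segs <- segs[segs$segment %in% segment, , drop = FALSE]
  out <- lapply(seq_len(nrow(segs)), function(i) {
    sl <- segment_slope(fit, segs$segment[i])
    trend_row("apc_d", NA_real_, segs$start[i], segs$end[i],
              apc_from_slope(sl["slope"]),
              100 * exp(sl["slope"]) * sl["se"])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# gradient of S(t | x) wrt the free parameters (alphas, beta, deltas);
# log S = -Lambda0(t) exp(h(x)), Lambda0(t) = sum_{j<=t} exp(alpha_j)
surv_gradient <- function(fit, x, t) {
  p <- fit$params
  J <- length(p$alphas)
  K <- length(p$taus)
  eh <- exp(hazard_offset(x, p))
  lam <- exp(p$alphas)
  S <- predict_cumulative_survival(p, x, t)
  logS <- log(S)
  g <- numeric(J + 1L + K)
  g[seq_len(t)] <- S * (-lam[seq_len(t)] * eh)
  g[J + 1L] <- S * logS * (x - p$anchor)
  if (K) {
    for (k in seq_len(K)) g[J + 1L + k] <- S * logS * max(x - p$taus[k], 0)
  }
  g
}

#' Average annual absolute change in t-year cumulative survival
#'
#' `AAC_S(t)` over calendar years `[year_start, year_end]` is the mean of
#' the year-over-year survival differences `S(t | x+1) - S(t | x)`, in
#' percentage points. The mean telescopes exactly to
#' `100 * (S(t | year_end) - S(t | year_start)) / (year_end - year_start)`.
#' Unlike APC_D it depends on the follow-up time t. The standard error is
#' by the delta method through the telescoped expression, with the
#' joinpoint locations treated as fixed; `se_method = "numeric"` replaces
#' the analytic gradient by central finite differences (relative step
#' 1e-6), which is used in tests to validate the analytic form.
#'
#' @param fit a converged `jp_fit`.
#' @param t follow-up time in whole years (scalar, 1..J).
#' @param year_start,year_end calendar-year window; defaults to every
#'   segment of the fitted model (one row each). Windows beyond the data
#'   range are allowed and use the last segment's projected trend.
#' @param se_method `"analytic"` (default) or `"numeric"`.
#' @return a data frame of trend estimates as in [apc_d()], `t` filled in,
#'   `estimate` in survival percentage points per year of diagnosis.
#' @export
aac_s <- function(fit, t, year_start = NULL, year_end = NULL,
                  se_method = c("analytic", "numeric")) {
  stopifnot(inherits(fit, "jp_fit"), length(t) == 1L)
  se_method <- match.arg(se_method)
  J <- length(fit$params$alphas)
  if (t < 1 || t > J) stop("t must be between 1 and ", J, call. = FALSE)
  if (is.null(year_start) != is.null(year_end)) {
    stop("give both year_start and year_end, or neither", call. = FALSE)
  }
  if (is.null(year_start)) {
    segs <- segment_bounds(fit)
    res <- do.call(rbind, lapply(seq_len(nrow(segs)), function(i) {
      aac_s(fit, t, segs$start[i], segs$end[i], se_method)
    }))
    rownames(res) <- NULL
    return(res)
  }
  if (year_end <= year_start) {
    stop("year_end must exceed year_start (a single-year window has no annual change)",
         call. = FALSE)
  }
  span <- year_end - year_start
  est <- 100 * (predict_cumulative_survival(fit$params, year_end, t) -
                  predict_cumulative_survival(fit$params, year_start, t)) / span
  if (se_method == "analytic") {
    g <- 100 * (surv_gradient(fit, year_end, t) -
                  surv_gradient(fit, year_start, t)) / span
  } else {
    theta <- coef(fit)
    f <- function(th) {
      pp <- jp_params(th[seq_len(J)], th[J + 1L],
                      th[-seq_len(J + 1L)], fit$params$taus, fit$params$anchor)
      100 * (predict_cumulative_survival(pp, year_end, t) -
               predict_cumulative_survival(pp, year_start, t)) / span
    }
    g <- vapply(seq_along(theta), function(i) {
      h <- 1e-6 * max(abs(theta[i]), 1)
      up <- theta; up[i] <- up[i] + h
      dn <- theta; dn[i] <- dn[i] - h
      (f(up) - f(dn)) / (2 * h)
    }, numeric(1))
  }
  se <- sqrt(max(drop(g %*% fit$cov %*% g), 0))
  trend_row("aac_s", t, year_start, year_end, est, se)
}

#' Project the survival surface beyond the observed data
#'
#' Evaluates model cumulative survival S(t | x) for every requested
#' follow-up time and for diagnosis years running from the first observed
#' year to `horizon` years past the last. Projection extends the last
#' segment's linear trend (the hinge terms grow linearly past the last
#' joinpoint, so no separate formula is needed) and also fills in t-year
#' survival for recent diagnosis years whose follow-up is still
#' incomplete; both kinds of extrapolated value are flagged `projected`.
#'
#' @param fit a converged `jp_fit`.
#' @param horizon years beyond the last observed diagnosis year (>= 0).
#' @param t_values follow-up times to evaluate (default 1..J).
#' @param warn_margin emit a caution when the last joinpoint is within
#'   this many years of the last data year (extrapolation from a short
#'   final segment is unstable); default 5, `0` to disable.
#' @return data frame with columns `year`, `t`, `survival`, `projected`.
#' @export
project_survival <- function(fit, horizon = 5, t_values = NULL,
                             warn_margin = 5) {
  stopifnot(inherits(fit, "jp_fit"), horizon >= 0)
  J <- length(fit$params$alphas)
  if (is.null(t_values)) t_values <- seq_len(J)
  if (any(t_values < 1 | t_values > J)) {
    stop("t_values must lie in 1..", J, call. = FALSE)
  }
  L <- max(fit$years)
  taus <- fit$params$taus
  if (warn_margin > 0 && length(taus) && L - max(taus) < warn_margin) {
    warning(sprintf("last joinpoint (%g) is within %d years of the last data year (%d); projected trends may be unstable",
                    max(taus), warn_margin, L), call. = FALSE)
  }
  years <- seq(min(fit$years), L + horizon)
  max_obs <- stats::setNames(fit$intervals, fit$years)
  grid <- expand.grid(year = years, t = sort(t_values))
  grid$survival <- predict_cumulative_survival(fit$params, grid$year, grid$t)
  obs_depth <- max_obs[as.character(grid$year)]
  obs_depth[is.na(obs_depth)] <- 0L
  grid$projected <- grid$year > L | grid$t > obs_depth
  grid[order(grid$t, grid$year), c("year", "t", "survival", "projected")]
}

#' Observed vs modeled cumulative survival by year of diagnosis
#'
#' Builds the plotting dataset behind the "X-year survival by calendar year
#' of diagnosis" display: model S(t | x) for each requested follow-up time
#' (with projections) merged with the observed actuarial values and their
#' Greenwood standard errors where follow-up is deep enough. Observed
#' values are passed through verbatim, never smoothed.
#'
#' @param fit a converged `jp_fit`.
#' @param observed output of [observed_lifetable()] for the fitted cohort,
#'   or `NULL` for model values only.
#' @param t_values follow-up times to display (e.g. `c(1, 5, 10)`).
#' @param horizon projection horizon in years (default 5).
#' @return data frame with columns `year`, `t`, `survival_model`,
#'   `projected`, `survival_obs`, `se_obs`.
#' @export
plot_survival_by_year <- function(fit, observed = NULL, t_values = c(1, 5),
                                  horizon = 5) {
  grid <- project_survival(fit, horizon, t_values, warn_margin = 0)
  names(grid)[names(grid) == "survival"] <- "survival_model"
  grid$survival_obs <- NA_real_
  grid$se_obs <- NA_real_
  if (!is.null(observed)) {
    key <- paste(grid$year, grid$t)
    okey <- paste(observed$year, observed$interval)
    idx <- match(key, okey)
    grid$survival_obs <- observed$S_obs[idx]
    grid$se_obs <- observed$se_S[idx]
  }
  rownames(grid) <- NULL
  grid
}

#' Observed vs modeled annual probability of cancer death by year
#'
#' The dataset behind the "interval j death probability by calendar year"
#' display, the natural visual check of the proportional-hazards
#' assumption: under proportionality the year trend is the same at every
#' follow-up interval, so opposite-signed observed-vs-model deviations in
#' early vs late intervals indicate non-proportionality.
#'
#' @param fit a converged `jp_fit`.
#' @param observed output of [observed_lifetable()], or `NULL`.
#' @param j_values follow-up intervals to display (non-empty).
#' @param horizon projection horizon in years.
#' @return data frame with columns `year`, `j`, `death_prob_model`,
#'   `projected`, `death_prob_obs`.
#' @export
plot_death_prob_by_year <- function(fit, observed = NULL, j_values = c(1, 5),
                                    horizon = 5) {
  if (!length(j_values)) stop("j_values must be non-empty", call. = FALSE)
  J <- length(fit$params$alphas)
  if (any(j_values < 1 | j_values > J)) {
    stop("j_values must lie in 1..", J, call. = FALSE)
  }
  L <- max(fit$years)
  years <- seq(min(fit$years), L + horizon)
  grid <- expand.grid(year = years, j = sort(j_values))
  grid$death_prob_model <- conditional_death_prob(fit$params, grid$year, grid$j)
  max_obs <- stats::setNames(fit$intervals, fit$years)
  obs_depth <- max_obs[as.character(grid$year)]
  obs_depth[is.na(obs_depth)] <- 0L
  grid$projected <- grid$year > L | grid$j > obs_depth
  grid$death_prob_obs <- NA_real_
  if (!is.null(observed)) {
    idx <- match(paste(grid$year, grid$j), paste(observed$year, observed$interval))
    grid$death_prob_obs <- 1 - observed$r_int[idx]
  }
  grid <- grid[order(grid$j, grid$year), ]
  rownames(grid) <- NULL
  grid
}

#' Modeled survival curves for selected diagnosis years
#'
#' Cumulative net survival by time since diagnosis for each requested
#' diagnosis year (observed or projected).
#'
#' @param fit a converged `jp_fit`.
#' @param years diagnosis years to display.
#' @param t_max deepest follow-up time (default the fitted J).
#' @return data frame with columns `year`, `t`, `survival`.
#' @export
plot_survival_curves <- function(fit, years, t_max = NULL) {
  J <- length(fit$params$alphas)
  if (is.null(t_max)) t_max <- J
  stopifnot(t_max >= 1, t_max <= J)
  grid <- expand.grid(t = seq_len(t_max), year = years)
  grid$survival <- predict_cumulative_survival(fit$params, grid$year, grid$t)
  grid[order(grid$year, grid$t), c("year", "t", "survival")]
}

#' Segment-wise trend report
#'
#' One row per segment of the final model with AAC_S(t) for each requested
#' follow-up time and APC_D, each with its 95% CI and direction marker
#' (`up` / `down` / `ns`), plus a `highlight` flag for large trends
#' (any AAC_S above 1 percentage point or APC_D below -5 percent).
#'
#' @param fit a converged `jp_fit`.
#' @param t_values follow-up times for the AAC_S columns (default
#'   `c(1, 5)` capped at the fitted J).
#' @return a data frame, one row per segment.
#' @export
trend_table <- function(fit, t_values = c(1, 5)) {
  J <- length(fit$params$alphas)
  t_values <- t_values[t_values <= J]
  if (!length(t_values)) stop("no requested t within fitted follow-up", call. = FALSE)
  segs <- segment_bounds(fit)
  out <- data.frame(segment = segs$segment, start_year = segs$start,
                    end_year = segs$end)
  highlight <- rep(FALSE, nrow(out))
  for (t in sort(t_values, decreasing = TRUE)) {
    a <- aac_s(fit, t)
    out[[sprintf("aac_s_%d", t)]] <- a$estimate
    out[[sprintf("aac_s_%d_lo", t)]] <- a$ci_lo
    out[[sprintf("aac_s_%d_hi", t)]] <- a$ci_hi
    out[[sprintf("aac_s_%d_dir", t)]] <- a$direction
    highlight <- highlight | a$estimate > 1
  }
  p <- apc_d(fit)
  out$apc_d <- p$estimate
  out$apc_d_lo <- p$ci_lo
  out$apc_d_hi <- p$ci_hi
  out$apc_d_dir <- p$direction
  out$highlight <- highlight | p$estimate < -5
  out
}
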