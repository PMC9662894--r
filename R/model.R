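#' Joinpoint proportional-hazards model parameters
#'
#' The discrete-time model for grouped survival: the net (cancer-specific or
#' relative) survival of follow-up interval j for patients diagnosed in
#' calendar year x is
#' \deqn{s_j(x) = \exp\{-\exp(\alpha_j + h(x))\},}
#' where \eqn{\alpha_j} is the log of the baseline hazard mass of interval j
#' and \eqn{h(x) = \beta (x - a) + \sum_k \delta_k (x - \tau_k)^+} is a
#' continuous piecewise-linear calendar-year effect with joinpoints at years
#' \eqn{\tau_1 < \dots < \tau_K} and anchor year a (the first diagnosis year,
#' used for numerical conditioning; predictions are invariant to it).
#' The slope of the first segment is \eqn{\beta}; the slope after joinpoint k
#' is \eqn{\beta + \delta_1 + \dots + \delta_k}.
#'
#' @param alphas numeric vector of interval baseline log-hazards, one per
#'   follow-up interval 1..J.
#' @param beta slope of the first segment (per year of diagnosis, log-hazard
#'   scale).
#' @param deltas slope changes at the joinpoints (may be empty).
#' @param taus integer joinpoint years, strictly increasing, same length as
#'   `deltas`.
#' @param anchor calendar year treated as x = 0.
#' @return an object of class `jp_params`.
#' @export
jp_params <- function(alphas, beta = 0, deltas = numeric(), taus = numeric(),
                      anchor = 0) {
  if (length(deltas) != length(taus)) {
    stop("deltas and taus must have the same length", call. = FALSE)
  }
  if (length(taus) > 1L && any(diff(taus) <= 0)) {
    stop("joinpoint years must be strictly increasing", call. = FALSE)
  }
  stopifnot(all(is.finite(alphas)), is.finite(beta), all(is.finite(deltas)))
  structure(list(alphas = as.numeric(alphas), beta = as.numeric(beta),
                 deltas = as.numeric(deltas), taus = as.numeric(taus),
                 anchor = as.numeric(anchor)),
            class = "jp_params")
}

#' @export
print.jp_params <- function(x, ...) {
  K <- length(x$taus)
  cat(sprintf("Joinpoint model parameters: %d interval(s), %d joinpoint(s)%s\n",
              length(x$alphas), K,
              if (K) paste0(" at ", paste(x$taus, collapse = ", ")) else ""))
  cat("  alphas:", paste(signif(x$alphas, 4), collapse = ", "), "\n")
  cat(sprintf("  beta: %.5g (anchor year %g)\n", x$beta, x$anchor))
  if (K) cat("  deltas:", paste(signif(x$deltas, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Calendar-year log-hazard offset h(x)
#'
#' Evaluates the piecewise-linear effect
#' \eqn{h(x) = \beta (x - a) + \sum_k \delta_k (x - \tau_k)^+}, where
#' \eqn{(u)^+ = \max(u, 0)}. Defined for any finite x, including years
#' beyond the data range: for \eqn{x > \tau_K} every hinge is active, so
#' evaluation automatically extends the last segment linearly, which is how
#' survival projections are produced.
#'
#' @param x diagnosis year(s), vectorized.
#' @param params a [jp_params()].
#' @return numeric vector h(x).
#' @export
hazard_offset <- function(x, params) {
  stopifnot(inherits(params, "jp_params"), all(is.finite(x)))
  h <- params$beta * (x - params$anchor)
  for (k in seq_along(params$taus)) {
    h <- h + params$deltas[k] * pmax(x - params$taus[k], 0)
  }
  h
}

#' Model net interval survival s_j(x)
#'
#' @param params a [jp_params()].
#' @param x diagnosis year(s).
#' @param j follow-up interval(s) in 1..J; `x` and `j` are recycled.
#' @return `exp(-exp(alpha_j + h(x)))`, always inside (0, 1).
#' @export
predict_interval_survival <- function(params, x, j) {
  stopifnot(inherits(params, "jp_params"))
  if (any(j < 1 | j > length(params$alphas) | j != round(j))) {
    stop("interval index out of range 1..", length(params$alphas), call. = FALSE)
  }
  exp(-exp(params$alphas[j] + hazard_offset(x, params)))
}

#' Model conditional probability of cancer death in an interval
#'
#' `1 - predict_interval_survival(...)`: the probability of dying of the
#' disease in interval j given alive at its start, for diagnosis year x.
#'
#' @inheritParams predict_interval_survival
#' @export
conditional_death_prob <- function(params, x, j) {
  1 - predict_interval_survival(params, x, j)
}

#' Model cumulative net survival S(t | x)
#'
#' Product of the interval survivals over j = 1..t; algebraically equal to
#' the proportional-hazards power form \eqn{S_0(t)^{\exp h(x)}} with
#' \eqn{S_0(t) = \exp(-\sum_{j \le t} e^{\alpha_j})}.
#'
#' @param params a [jp_params()].
#' @param x diagnosis year(s).
#' @param t follow-up time in whole years, 1..J.
#' @return cumulative survival S(t | x), recycled over `x` and `t`.
#' @export
predict_cumulative_survival <- function(params, x, t) {
  stopifnot(inherits(params, "jp_params"))
  if (any(t < 1 | t > length(params$alphas) | t != round(t))) {
    stop("follow-up time out of range 1..", length(params$alphas), call. = FALSE)
  }
  lam0 <- cumsum(exp(params$alphas))   # cumulative baseline hazard mass
  exp(-lam0[t] * exp(hazard_offset(x, params)))
}

# --- likelihood machinery ----------------------------------------------------

# Assemble per-cell quantities once per fit: y (death fraction), n_eff
# (actuarial weight), e (expected interval survival multiplier; 1 outside
# relative mode), x, j.
likelihood_cells <- function(table) {
  obs <- observed_lifetable(table)
  e <- if (attr(table, "mode") == "relative") table$e_exp else rep(1, nrow(table))
  list(x = table$year, j = as.integer(table$interval),
       y = obs$q_obs, n_eff = obs$n_eff, e = as.numeric(e))
}

# design matrix: J interval indicators, centred year, one hinge per joinpoint
jp_design <- function(x, j, J, taus, anchor) {
  X <- matrix(0, length(x), J + 1L + length(taus))
  X[cbind(seq_along(j), j)] <- 1
  X[, J + 1L] <- x - anchor
  for (k in seq_along(taus)) X[, J + 1L + k] <- pmax(x - taus[k], 0)
  colnames(X) <- c(paste0("alpha", seq_len(J)), "beta",
                   if (length(taus)) paste0("delta", seq_along(taus)))
  X
}

# pi = 1 - e * exp(-exp(eta)): fitted all-cause interval death probability
fitted_pi <- function(eta, e) 1 - e * exp(-exp(eta))

CLIP <- 1e-12

#' Grouped-data log-likelihood of a joinpoint survival model
#'
#' Quasi-binomial log-likelihood over the (year, interval) cells of a
#' grouped life table. Each cell contributes
#' `n_eff * (y * log(pi) + (1 - y) * log(1 - pi))` with `y` the observed
#' death fraction `n_died / n_eff`, effective denominator
#' `n_eff = n_at_risk - n_lost/2`, and fitted all-cause interval death
#' probability `pi = 1 - e * s_j(x)` (`e` the expected interval survival in
#' relative mode, 1 otherwise). Fitted probabilities are clipped to
#' `[1e-12, 1 - 1e-12]`; a clip is counted and reported via the
#' `"n_clipped"` attribute.
#'
#' @param params a [jp_params()] dimensioned for the table's intervals.
#' @param table a validated [survtable()] (single cohort).
#' @return the scalar log-likelihood, with attribute `n_clipped`.
#' @export
jp_loglik <- function(params, table) {
  cells <- likelihood_cells(table)
  J <- max(cells$j)
  if (length(params$alphas) < J) {
    stop("params have ", length(params$alphas), " intervals but table needs ", J,
         call. = FALSE)
  }
  eta <- params$alphas[cells$j] + hazard_offset(cells$x, params)
  loglik_from_eta(eta, cells)
}

loglik_from_eta <- function(eta, cells) {
  pi <- fitted_pi(eta, cells$e)
  clipped <- sum(pi < CLIP | pi > 1 - CLIP)
  pi <- pmin(pmax(pi, CLIP), 1 - CLIP)
  ll <- sum(cells$n_eff * (cells$y * log(pi) + (1 - cells$y) * log1p(-pi)))
  attr(ll, "n_clipped") <- clipped
  ll
}

# gradient and (observed) hessian of the loglik wrt theta, given eta = X theta.
# d ll / d eta  = n_eff * mu * (y - pi) / pi,               mu = exp(eta)
# d2 ll / d eta2 = n_eff * [mu (y - pi)/pi - mu^2 y (1 - pi)/pi^2]
loglik_derivs <- function(eta, cells) {
  mu <- exp(eta)
  pi <- pmin(pmax(fitted_pi(eta, cells$e), CLIP), 1 - CLIP)
  u <- cells$n_eff * mu * (cells$y - pi) / pi
  d2 <- cells$n_eff * (mu * (cells$y - pi) / pi -
                         mu^2 * cells$y * (1 - pi) / pi^2)
  list(u = u, d2 = d2, mu = mu, pi = pi)
}

#' Maximum-likelihood fit at fixed joinpoint locations
#'
#' Maximizes [jp_loglik()] over the interval baselines, the first-segment
#' slope and the slope changes, holding the joinpoint years fixed, by
#' Fisher-scoring IRLS for the grouped binomial model with complementary
#' log-log link, offset structure from [hazard_offset()] and prior weights
#' `n_eff`. Step-halving is applied whenever a scoring step would decrease
#' the log-likelihood. The covariance of the free parameters is the inverse
#' of the observed information (negative Hessian) at the optimum, with the
#' joinpoint locations treated as fixed.
#'
#' @param table a validated single-cohort [survtable()] with at least two
#'   diagnosis years.
#' @param taus integer joinpoint years, strictly inside the table's year
#'   range (possibly empty for the no-joinpoint model).
#' @param control list of fit options: `max_iter` (default 100), `tol`
#'   (relative log-likelihood change, default 1e-8).
#' @return an object of class `jp_fit`: list with elements `params`
#'   ([jp_params()]), `loglik`, `cov` (free parameters, taus excluded),
#'   `n_cells`, `p` (parameter count J + 1 + 2K: joinpoint locations are
#'   counted), `bic`, `aic`, `converged`, `n_iter`, `n_clipped`, `mode`,
#'   `years` (diagnosis years used), `intervals` (per-year max interval).
#' @export
fit_fixed_joinpoints <- function(table, taus = numeric(), control = list()) {
  ctrl <- utils::modifyList(list(max_iter = 100L, tol = 1e-8), control)
  validate_survival_table(table)
  if (length(unique(cohort_key(table))) > 1L) {
    stop("fit requires a single cohort; use select_cohort() first", call. = FALSE)
  }
  years <- sort(unique(table$year))
  if (length(years) < 2L) stop("need at least two diagnosis years", call. = FALSE)
  taus <- sort(as.numeric(taus))
  if (length(taus)) {
    if (any(taus <= min(years)) || any(taus >= max(years))) {
      stop("joinpoints must lie strictly inside the diagnosis-year range",
           call. = FALSE)
    }
    bounds <- c(min(years), taus, max(years))
    for (m in seq_len(length(bounds) - 1L)) {
      n_in <- sum(years >= bounds[m] & years < bounds[m + 1L]) +
        (m == length(bounds) - 1L) * sum(years == bounds[m + 1L])
      if (n_in < 2L) {
        stop(sprintf("segment %d (%g to %g) contains fewer than two diagnosis years",
                     m, bounds[m], bounds[m + 1L]), call. = FALSE)
      }
    }
  }
  cells <- likelihood_cells(table)
  J <- max(cells$j)
  anchor <- min(years)
  X <- jp_design(cells$x, cells$j, J, taus, anchor)
  if (qr(X)$rank < ncol(X)) {
    stop("degenerate design: calendar-year columns are collinear for these joinpoints",
         call. = FALSE)
  }

  # start: crude per-interval baseline log-hazards from pooled death fractions
  theta <- numeric(ncol(X))
  for (jj in seq_len(J)) {
    sel <- cells$j == jj
    s0 <- sum(cells$n_eff[sel] * (1 - cells$y[sel])) /
      sum(cells$n_eff[sel] * cells$e[sel])
    s0 <- min(max(s0, 1e-6), 1 - 1e-6)
    theta[jj] <- log(-log(s0))
  }

  eta <- drop(X %*% theta)
  ll <- loglik_from_eta(eta, cells)
  converged <- FALSE
  iter <- 0L
  n_small <- 0L   # consecutive iterations with a negligible loglik change
  for (iter in seq_len(ctrl$max_iter)) {
    d <- loglik_derivs(eta, cells)
    score <- drop(crossprod(X, d$u))
    # primary stop: score equations satisfied (scaled by the loglik size);
    # fallback: loglik stalled on three consecutive iterations
    if (max(abs(score)) / (abs(ll) + 1) < 1e-7 || n_small >= 3L) {
      converged <- TRUE
      break
    }
    # Fisher weights: expected information, always positive
    w <- cells$n_eff * d$mu^2 * (1 - d$pi) / d$pi
    z <- eta + (cells$y - d$pi) / (d$mu * (1 - d$pi))
    fit_ls <- stats::lm.wfit(X, z, w)
    theta_new <- fit_ls$coefficients
    if (anyNA(theta_new)) {
      stop("degenerate design: IRLS normal equations are singular", call. = FALSE)
    }
    step <- theta_new - theta
    ll_new <- loglik_from_eta(drop(X %*% theta_new), cells)
    halvings <- 0L
    while (ll_new < ll && halvings < 30L) {
      step <- step / 2
      theta_new <- theta + step
      ll_new <- loglik_from_eta(drop(X %*% theta_new), cells)
      halvings <- halvings + 1L
    }
    n_small <- if (abs(ll_new - ll) < ctrl$tol * (abs(ll) + 1)) n_small + 1L else 0L
    theta <- theta_new
    eta <- drop(X %*% theta)
    ll <- ll_new
  }

  d <- loglik_derivs(eta, cells)
  info <- crossprod(X, -d$d2 * X)           # observed information
  cov <- tryCatch(solve(info), error = function(e) {
    matrix(NA_real_, ncol(X), ncol(X))
  })
  dimnames(cov) <- list(colnames(X), colnames(X))
  cov <- (cov + t(cov)) / 2

  K <- length(taus)
  params <- jp_params(alphas = theta[seq_len(J)], beta = theta[J + 1L],
                      deltas = if (K) theta[J + 1L + seq_len(K)] else numeric(),
                      taus = taus, anchor = anchor)
  n_cells <- length(cells$y)
  p <- J + 1L + 2L * K
  per_year <- tapply(cells$j, cells$x, max)
  structure(list(params = params, loglik = as.numeric(ll), cov = cov,
                 n_cells = n_cells, p = p,
                 bic = -2 * as.numeric(ll) + p * log(n_cells),
                 aic = -2 * as.numeric(ll) + 2 * p,
                 converged = converged, n_iter = iter,
                 n_clipped = attr(ll, "n_clipped"),
                 mode = attr(table, "mode"),
                 years = years,
                 intervals = as.integer(per_year[as.character(years)])),
            class = "jp_fit")
}

#' @export
print.jp_fit <- function(x, ...) {
  K <- length(x$params$taus)
  cat(sprintf("Joinpoint survival fit (%s mode): %d joinpoint(s)%s\n",
              x$mode, K,
              if (K) paste0(" at ", paste(x$params$taus, collapse = ", ")) else ""))
  cat(sprintf("  log-likelihood %.4f on %d cells (%d parameters); BIC %.2f, AIC %.2f\n",
              x$loglik, x$n_cells, x$p, x$bic, x$aic))
  cat(sprintf("  converged: %s after %d IRLS iteration(s)\n",
              if (x$converged) "yes" else "NO", x$n_iter))
  invisible(x)
}

#' @export
coef.jp_fit <- function(object, ...) {
  p <- object$params
  K <- length(p$taus)
  stats::setNames(c(p$alphas, p$beta, p$deltas),
                  c(paste0("alpha", seq_along(p$alphas)), "beta",
                    if (K) paste0("delta", seq_len(K))))
}

#' @export
vcov.jp_fit <- function(object, ...) object$cov

#' @export
logLik.jp_fit <- function(object, ...) {
  structure(object$loglik, df = object$p, nobs = object$n_cells,
            class = "logLik")
}
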