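#' Configuration for the grouped-survival simulator
#'
#' Defines a generative joinpoint truth from which grouped life tables are
#' drawn. Defaults emulate a registry-style extract: diagnosis years
#' 1975-2015 with up to 10 annual follow-up intervals, relative-survival
#' mode with a constant expected interval survival of 0.97 (a typical
#' annual expected survival for an elderly cancer population), 2% annual
#' loss to follow-up, a moderately lethal first year with flattening
#' hazard thereafter, and a single joinpoint in 1995 where a slow survival
#' improvement accelerates.
#'
#' @param year_range integer diagnosis years (vector; only min..max used).
#' @param J number of annual follow-up intervals.
#' @param cohort_size diagnoses per year (scalar or one per year).
#' @param baseline_interval_survival net interval survival s0_j at the
#'   anchor year, length J, values in (0,1).
#' @param beta first-segment slope on the log-hazard scale.
#' @param deltas,taus slope changes and joinpoint years (may be empty).
#' @param expected_interval_survival expected interval survival: a scalar,
#'   a length-J vector, or a function `(x, j)` returning values in (0,1].
#'   Ignored outside relative mode.
#' @param loss_prob per-interval probability of loss to follow-up.
#' @param mode survival mode, see [survtable()].
#' @param nonprop optional non-proportionality: a list
#'   `list(factor, j_min, break_year)` multiplying the calendar effect
#'   h(x) by `factor` for intervals `j >= j_min` of patients diagnosed
#'   after `break_year` — late intervals then improve faster (or slower)
#'   than early ones, violating the proportional-hazards assumption.
#' @param data_cutoff_year optional last follow-up calendar year: cells
#'   with `year + interval > data_cutoff_year` are not observed, giving
#'   recent diagnosis years incomplete follow-up as in registry data.
#' @param seed RNG seed (mandatory: tables must be reproducible).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(year_range = 1975:2015, J = 10L, cohort_size = 1000L,
                       baseline_interval_survival =
                         c(0.80, 0.88, 0.92, 0.94, 0.95, 0.96, 0.96, 0.97, 0.97, 0.97)[seq_len(J)],
                       beta = -0.005, deltas = -0.03, taus = 1995L,
                       expected_interval_survival = 0.97,
                       loss_prob = 0.02,
                       mode = c("relative", "cause_specific", "overall"),
                       nonprop = NULL, data_cutoff_year = NULL, seed) {
  mode <- match.arg(mode)
  if (missing(seed)) stop("a seed is required for reproducible simulation", call. = FALSE)
  J <- as.integer(J)
  years <- seq(min(year_range), max(year_range))
  cohort_size <- rep_len(as.integer(cohort_size), length(years))
  s0 <- baseline_interval_survival
  stopifnot(length(s0) == J, all(s0 > 0 & s0 < 1),
            length(deltas) == length(taus),
            loss_prob >= 0, loss_prob < 1, all(cohort_size >= 1))
  if (length(taus) && (any(taus <= min(years)) || any(taus >= max(years)))) {
    stop("generative joinpoints must lie strictly inside the year range", call. = FALSE)
  }
  if (!is.null(nonprop)) {
    stopifnot(is.list(nonprop),
              all(c("factor", "j_min", "break_year") %in% names(nonprop)))
  }
  e_fun <- expected_interval_survival
  if (!is.function(e_fun)) {
    e_vals <- rep_len(as.numeric(expected_interval_survival), J)
    stopifnot(all(e_vals > 0 & e_vals <= 1))
    e_fun <- function(x, j) e_vals[j]
  }
  structure(list(years = years, J = J, cohort_size = cohort_size,
                 s0 = s0, beta = beta, deltas = as.numeric(deltas),
                 taus = as.numeric(taus), e_fun = e_fun,
                 loss_prob = loss_prob, mode = mode, nonprop = nonprop,
                 data_cutoff_year = data_cutoff_year, seed = as.integer(seed)),
            class = "sim_config")
}

# generative parameters as a jp_params anchored at the first year
sim_params <- function(config) {
  jp_params(alphas = log(-log(config$s0)), beta = config$beta,
            deltas = config$deltas, taus = config$taus,
            anchor = min(config$years))
}

# generative net interval survival, including the non-proportional break
sim_interval_survival <- function(config, x, j) {
  p <- sim_params(config)
  h <- hazard_offset(x, p)
  if (!is.null(config$nonprop)) {
    np <- config$nonprop
    late <- j >= np$j_min & x > np$break_year
    h <- ifelse(late, h * np$factor, h)
  }
  exp(-exp(p$alphas[j] + h))
}

# run fn with a private RNG stream seeded from seed, restoring caller state
with_sim_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Simulate a grouped survival table from a joinpoint truth
#'
#' For each diagnosis year, walks the follow-up intervals: draws losses to
#' follow-up as Binomial(at-risk, loss_prob), computes the generative net
#' interval survival \eqn{s_j(x) = s_{0j}^{\exp h(x)}} (with the optional
#' non-proportional modification), forms the all-cause interval death
#' probability `pi = 1 - e_j(x) * s_j(x)` in relative mode (`1 - s_j(x)`
#' otherwise), draws deaths as Binomial over the half-loss actuarial
#' exposure, and decrements the at-risk count. The half-loss exposure
#' convention matches [observed_lifetable()], so the actuarial estimator is
#' unbiased for the generative interval survival. Deterministic given the
#' config seed; the caller's RNG state is left untouched.
#'
#' @param config a [sim_config()].
#' @return a validated [survtable()] with attribute `"sim_config"` echoing
#'   the configuration (including the seed).
#' @export
simulate_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  # validate generative probabilities before sampling
  chk <- expand.grid(x = range(config$years), j = seq_len(config$J))
  s_chk <- sim_interval_survival(config, chk$x, chk$j)
  e_chk <- vapply(seq_len(nrow(chk)),
                  function(i) config$e_fun(chk$x[i], chk$j[i]), numeric(1))
  pi_chk <- if (config$mode == "relative") 1 - e_chk * s_chk else 1 - s_chk
  if (any(!is.finite(pi_chk) | pi_chk < 0 | pi_chk >= 1)) {
    stop("generative death probability outside [0, 1): check slopes and baselines",
         call. = FALSE)
  }
  rows <- with_sim_seed(config$seed, function() {
    out <- vector("list", length(config$years))
    for (i in seq_along(config$years)) {
      x <- config$years[i]
      at_risk <- config$cohort_size[i]
      J_x <- config$J
      if (!is.null(config$data_cutoff_year)) {
        J_x <- min(config$J, config$data_cutoff_year - x)
        if (J_x < 1L) next
      }
      yr_rows <- vector("list", J_x)
      for (j in seq_len(J_x)) {
        if (at_risk == 0L) break
        lost <- stats::rbinom(1L, at_risk, config$loss_prob)
        s <- sim_interval_survival(config, x, j)
        e <- config$e_fun(x, j)
        pi <- if (config$mode == "relative") 1 - e * s else 1 - s
        exposure <- round(at_risk - lost / 2)
        died <- stats::rbinom(1L, exposure, pi)
        died <- min(died, at_risk - lost)
        yr_rows[[j]] <- data.frame(year = x, interval = j,
                                   n_at_risk = at_risk, n_lost = lost,
                                   n_died = died, e_exp = e)
        at_risk <- at_risk - lost - died
      }
      out[[i]] <- do.call(rbind, yr_rows)
    }
    do.call(rbind, out)
  })
  tab <- survtable(rows, mode = config$mode, strata = character())
  validate_survival_table(tab)
  attr(tab, "sim_config") <- config
  tab
}

#' Closed-form trend truth implied by a simulation config
#'
#' The generative counterparts of everything the pipeline estimates:
#' per-segment slope, APC_D and AAC_S(t) (telescoped over each segment),
#' plus closed-form S(t | x) and interval death probabilities, for
#' comparison against fitted values. Not defined under a non-proportional
#' config (the generative model is then outside the model class).
#'
#' @param config a [sim_config()].
#' @param t_values follow-up times for the AAC_S truth (default `c(1, 5)`
#'   capped at J).
#' @return list with `params` (the generative [jp_params()]), `segments`
#'   (data frame: segment, start, end, slope, apc_d, and one aac_s column
#'   per t), `surv` (function `(x, t)`), `death_prob` (function `(x, j)`).
#' @export
true_summaries <- function(config, t_values = c(1, 5)) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$nonprop)) {
    stop("closed-form truth is only defined for proportional configs", call. = FALSE)
  }
  p <- sim_params(config)
  t_values <- t_values[t_values <= config$J]
  bounds <- c(min(config$years), config$taus, max(config$years))
  K <- length(config$taus)
  segs <- data.frame(segment = 0:K, start = bounds[1:(K + 1)],
                     end = bounds[2:(K + 2)])
  segs$slope <- config$beta + c(0, cumsum(config$deltas))[segs$segment + 1]
  segs$apc_d <- apc_from_slope(segs$slope)
  for (t in t_values) {
    segs[[sprintf("aac_s_%d", t)]] <- 100 *
      (predict_cumulative_survival(p, segs$end, t) -
         predict_cumulative_survival(p, segs$start, t)) / (segs$end - segs$start)
  }
  list(params = p, segments = segs,
       surv = function(x, t) predict_cumulative_survival(p, x, t),
       death_prob = function(x, j) conditional_death_prob(p, x, j))
}
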