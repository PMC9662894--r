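#' Constraints on the joinpoint grid search
#'
#' @param max_joinpoints maximum number of joinpoints tested (0..5).
#' @param min_years_between minimum diagnosis years separating consecutive
#'   joinpoints (default 2).
#' @param min_years_before_first years at the start of the diagnosis-year
#'   range excluded from joinpoint placement (default 3).
#' @param min_years_after_last years at the end of the range excluded
#'   (default 5).
#' @param criterion information criterion used to pick the final model:
#'   `"bic"` (default) or `"aic"`.
#' @return an object of class `jp_constraints`.
#' @export
jp_constraints <- function(max_joinpoints = 0L, min_years_between = 2L,
                           min_years_before_first = 3L,
                           min_years_after_last = 5L,
                           criterion = c("bic", "aic")) {
  criterion <- match.arg(criterion)
  if (max_joinpoints < 0 || max_joinpoints > 5) {
    stop("max_joinpoints must be between 0 and 5", call. = FALSE)
  }
  if (min_years_between < 1 || min_years_before_first < 1 ||
      min_years_after_last < 1) {
    stop("spacing constraints must all be >= 1", call. = FALSE)
  }
  structure(list(max_joinpoints = as.integer(max_joinpoints),
                 min_years_between = as.integer(min_years_between),
                 min_years_before_first = as.integer(min_years_before_first),
                 min_years_after_last = as.integer(min_years_after_last),
                 criterion = criterion),
            class = "jp_constraints")
}

#' Enumerate admissible joinpoint configurations
#'
#' All strictly increasing K-tuples of integer years inside the diagnosis
#' range that satisfy the edge and spacing constraints, in deterministic
#' lexicographic order. K = 0 yields a single empty configuration.
#'
#' @param year_range integer vector of diagnosis years (only its range is
#'   used) or a length-2 c(min, max).
#' @param K number of joinpoints.
#' @param constraints a [jp_constraints()].
#' @return a list of integer vectors (each of length K).
#' @export
candidate_joinpoints <- function(year_range, K, constraints = jp_constraints()) {
  stopifnot(K >= 0)
  y0 <- min(year_range); y1 <- max(year_range)
  if (K == 0L) return(list(integer()))
  lo <- y0 + constraints$min_years_before_first
  hi <- y1 - constraints$min_years_after_last
  if (lo > hi) {
    stop(sprintf("no admissible joinpoint years: edge exclusions (%d before, %d after) exhaust %d-%d",
                 constraints$min_years_before_first,
                 constraints$min_years_after_last, y0, y1), call. = FALSE)
  }
  gap <- constraints$min_years_between
  out <- list()
  recurse <- function(prefix, next_lo) {
    k <- length(prefix)
    if (k == K) { out[[length(out) + 1L]] <<- prefix; return(invisible()) }
    remaining <- K - k - 1L
    for (tau in seq(next_lo, hi, by = 1L)) {
      if (tau + remaining * gap > hi) break
      recurse(c(prefix, tau), tau + gap)
    }
  }
  if (lo + (K - 1L) * gap > hi) {
    stop(sprintf("no admissible %d-joinpoint configuration: minimum spacing of %d years does not fit in %d-%d",
                 K, gap, lo, hi), call. = FALSE)
  }
  recurse(integer(), lo)
  out
}

#' Information criteria of a fitted joinpoint model
#'
#' `BIC = -2 l + p log(n)` and `AIC = -2 l + 2 p`, where l is the maximized
#' log-likelihood, n the number of (year, interval) data cells (the total
#' number of follow-up years over all diagnosis years), and p the parameter
#' count J + 1 + 2K: one baseline log-hazard per follow-up interval, the
#' first-segment slope, and, per joinpoint, its slope change and its
#' (searched) location.
#'
#' @param fit a `jp_fit` from [fit_fixed_joinpoints()].
#' @return named numeric vector `c(bic, aic)`.
#' @export
information_criteria <- function(fit) {
  stopifnot(inherits(fit, "jp_fit"))
  c(bic = -2 * fit$loglik + fit$p * log(fit$n_cells),
    aic = -2 * fit$loglik + 2 * fit$p)
}

#' Grid search over joinpoint number and location
#'
#' For each K from 0 to `max_joinpoints`, fits every admissible joinpoint
#' configuration by [fit_fixed_joinpoints()] and keeps the converged fit
#' with the largest log-likelihood (ties broken by the earliest
#' configuration in lexicographic order). The final model minimizes the
#' requested information criterion over the converged ladder entries.
#'
#' @param table a validated single-cohort [survtable()].
#' @param constraints a [jp_constraints()].
#' @param control fit options passed to [fit_fixed_joinpoints()].
#' @param progress print one line per K (the search is the slow part of a
#'   run).
#' @return an object of class `jp_ladder`: list with `fits` (best `jp_fit`
#'   per K, possibly with gaps where no candidate converged), `table` (a
#'   data frame mirroring the model-ladder report: K, joinpoint years, BIC,
#'   AIC, log-likelihood, converged, final flag), `selected_K`, `criterion`.
#' @export
grid_search <- function(table, constraints = jp_constraints(),
                        control = list(), progress = FALSE) {
  validate_survival_table(table)
  years <- sort(unique(table$year))
  fits <- list()
  warn_k <- integer()
  for (K in 0:constraints$max_joinpoints) {
    cands <- candidate_joinpoints(years, K, constraints)
    best <- NULL
    for (taus in cands) {
      f <- tryCatch(fit_fixed_joinpoints(table, taus, control),
                    error = function(e) NULL)
      if (is.null(f) || !f$converged) next
      if (is.null(best) || f$loglik > best$loglik + 1e-10) best <- f
    }
    if (is.null(best)) {
      warn_k <- c(warn_k, K)
    } else {
      fits[[as.character(K)]] <- best
    }
    if (progress) {
      message(sprintf("K = %d: %d candidate(s)%s", K, length(cands),
                      if (is.null(best)) ", none converged"
                      else sprintf(", best loglik %.4f", best$loglik)))
    }
  }
  if (length(warn_k)) {
    warning("no candidate converged for K = ", paste(warn_k, collapse = ", "),
            call. = FALSE)
  }
  if (!length(fits)) stop("grid search failed: no model converged", call. = FALSE)

  ladder <- do.call(rbind, lapply(fits, function(f) {
    data.frame(n_joinpoints = length(f$params$taus),
               joinpoints = paste(f$params$taus, collapse = ", "),
               bic = f$bic, aic = f$aic, loglik = f$loglik,
               converged = f$converged, final = FALSE,
               stringsAsFactors = FALSE)
  }))
  rownames(ladder) <- NULL
  crit <- ladder[[constraints$criterion]]
  sel <- which.min(crit)
  ladder$final[sel] <- TRUE
  structure(list(fits = fits, table = ladder,
                 selected_K = ladder$n_joinpoints[sel],
                 criterion = constraints$criterion,
                 constraints = constraints),
            class = "jp_ladder")
}

#' @export
print.jp_ladder <- function(x, ...) {
  cat(sprintf("Joinpoint model ladder (final model by %s):\n",
              toupper(x$criterion)))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Pick the final model from a ladder
#'
#' @param ladder a `jp_ladder` from [grid_search()].
#' @param criterion `"bic"` (default) or `"aic"`; overrides the criterion
#'   stored in the ladder.
#' @return the selected `jp_fit`.
#' @export
select_model <- function(ladder, criterion = NULL) {
  stopifnot(inherits(ladder, "jp_ladder"))
  if (is.null(criterion)) criterion <- ladder$criterion
  criterion <- match.arg(criterion, c("bic", "aic"))
  crit <- ladder$table[[criterion]]
  ladder$fits[[which.min(crit)]]
}
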