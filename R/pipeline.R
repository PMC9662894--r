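#' Run the full trend analysis for every cohort in an input file
#'
#' Batch analogue of an interactive session: reads a grouped survival
#' file, fans out over every cohort defined by the stratifier columns
#' (or the cohorts selected by `strata_filter`), and for each cohort runs
#' the joinpoint grid search, model selection, trend measures and
#' projections with the same settings. Per cohort it writes, under
#' `out_dir/<cohort>/`: `ladder.tsv` (the model ladder), `params.json`
#' (final-model parameters), `trends.tsv` (segment trend report),
#' `survival_by_year.tsv`, `death_prob_by_year.tsv`, `survival_curves.tsv`
#' (the three plotting datasets) and `projections.tsv`. A `run_log.txt`
#' and a `config.json` echo of the settings are written at the top level.
#' Failures are isolated per cohort: the run continues and the failure is
#' recorded in the log; the call errors only if every cohort fails.
#'
#' @param input path to a delimited survival file, or a [survtable()].
#' @param out_dir output directory (created if needed).
#' @param mode,column_map passed to [read_survival_table()] when `input`
#'   is a path.
#' @param strata_filter,year_min,year_max,max_followup cohort restriction
#'   applied before the fan-out.
#' @param max_joinpoints,criterion,min_years_between,min_years_before_first,min_years_after_last
#'   grid-search settings, see [jp_survfit()].
#' @param t_values follow-up times for trend reports and survival plots.
#' @param horizon projection horizon in years.
#' @param curve_years diagnosis years for the survival-curve dataset
#'   (default: first, middle and last fitted year).
#' @param control IRLS options.
#' @param quiet suppress per-cohort progress messages.
#' @return invisibly, a named list per cohort: the fitted `joinsurv` object
#'   or the error condition.
#' @export
run_analysis <- function(input, out_dir,
                         mode = c("relative", "cause_specific", "overall"),
                         column_map = NULL, strata_filter = NULL,
                         year_min = NULL, year_max = NULL, max_followup = NULL,
                         max_joinpoints = 2L, criterion = c("bic", "aic"),
                         min_years_between = 2L, min_years_before_first = 3L,
                         min_years_after_last = 5L,
                         t_values = c(1, 5), horizon = 5,
                         curve_years = NULL, control = list(), quiet = FALSE) {
  mode <- match.arg(mode)
  criterion <- match.arg(criterion)
  tab <- if (inherits(input, "survtable")) input
         else read_survival_table(input, mode, column_map)
  tab <- select_cohort(tab, strata_filter, year_min, year_max, max_followup)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run_log.txt")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  logmsg <- function(...) {
    msg <- sprintf(...)
    writeLines(msg, log_con)
    if (!quiet) message(msg)
  }
  settings <- list(mode = mode, max_joinpoints = max_joinpoints,
                   criterion = criterion,
                   min_years_between = min_years_between,
                   min_years_before_first = min_years_before_first,
                   min_years_after_last = min_years_after_last,
                   year_min = year_min, year_max = year_max,
                   max_followup = max_followup, t_values = t_values,
                   horizon = horizon)
  jsonlite::write_json(settings, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  keys <- unique(cohort_key(tab))
  st <- attr(tab, "strata")
  results <- list()
  for (key in keys) {
    label <- if (nzchar(key)) key else "all"
    logmsg("cohort '%s': starting", label)
    res <- tryCatch({
      sub <- tab[cohort_key(tab) == key, , drop = FALSE]
      rownames(sub) <- NULL
      sub <- structure(sub, mode = mode, strata = st,
                       class = c("survtable", "data.frame"))
      model <- withCallingHandlers(
        jp_survfit(sub, max_joinpoints, criterion, control = control),
        warning = function(w) {
          logmsg("cohort '%s': warning: %s", label, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      cdir <- file.path(out_dir, gsub("[^A-Za-z0-9_.-]+", "_", label))
      dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
      write_tsv <- function(d, f) {
        utils::write.table(d, file.path(cdir, f), sep = "\t",
                           row.names = FALSE, quote = FALSE)
      }
      write_tsv(model$ladder$table, "ladder.tsv")
      write_tsv(trend_table(model$fit, t_values), "trends.tsv")
      p <- model$fit$params
      jsonlite::write_json(
        list(alphas = p$alphas, beta = p$beta, deltas = p$deltas,
             taus = p$taus, anchor = p$anchor,
             loglik = model$fit$loglik, bic = model$fit$bic,
             aic = model$fit$aic, n_cells = model$fit$n_cells,
             n_parameters = model$fit$p, converged = model$fit$converged),
        file.path(cdir, "params.json"), digits = NA)
      J <- length(p$alphas)
      tv <- t_values[t_values <= J]
      write_tsv(plot_survival_by_year(model$fit, model$observed, tv, horizon),
                "survival_by_year.tsv")
      write_tsv(plot_death_prob_by_year(model$fit, model$observed, tv, horizon),
                "death_prob_by_year.tsv")
      cy <- curve_years
      if (is.null(cy)) {
        yrs <- model$fit$years
        cy <- unique(round(stats::quantile(yrs, c(0, 0.5, 1))))
      }
      write_tsv(plot_survival_curves(model$fit, cy), "survival_curves.tsv")
      proj <- withCallingHandlers(
        project_survival(model$fit, horizon, tv),
        warning = function(w) {
          logmsg("cohort '%s': caution: %s", label, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      write_tsv(proj, "projections.tsv")
      logmsg("cohort '%s': final model has %d joinpoint(s) [%s]",
             label, length(p$taus), toupper(criterion))
      model
    }, error = function(e) {
      logmsg("cohort '%s': FAILED: %s", label, conditionMessage(e))
      e
    })
    results[[label]] <- res
  }
  failed <- vapply(results, inherits, logical(1), "error")
  if (all(failed)) stop("all cohorts failed; see ", log_path, call. = FALSE)
  invisible(results)
}

#' Simulate a dataset to disk together with its generative truth
#'
#' Writes `survival_table.csv` (the simulated grouped table, readable by
#' [read_survival_table()]), `truth.tsv` (the closed-form per-segment trend
#' truth, when defined) and `sim_config.json` (an echo of the generative
#' settings including the seed).
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the simulated [survtable()].
#' @export
run_simulation <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  tab <- simulate_table(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_survival_table(tab, file.path(out_dir, "survival_table.csv"))
  if (is.null(config$nonprop)) {
    truth <- true_summaries(config)
    utils::write.table(truth$segments, file.path(out_dir, "truth.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  echo <- config[c("years", "J", "cohort_size", "s0", "beta", "deltas",
                   "taus", "loss_prob", "mode", "seed")]
  echo$nonprop <- config$nonprop
  echo$data_cutoff_year <- config$data_cutoff_year
  jsonlite::write_json(echo, file.path(out_dir, "sim_config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(tab)
}
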