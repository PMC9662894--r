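#' Grouped survival life tables
#'
#' A `survtable` is a validated data frame of grouped survival counts by
#' single calendar year of diagnosis (`year`) and annual follow-up interval
#' (`interval`, 1-based; interval j covers (j-1, j] years since diagnosis).
#' Each row carries the number alive at the start of the interval
#' (`n_at_risk`), the number lost to follow-up in the interval (`n_lost`),
#' the number of deaths in the interval (`n_died`; cause-specific or
#' all-cause depending on `mode`), and, in relative-survival mode, the
#' expected interval survival probability `e_exp` of a matched general
#' population. Additional columns are treated as cohort stratifiers
#' (site, sex, stage, ...).
#'
#' @param data a data frame with columns `year`, `interval`, `n_at_risk`,
#'   `n_lost`, `n_died` and, for `mode = "relative"`, `e_exp`; any other
#'   columns are stratifiers.
#' @param mode survival mode: `"relative"`, `"cause_specific"` or
#'   `"overall"`. In relative mode the likelihood multiplies model net
#'   survival by `e_exp`; the other two modes are computationally identical
#'   and differ only in what `n_died` counts.
#' @param strata character vector of stratifier column names; defaults to
#'   every column not among the canonical five (six in relative mode).
#' @return an object of class `survtable`: the sorted, validated data frame
#'   with attributes `mode` and `strata`.
#' @seealso [read_survival_table()], [select_cohort()], [observed_lifetable()]
#' @export
survtable <- function(data, mode = c("relative", "cause_specific", "overall"),
                      strata = NULL) {
  mode <- match.arg(mode)
  data <- as.data.frame(data)
  core <- c("year", "interval", "n_at_risk", "n_lost", "n_died", "e_exp")
  if (is.null(strata)) strata <- setdiff(names(data), core)
  missing_cols <- setdiff(c("year", "interval", "n_at_risk", "n_lost", "n_died"),
                          names(data))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (mode == "relative" && !"e_exp" %in% names(data)) {
    stop("relative-survival mode requires an expected interval survival column (e_exp)",
         call. = FALSE)
  }
  if (!"e_exp" %in% names(data)) data$e_exp <- NA_real_
  data <- data[c(strata, core)]
  ord <- do.call(order, data[c(strata, "year", "interval")])
  data <- data[ord, , drop = FALSE]
  rownames(data) <- NULL
  structure(data, mode = mode, strata = strata,
            class = c("survtable", "data.frame"))
}

#' @export
print.survtable <- function(x, ...) {
  cat(sprintf("Grouped survival table (%s mode): %d rows, diagnosis years %d-%d, intervals 1-%d\n",
              attr(x, "mode"), nrow(x), min(x$year), max(x$year), max(x$interval)))
  st <- attr(x, "strata")
  if (length(st)) cat("Stratifiers:", paste(st, collapse = ", "), "\n")
  NextMethod()
  invisible(x)
}

# cohort key: one label per row, "" when unstratified
cohort_key <- function(table) {
  st <- attr(table, "strata")
  if (!length(st)) return(rep("", nrow(table)))
  do.call(paste, c(unclass(table)[st], sep = " / "))
}

#' Validate a grouped survival table
#'
#' Checks the life-table invariants: integer years and intervals,
#' non-negative counts with `n_at_risk >= n_died + n_lost`, unique
#' (cohort, year, interval) cells, expected survival in (0, 1] in relative
#' mode, and coherence of consecutive intervals
#' (`n_at_risk[j+1] == n_at_risk[j] - n_died[j] - n_lost[j]`); a strict
#' shortfall means rows were truncated, which is rejected.
#'
#' @param table a [survtable()].
#' @return the table, invisibly, if valid; otherwise an error naming the
#'   offending row or (cohort, year, interval) cell.
#' @export
validate_survival_table <- function(table) {
  stopifnot(inherits(table, "survtable"))
  mode <- attr(table, "mode")
  bad_int <- which(table$year != round(table$year) |
                     table$interval != round(table$interval) |
                     table$interval < 1)
  if (length(bad_int)) {
    stop("non-integer year or invalid interval index at row(s) ",
         paste(utils::head(bad_int, 5L), collapse = ", "), call. = FALSE)
  }
  bad_neg <- which(table$n_at_risk < 0 | table$n_lost < 0 | table$n_died < 0)
  if (length(bad_neg)) {
    stop("negative count at row(s) ",
         paste(utils::head(bad_neg, 5L), collapse = ", "), call. = FALSE)
  }
  bad_sum <- which(table$n_died + table$n_lost > table$n_at_risk)
  if (length(bad_sum)) {
    stop("n_died + n_lost exceeds n_at_risk at row(s) ",
         paste(utils::head(bad_sum, 5L), collapse = ", "), call. = FALSE)
  }
  if (mode == "relative") {
    bad_e <- which(!is.finite(table$e_exp) | table$e_exp <= 0 | table$e_exp > 1)
    if (length(bad_e)) {
      stop("expected interval survival outside (0, 1] at row(s) ",
           paste(utils::head(bad_e, 5L), collapse = ", "), call. = FALSE)
    }
  }
  key <- paste(cohort_key(table), table$year, table$interval)
  if (anyDuplicated(key)) {
    stop("duplicate (cohort, year, interval) cell: ",
         key[anyDuplicated(key)], call. = FALSE)
  }
  # coherence within each (cohort, year) run of consecutive intervals
  grp <- paste(cohort_key(table), table$year)
  for (g in split(seq_len(nrow(table)), grp)) {
    rows <- g[order(table$interval[g])]
    j <- table$interval[rows]
    if (length(rows) > 1L) {
      consec <- which(diff(j) == 1L)
      a <- rows[consec]; b <- rows[consec + 1L]
      expect_next <- table$n_at_risk[a] - table$n_died[a] - table$n_lost[a]
      bad <- which(table$n_at_risk[b] != expect_next)
      if (length(bad)) {
        i <- bad[1L]
        stop(sprintf(
          "incoherent life table at (cohort '%s', year %d, interval %d): %d at risk next interval, expected %d",
          cohort_key(table)[a[i]], table$year[a[i]], table$interval[a[i]] + 1L,
          table$n_at_risk[b[i]], expect_next[i]), call. = FALSE)
      }
    }
  }
  invisible(table)
}

#' Read a grouped survival table from a delimited text file
#'
#' Reads a comma- or tab-delimited file with a header row. Canonical column
#' names are `Year`, `Interval`, `Alive_at_Start`, `Lost_to_Followup`,
#' `Died` and (relative mode) `Expected_Survival_Interval`; files with other
#' headers are handled through `column_map`. Any unmapped column is kept as
#' a cohort stratifier, except columns named in `ignore` (for precomputed
#' survival columns, which are accepted but not used: observed survival is
#' always re-derived from the counts).
#'
#' @param path path to the delimited file.
#' @param mode survival mode, see [survtable()].
#' @param column_map named character vector mapping canonical names
#'   (`year`, `interval`, `n_at_risk`, `n_lost`, `n_died`, `e_exp`) to the
#'   file's column names; defaults to the canonical header.
#' @param sep field delimiter; `NULL` (default) auto-detects comma vs tab
#'   from the header line.
#' @param ignore character vector of file columns to drop.
#' @return a validated [survtable()].
#' @export
read_survival_table <- function(path, mode = c("relative", "cause_specific", "overall"),
                                column_map = NULL, sep = NULL, ignore = character()) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  default_map <- c(year = "Year", interval = "Interval",
                   n_at_risk = "Alive_at_Start", n_lost = "Lost_to_Followup",
                   n_died = "Died", e_exp = "Expected_Survival_Interval")
  map <- default_map
  if (!is.null(column_map)) map[names(column_map)] <- column_map
  required <- c("year", "interval", "n_at_risk", "n_lost", "n_died",
                if (mode == "relative") "e_exp")
  absent <- required[!map[required] %in% names(raw)]
  if (length(absent)) {
    stop("input file lacks mapped column(s): ",
         paste(sprintf("%s (expected '%s')", absent, map[absent]), collapse = ", "),
         call. = FALSE)
  }
  present <- map[map %in% names(raw)]
  out <- raw[unname(present)]
  names(out) <- names(present)
  strata_cols <- setdiff(names(raw), c(unname(present), ignore))
  for (s in strata_cols) out[[s]] <- raw[[s]]
  for (col in c("year", "interval", "n_at_risk", "n_lost", "n_died")) {
    v <- out[[col]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      if (anyNA(vn)) {
        stop("non-numeric value in column '", map[col], "' at row ",
             which(is.na(vn))[1L], call. = FALSE)
      }
      out[[col]] <- vn
    }
  }
  tab <- survtable(out, mode = mode, strata = strata_cols)
  validate_survival_table(tab)
  tab
}

#' Write a grouped survival table to a delimited text file
#'
#' Inverse of [read_survival_table()] under the canonical header; reading
#' the written file back reproduces the counts and labels exactly.
#'
#' @param table a [survtable()].
#' @param path output path.
#' @param sep field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_survival_table <- function(table, path, sep = ",") {
  stopifnot(inherits(table, "survtable"))
  out <- as.data.frame(table)
  canon <- c(year = "Year", interval = "Interval", n_at_risk = "Alive_at_Start",
             n_lost = "Lost_to_Followup", n_died = "Died",
             e_exp = "Expected_Survival_Interval")
  if (attr(table, "mode") != "relative" && all(is.na(out$e_exp))) {
    out$e_exp <- NULL
    canon <- canon[names(canon) != "e_exp"]
  }
  names(out)[match(names(canon), names(out))] <- canon
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Restrict a survival table to one cohort, year window and follow-up depth
#'
#' @param table a [survtable()].
#' @param strata_filter named list/vector selecting stratifier values, e.g.
#'   `list(Stage = "Distant")`; keys must be stratifier columns.
#' @param year_min,year_max diagnosis-year window (inclusive); default the
#'   full range.
#' @param max_followup keep intervals `j <= max_followup`; restricting
#'   follow-up (e.g. to 2 or 5 years) is also the standard check of the
#'   proportional-hazards assumption across follow-up intervals.
#' @param require_single_cohort error if more than one cohort remains
#'   (model fitting is per cohort).
#' @return the restricted [survtable()] with updated metadata.
#' @export
select_cohort <- function(table, strata_filter = NULL,
                          year_min = NULL, year_max = NULL,
                          max_followup = NULL, require_single_cohort = FALSE) {
  stopifnot(inherits(table, "survtable"))
  st <- attr(table, "strata")
  keep <- rep(TRUE, nrow(table))
  if (!is.null(strata_filter)) {
    bad <- setdiff(names(strata_filter), st)
    if (length(bad)) {
      stop("unknown stratifier(s) in filter: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    for (k in names(strata_filter)) {
      keep <- keep & table[[k]] %in% strata_filter[[k]]
    }
  }
  if (is.null(year_min)) year_min <- min(table$year)
  if (is.null(year_max)) year_max <- max(table$year)
  if (year_min > year_max) stop("year_min exceeds year_max", call. = FALSE)
  keep <- keep & table$year >= year_min & table$year <= year_max
  if (!is.null(max_followup)) {
    if (max_followup < 1) stop("max_followup must be >= 1", call. = FALSE)
    keep <- keep & table$interval <= max_followup
  }
  if (!any(keep)) stop("cohort selection is empty", call. = FALSE)
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out <- structure(out, mode = attr(table, "mode"), strata = st,
                   class = c("survtable", "data.frame"))
  if (require_single_cohort && length(unique(cohort_key(out))) > 1L) {
    stop("filter matches more than one cohort: ",
         paste(unique(cohort_key(out)), collapse = "; "), call. = FALSE)
  }
  out
}

#' Actuarial life-table estimates from grouped counts
#'
#' Computes, for every (cohort, diagnosis year, interval) cell, the
#' effective number at risk under the actuarial half-loss correction
#' `n_eff = n_at_risk - n_lost/2`, the observed interval death probability
#' `q_obs = n_died / n_eff`, interval survival `1 - q_obs` (divided by the
#' expected interval survival in relative mode), the cumulative survival
#' `S_obs` as the running product over intervals, and its Greenwood
#' standard error `S_obs * sqrt(sum q / (n_eff (1 - q)))`.
#'
#' Observed relative survival may exceed 1 and is retained as data, not
#' clamped. An interval with `q_obs = 1` before the last follow-up interval
#' flags a degenerate cohort (survival hits zero) with a warning.
#'
#' @param table a validated [survtable()].
#' @return a data frame with one row per input cell: the stratifiers,
#'   `year`, `interval`, `n_eff`, `q_obs`, `s_int` (all-cause interval
#'   survival), `r_int` (interval survival on the net scale entering the
#'   model: `s_int / e_exp` in relative mode, `s_int` otherwise), `S_obs`
#'   (cumulative survival on the net scale), `se_S` (Greenwood), and
#'   `zero_flag` for degenerate intervals.
#' @export
observed_lifetable <- function(table) {
  validate_survival_table(table)
  mode <- attr(table, "mode")
  n_eff <- table$n_at_risk - table$n_lost / 2
  bad <- which(n_eff <= 0)
  if (length(bad)) {
    stop("effective number at risk is not positive at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  q <- table$n_died / n_eff
  s_int <- 1 - q
  r_int <- if (mode == "relative") s_int / table$e_exp else s_int
  out <- as.data.frame(table)[c(attr(table, "strata"), "year", "interval")]
  out$n_eff <- n_eff
  out$q_obs <- q
  out$s_int <- s_int
  out$r_int <- r_int
  out$S_obs <- NA_real_
  out$se_S <- NA_real_
  out$zero_flag <- FALSE
  grp <- paste(cohort_key(table), table$year)
  for (g in split(seq_len(nrow(out)), grp)) {
    rows <- g[order(out$interval[g])]
    out$S_obs[rows] <- cumprod(out$r_int[rows])
    gw_inc <- ifelse(out$q_obs[rows] < 1,
                     out$q_obs[rows] / (out$n_eff[rows] * (1 - out$q_obs[rows])),
                     Inf)
    out$se_S[rows] <- abs(out$S_obs[rows]) * sqrt(cumsum(gw_inc))
    deg <- which(out$q_obs[rows] >= 1)
    deg <- deg[deg < length(rows)]
    if (length(deg)) {
      out$zero_flag[rows[deg]] <- TRUE
      warning(sprintf("observed survival hits zero before the last interval (year %d, interval %d)",
                      out$year[rows[deg[1L]]], out$interval[rows[deg[1L]]]),
              call. = FALSE)
    }
  }
  out
}
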