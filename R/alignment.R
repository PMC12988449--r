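# Alignment of the harmonized table into the two analytic datasets:
# index-year series (each release's estimate for its own final year) and
# matched-year panels (all values ever published for one calendar year).

#' Default iteration-to-index-year map
#'
#' Each release iteration estimates the historical series up to a final
#' calendar year — its index year. For the eight release cycles 2010-2023 the
#' index year equals the release year. Override by passing an edited copy to
#' [build_index_year_series()].
#'
#' @param iterations integer vector of release years.
#' @return tibble (iteration, index_year).
#' @export
default_iteration_index_map <- function(iterations = c(2010L, 2013L, 2015L, 2016L,
                                                       2017L, 2019L, 2021L, 2023L)) {
  tibble::tibble(iteration = as.integer(iterations),
                 index_year = as.integer(iterations))
}

validate_index_map <- function(map) {
  map <- tibble::as_tibble(map)
  if (!all(c("iteration", "index_year") %in% names(map))) {
    rs_abort("index map needs columns iteration, index_year", "revstab_schema_error")
  }
  if (anyDuplicated(map$iteration)) {
    rs_abort("index map has duplicate iterations", "revstab_integrity_error")
  }
  if (any(map$index_year > map$iteration)) {
    rs_abort("index_year cannot exceed its iteration", "revstab_integrity_error")
  }
  map
}

# restrict to the default global/both/all stratum unless asked otherwise
apply_stratum <- function(table, stratum) {
  if (is.null(stratum)) return(table)
  for (col in names(stratum)) {
    table <- table[table[[col]] %in% stratum[[col]], ]
  }
  table
}

#' Build index-year series
#'
#' For each (risk, metric), collects the value each iteration published for
#' its own index year — the "year of analysis" comparison (e.g. the 2010
#' release's estimate for 2010 against the 2013 release's estimate for 2013).
#' Iterations lacking such a record are simply absent: there is no
#' interpolation or imputation anywhere in the pipeline.
#'
#' @param table harmonized, filtered estimate table.
#' @param index_map tibble (iteration, index_year); default
#'   [default_iteration_index_map()].
#' @param stratum named list restricting strata; default keeps the
#'   global / both-sex / all-cause slice. `NULL` keeps everything.
#' @return tidy tibble (risk_id, metric, iteration, year, value), ordered by
#'   risk, metric, iteration — one series per (risk_id, metric).
#' @export
build_index_year_series <- function(table,
                                    index_map = default_iteration_index_map(),
                                    stratum = list(sex = "both", location = "global",
                                                   cause_group = "all")) {
  index_map <- validate_index_map(index_map)
  tab <- apply_stratum(tibble::as_tibble(table), stratum)
  if (!nrow(tab)) {
    return(tibble::tibble(risk_id = character(0), metric = character(0),
                          iteration = integer(0), year = integer(0),
                          value = numeric(0)))
  }
  idx <- index_map$index_year[match(tab$iteration, index_map$iteration)]
  keep <- !is.na(idx) & tab$year == idx
  out <- tab[keep, c("risk_id", "metric", "iteration", "year", "value")]
  dplyr::arrange(out, .data$risk_id, .data$metric, .data$iteration)
}

#' Build matched-year revision panels
#'
#' For each (risk, metric, calendar year), collects every value published for
#' that same year by successive iterations — the original estimate plus all
#' its revisions. Years are never pooled: each panel holds exactly one
#' calendar year. Panels backed by fewer than `min_iterations` iterations are
#' not emitted (a single publication is not a revision).
#'
#' @param table harmonized, filtered estimate table.
#' @param min_iterations minimum number of distinct iterations per panel
#'   (default 2; values below 2 are a parameter error).
#' @param stratum as in [build_index_year_series()].
#' @return tidy tibble (risk_id, metric, year, iteration, value) ordered by
#'   panel then iteration — one panel per (risk_id, metric, year).
#' @export
build_matched_year_panels <- function(table, min_iterations = 2L,
                                      stratum = list(sex = "both", location = "global",
                                                     cause_group = "all")) {
  if (min_iterations < 2) {
    rs_abort("min_iterations must be at least 2", "revstab_parameter_error")
  }
  tab <- apply_stratum(tibble::as_tibble(table), stratum)
  out <- tab[, c("risk_id", "metric", "year", "iteration", "value")]
  out <- dplyr::arrange(out, .data$risk_id, .data$metric, .data$year, .data$iteration)
  out <- dplyr::group_by(out, .data$risk_id, .data$metric, .data$year)
  out <- dplyr::filter(out, dplyr::n_distinct(.data$iteration) >= min_iterations)
  dplyr::ungroup(out)
}

#' Build full time-series panels
#'
#' Groups per-year rows (with their uncertainty intervals) into one panel per
#' (risk, metric, iteration, sex, location, cause group), year-sorted. These
#' panels are the input to the uncertainty-interval consistency analysis
#' ([compare_iterations()]).
#'
#' @param table harmonized estimate table with per-year rows and optional UIs.
#' @param risks optional character vector of risk_ids to keep.
#' @param metrics optional metrics to keep.
#' @param iterations optional iterations to keep.
#' @param strata optional named list of stratum filters (e.g.
#'   `list(sex = c("male", "female"))`); `NULL` keeps all strata.
#' @return tidy tibble (risk_id, metric, iteration, sex, location,
#'   cause_group, year, value, ui_lower, ui_upper), year-sorted within panel.
#' @export
build_time_series_panels <- function(table, risks = NULL, metrics = NULL,
                                     iterations = NULL, strata = NULL) {
  tab <- tibble::as_tibble(table)
  if (!is.null(risks)) tab <- tab[tab$risk_id %in% risks, ]
  if (!is.null(metrics)) tab <- tab[tab$metric %in% metrics, ]
  if (!is.null(iterations)) tab <- tab[tab$iteration %in% iterations, ]
  tab <- apply_stratum(tab, strata)
  out <- tab[, c("risk_id", "metric", "iteration", "sex", "location",
                 "cause_group", "year", "value", "ui_lower", "ui_upper")]
  dplyr::arrange(out, .data$risk_id, .data$metric, .data$iteration,
                 .data$sex, .data$location, .data$cause_group, .data$year)
}
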