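# Consistency of later point estimates with earlier 95% uncertainty
# intervals: a revised point either falls below, within, or above the
# interval the previous release published for the same cell.

#' Classify a point estimate against an uncertainty interval
#'
#' Closed-interval containment: equality with a bound counts as within
#' ("outside" is read strictly). Vectorized.
#'
#' @param point numeric point estimate(s) from the later iteration.
#' @param lower,upper 95% UI bounds from the earlier iteration
#'   (`lower <= upper` required).
#' @return factor with levels below / within / above.
#' @export
classify_point_vs_ui <- function(point, lower, upper) {
  if (any(lower > upper, na.rm = TRUE)) {
    rs_abort("classify_point_vs_ui: lower > upper", "revstab_data_error")
  }
  factor(ifelse(point < lower, "below",
                ifelse(point > upper, "above", "within")),
         levels = c("below", "within", "above"))
}

#' Compare a later iteration's points with an earlier iteration's UIs
#'
#' Joins two release iterations cell-wise on the finest available
#' stratification (risk, metric, sex, location, cause group, year) and
#' classifies each later point against the earlier 95% UI. Cells present with
#' a UI in the reference but absent from the comparison — or vice versa, or
#' lacking a UI — are excluded and recorded in the [dropped_cells()] ledger,
#' so denominators are data-driven, never imputed.
#'
#' @param panels tidy time-series tibble from [build_time_series_panels()]
#'   containing both iterations.
#' @param reference_iteration iteration supplying the 95% UIs.
#' @param comparison_iteration later iteration supplying the point estimates.
#' @return tibble, one row per overlapping cell: identifying columns,
#'   `reference_iteration`, `comparison_iteration`, `ui_lower`, `ui_upper`,
#'   `point`, `verdict`. Warns (and returns zero rows) when nothing overlaps.
#' @export
compare_iterations <- function(panels, reference_iteration, comparison_iteration) {
  panels <- tibble::as_tibble(panels)
  cell_key <- c("risk_id", "metric", "sex", "location", "cause_group", "year")
  ref <- panels[panels$iteration == reference_iteration, ]
  cmp <- panels[panels$iteration == comparison_iteration, ]

  ref_has_ui <- !is.na(ref$ui_lower) & !is.na(ref$ui_upper)
  dropped <- tibble::tibble()
  if (any(!ref_has_ui)) {
    d <- ref[!ref_has_ui, cell_key]
    d$reason <- "missing-ui-in-reference"
    dropped <- dplyr::bind_rows(dropped, d)
    ref <- ref[ref_has_ui, ]
  }

  ref_ids <- do.call(paste, c(ref[cell_key], sep = "\r"))
  cmp_ids <- do.call(paste, c(cmp[cell_key], sep = "\r"))
  in_both_ref <- ref_ids %in% cmp_ids
  in_both_cmp <- cmp_ids %in% ref_ids
  if (any(!in_both_ref)) {
    d <- ref[!in_both_ref, cell_key]
    d$reason <- "missing-point-in-comparison"
    dropped <- dplyr::bind_rows(dropped, d)
  }
  if (any(!in_both_cmp)) {
    d <- cmp[!in_both_cmp, cell_key]
    d$reason <- "missing-cell-in-reference"
    dropped <- dplyr::bind_rows(dropped, d)
  }
  ref <- ref[in_both_ref, ]
  cmp <- cmp[in_both_cmp, ]
  k <- match(do.call(paste, c(ref[cell_key], sep = "\r")),
             do.call(paste, c(cmp[cell_key], sep = "\r")))
  out <- ref[, cell_key]
  out$reference_iteration <- as.integer(reference_iteration)
  out$comparison_iteration <- as.integer(comparison_iteration)
  out$ui_lower <- ref$ui_lower
  out$ui_upper <- ref$ui_upper
  out$point <- cmp$value[k]
  out$verdict <- classify_point_vs_ui(out$point, out$ui_lower, out$ui_upper)
  if (!nrow(out)) {
    rlang::warn("compare_iterations: no overlapping cells between iterations")
  }
  set_ledger(out, "dropped", dropped)
}

#' Tabulate UI coverage proportions
#'
#' Counts below / within / above verdicts per risk and metric (plus an
#' aggregate row per metric, `risk_id = "(all)"`) and derives the proportion
#' of revised points falling outside the prior 95% UI. Output is ordered by
#' `proportion_outside` descending; counts always conserve
#' (`n_below + n_within + n_above == n_total`).
#'
#' @param comparisons output of [compare_iterations()].
#' @return tibble: risk_id, metric, reference_iteration,
#'   comparison_iteration, n_total, n_below, n_within, n_above,
#'   proportion_outside, pct_outside (round-half-up integer percent).
#' @export
summarize_coverage <- function(comparisons) {
  if (!nrow(comparisons)) {
    rs_abort("summarize_coverage: empty comparisons", "revstab_data_error")
  }
  count_one <- function(df) {
    tibble::tibble(
      n_total = nrow(df),
      n_below = sum(df$verdict == "below"),
      n_within = sum(df$verdict == "within"),
      n_above = sum(df$verdict == "above")
    )
  }
  per_risk <- dplyr::reframe(
    dplyr::group_by(comparisons, .data$risk_id, .data$metric,
                    .data$reference_iteration, .data$comparison_iteration),
    count_one(dplyr::pick(dplyr::everything()))
  )
  agg <- dplyr::reframe(
    dplyr::group_by(comparisons, .data$metric,
                    .data$reference_iteration, .data$comparison_iteration),
    count_one(dplyr::pick(dplyr::everything()))
  )
  agg$risk_id <- "(all)"
  out <- dplyr::bind_rows(per_risk, agg)
  out$proportion_outside <- (out$n_below + out$n_above) / out$n_total
  out$pct_outside <- percent_of(out$n_below + out$n_above, out$n_total)
  dplyr::arrange(out, dplyr::desc(.data$proportion_outside))
}
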