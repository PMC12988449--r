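# Core instability statistics: range-to-mean ratio (R:M), coefficient of
# variation (CV), threshold classification, and group-level rollups.
#
# Interpretation conventions (strict "greater than" at every boundary):
#   R:M > 1    of concern        R:M > 1.5  extremely high
#   CV  > 0.2  high              CV  > 0.5  very high

#' Default instability thresholds
#'
#' @return named list with `rm = c(concern = 1, extreme = 1.5)` and
#'   `cv = c(high = 0.2, very_high = 0.5)`.
#' @export
default_thresholds <- function() {
  list(rm = c(concern = 1, extreme = 1.5),
       cv = c(high = 0.2, very_high = 0.5))
}

check_values <- function(values, what) {
  values <- as.numeric(values)
  if (anyNA(values)) {
    rs_abort(paste0(what, ": values must not contain NA"), "revstab_data_error")
  }
  if (any(values < 0)) {
    rs_abort(paste0(what, ": values must be nonnegative"), "revstab_data_error")
  }
  if (length(values) < 2) {
    rs_abort(paste0(what, ": need at least 2 values, got ", length(values)),
             "revstab_insufficient_data")
  }
  values
}

#' Range-to-mean ratio
#'
#' The primary instability statistic for a vector of repeated estimates of
#' the same quantity: `(max - min) / mean`. It is dimensionless, zero for a
#' constant series, and invariant to rescaling all values by a positive
#' constant. For a two-value panel `a <= b` it reduces to the closed form
#' `2 (b - a) / (a + b)`.
#'
#' The denominator is the arithmetic mean by default; a median denominator is
#' selectable for sensitivity analysis (`center = "median"`), but printed
#' summary rows in the literature are consistent with the mean reading.
#'
#' @param values numeric vector of nonnegative estimates, length >= 2.
#' @param center denominator: "mean" (default) or "median".
#' @return dimensionless ratio >= 0; exactly 0 when all values are equal
#'   (including the all-zero series).
#' @export
range_to_mean <- function(values, center = c("mean", "median")) {
  center <- match.arg(center)
  values <- check_values(values, "range_to_mean")
  rng <- max(values) - min(values)
  if (rng == 0) return(0)
  denom <- if (center == "mean") mean(values) else median(values)
  # nonnegative values with a nonzero range always have positive mean;
  # a zero median can still occur and is a data error for this ratio
  if (denom <= 0) {
    rs_abort("range_to_mean: nonpositive denominator", "revstab_data_error")
  }
  rng / denom
}

#' Coefficient of variation
#'
#' Standard deviation over mean for a vector of repeated estimates. The
#' default uses the sample standard deviation (n-1 denominator); because
#' revision panels are short (typically 2-8 values) the denominator choice is
#' material and therefore selectable.
#'
#' @param values numeric vector of nonnegative estimates, length >= 2.
#' @param sd_denominator "n-1" (sample SD, default) or "n" (population SD).
#' @return dimensionless ratio >= 0; exactly 0 for a constant series.
#' @export
coefficient_of_variation <- function(values, sd_denominator = c("n-1", "n")) {
  sd_denominator <- match.arg(sd_denominator)
  values <- check_values(values, "coefficient_of_variation")
  if (max(values) == min(values)) return(0)
  n <- length(values)
  s <- sd(values)
  if (sd_denominator == "n") s <- s * sqrt((n - 1) / n)
  m <- mean(values)
  if (m <= 0) {
    rs_abort("coefficient_of_variation: nonpositive mean", "revstab_data_error")
  }
  s / m
}

#' Classify instability against the standard thresholds
#'
#' Maps an R:M value (and optionally a CV) onto categorical flags using
#' strictly-greater-than comparisons: R:M of exactly 1 is still "low",
#' CV of exactly 0.5 is still "high".
#'
#' @param rm range-to-mean ratio (vectorized, >= 0).
#' @param cv optional coefficient of variation (vectorized, >= 0).
#' @param thresholds threshold list as from [default_thresholds()].
#' @return tibble with columns `rm_flag` (low / concern / extreme) and, when
#'   `cv` is given, `cv_flag` (low / high / very_high); factors with ordered
#'   levels.
#' @export
classify_instability <- function(rm, cv = NULL, thresholds = default_thresholds()) {
  out <- tibble::tibble(rm_flag = classify_rm(rm, thresholds$rm))
  if (!is.null(cv)) out$cv_flag <- classify_cv(cv, thresholds$cv)
  out
}

#' @rdname classify_instability
#' @export
classify_rm <- function(rm, thresholds = default_thresholds()$rm) {
  if (any(rm < 0, na.rm = TRUE)) {
    rs_abort("rm must be nonnegative", "revstab_data_error")
  }
  factor(ifelse(is.na(rm), NA_character_,
                ifelse(rm > thresholds[["extreme"]], "extreme",
                       ifelse(rm > thresholds[["concern"]], "concern", "low"))),
         levels = c("low", "concern", "extreme"))
}

#' @rdname classify_instability
#' @export
classify_cv <- function(cv, thresholds = default_thresholds()$cv) {
  if (any(cv < 0, na.rm = TRUE)) {
    rs_abort("cv must be nonnegative", "revstab_data_error")
  }
  factor(ifelse(is.na(cv), NA_character_,
                ifelse(cv > thresholds[["very_high"]], "very_high",
                       ifelse(cv > thresholds[["high"]], "high", "low"))),
         levels = c("low", "high", "very_high"))
}

#' Summarize one value panel
#'
#' Computes the full instability summary (order statistics, R:M, CV, flags)
#' for a single vector of panel values. Order of the values is irrelevant.
#'
#' @param values numeric vector of nonnegative estimates, length >= 2.
#' @param center,sd_denominator passed to [range_to_mean()] and
#'   [coefficient_of_variation()].
#' @param thresholds threshold list as from [default_thresholds()].
#' @return one-row tibble: n, min, max, mean, median, sd, rm, cv, rm_flag,
#'   cv_flag.
#' @export
summarize_panel <- function(values, center = "mean", sd_denominator = "n-1",
                            thresholds = default_thresholds()) {
  values <- check_values(values, "summarize_panel")
  rm_v <- range_to_mean(values, center = center)
  cv_v <- coefficient_of_variation(values, sd_denominator = sd_denominator)
  tibble::tibble(
    n = length(values),
    min = min(values), max = max(values),
    mean = mean(values), median = median(values), sd = sd(values),
    rm = rm_v, cv = cv_v,
    rm_flag = classify_rm(rm_v, thresholds$rm),
    cv_flag = classify_cv(cv_v, thresholds$cv)
  )
}

#' Summarize every panel in an aligned dataset
#'
#' Applies [summarize_panel()] to each series of an index-year alignment
#' (one panel per risk and metric) or each matched-year panel (one per risk,
#' metric and calendar year; the `context` column then reads
#' `"matched_year:<year>"`). Panels with fewer than two values are skipped
#' and recorded in the [skipped_panels()] ledger — they never contribute
#' zeros.
#'
#' @param panels tidy tibble from [build_index_year_series()] or
#'   [build_matched_year_panels()].
#' @param context "index_year" or "matched_year"; determines grouping and the
#'   context label.
#' @param center,sd_denominator,thresholds passed through to
#'   [summarize_panel()].
#' @return tibble of instability summaries, one row per panel, with
#'   identifying columns (risk_id, metric, context, and year for matched
#'   panels) followed by the summary fields.
#' @export
summarize_panels <- function(panels, context = c("index_year", "matched_year"),
                             center = "mean", sd_denominator = "n-1",
                             thresholds = default_thresholds()) {
  context <- match.arg(context)
  keys <- if (context == "index_year") c("risk_id", "metric") else
    c("risk_id", "metric", "year")
  panels <- tibble::as_tibble(panels)
  grouped <- dplyr::group_by(panels, dplyr::across(dplyr::all_of(keys)))
  sizes <- dplyr::summarise(grouped, n = dplyr::n(), .groups = "drop")
  small <- sizes[sizes$n < 2, ]
  ok <- dplyr::filter(grouped, dplyr::n() >= 2)
  out <- dplyr::reframe(ok, summarize_panel(.data$value, center = center,
                                            sd_denominator = sd_denominator,
                                            thresholds = thresholds))
  out <- dplyr::ungroup(out)
  out$context <- if (context == "index_year") "index_year" else
    paste0("matched_year:", out$year)
  front <- c(keys, "context")
  out <- out[, c(front, setdiff(names(out), front))]
  set_ledger(out, "skipped", small)
}

#' Group-level instability rollup
#'
#' Aggregates instability summaries to broad risk groups (level-1 categories)
#' or level-2 parents: how many estimates each group contributes, how many
#' exceed the R:M and CV thresholds, the median and range of R:M, and
#' report-style integer percentages (round-half-up, as in "17 of 34 (50%)").
#'
#' @param summaries output of [summarize_panels()].
#' @param hierarchy validated risk hierarchy (used to look up each risk's
#'   group or level-2 ancestor).
#' @param by "group" for level-1 broad categories (default) or "level2" for
#'   level-2 parent risks.
#' @param thresholds threshold list as from [default_thresholds()].
#' @return tibble, one row per (grouping value, metric): n_risks,
#'   n_flagged_rm_gt1, proportion_rm_gt1, pct_rm_gt1, median_rm, rm_min,
#'   rm_max, median_cv, prop_cv_high, prop_cv_very_high, pct_cv_high,
#'   pct_cv_very_high.
#' @export
summarize_group <- function(summaries, hierarchy, by = c("group", "level2"),
                            thresholds = default_thresholds()) {
  by <- match.arg(by)
  if (!nrow(summaries)) {
    rs_abort("summarize_group: empty summaries", "revstab_data_error")
  }
  h <- tibble::as_tibble(hierarchy)
  if (by == "group") {
    key <- h$group[match(summaries$risk_id, h$risk_id)]
  } else {
    key <- level_k_ancestor(h, summaries$risk_id, k = 2L)
  }
  df <- summaries
  df$grouping <- key
  rm_cut <- thresholds$rm[["concern"]]
  cv_hi <- thresholds$cv[["high"]]
  cv_vhi <- thresholds$cv[["very_high"]]
  out <- dplyr::summarise(
    dplyr::group_by(df, .data$grouping, .data$metric),
    n_risks = dplyr::n(),
    n_flagged_rm_gt1 = sum(.data$rm > rm_cut),
    proportion_rm_gt1 = mean(.data$rm > rm_cut),
    median_rm = median(.data$rm),
    rm_min = min(.data$rm),
    rm_max = max(.data$rm),
    median_cv = median(.data$cv),
    n_cv_high = sum(.data$cv > cv_hi),
    n_cv_very_high = sum(.data$cv > cv_vhi),
    prop_cv_high = mean(.data$cv > cv_hi),
    prop_cv_very_high = mean(.data$cv > cv_vhi),
    .groups = "drop"
  )
  out$pct_rm_gt1 <- percent_of(out$n_flagged_rm_gt1, out$n_risks)
  out$pct_cv_high <- percent_of(out$n_cv_high, out$n_risks)
  out$pct_cv_very_high <- percent_of(out$n_cv_very_high, out$n_risks)
  dplyr::arrange(out, .data$metric, dplyr::desc(.data$proportion_rm_gt1))
}

# ancestor risk_id at level k for arbitrary risk ids (NA when above level k)
level_k_ancestor <- function(h, risk_ids, k) {
  anc <- risk_ids
  lev <- h$level[match(anc, h$risk_id)]
  repeat {
    up <- !is.na(lev) & lev > k
    if (!any(up)) break
    anc[up] <- h$parent_id[match(anc[up], h$risk_id)]
    lev[up] <- lev[up] - 1
  }
  anc[is.na(lev) | lev < k] <- NA_character_
  anc
}
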