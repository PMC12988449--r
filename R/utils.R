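# Shared helpers: error signalling, rounding conventions, ledger attributes.

rs_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "revstab_error"), ...)
}

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even ("banker's rounding"), which is not
#' how proportions are conventionally reported in epidemiology tables: 21.48%
#' prints as 21%, but 50.5% prints as 51%, never 50%. `round_half_up()`
#' implements the report-table convention (half rounds up for nonnegative
#' input).
#'
#' @param x numeric vector.
#' @param digits integer; decimal places to keep (default 0).
#' @return numeric vector rounded half-up at `digits` decimals.
#' @examples
#' round_half_up(21.48) # 21
#' round_half_up(0.5)   # 1
#' round(0.5)           # 0 under banker's rounding
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  floor(x * scale + 0.5) / scale
}

#' Integer percentage in report style
#'
#' Formats a count out of a denominator as a whole-number percentage using
#' round-half-up, the convention used in report tables such as
#' "145 of 675 (21%)".
#'
#' @param numerator,denominator nonnegative counts (vectorized).
#' @return numeric vector of integer-valued percentages.
#' @examples
#' percent_of(17, 34)   # 50
#' percent_of(145, 675) # 21
#' @export
percent_of <- function(numerator, denominator) {
  round_half_up(100 * numerator / denominator)
}

# Ledger attributes: several stages exclude records with a reason rather than
# dropping them silently. The excluded rows travel on the returned table as an
# attribute so record counts always reconcile.

set_ledger <- function(x, name, value) {
  attr(x, name) <- value
  x
}

#' Exclusion ledger of a filtered table
#'
#' @param x a table returned by [filter_analysis_set()].
#' @return tibble of excluded records with a `reason` column (empty tibble if
#'   nothing was excluded).
#' @export
exclusion_ledger <- function(x) {
  led <- attr(x, "exclusions", exact = TRUE)
  if (is.null(led)) tibble::tibble() else led
}

#' Unmapped-name report of a harmonized table
#'
#' @param x a table returned by [harmonize()].
#' @return tibble of raw names that had no harmonization entry, with record
#'   counts per (raw name, iteration).
#' @export
unmapped_report <- function(x) {
  rep <- attr(x, "unmapped", exact = TRUE)
  if (is.null(rep)) tibble::tibble() else rep
}

#' Dropped-cell ledger of an uncertainty-interval comparison
#'
#' @param x a table returned by [compare_iterations()].
#' @return tibble of cells present on only one side of the comparison, with a
#'   `reason` column.
#' @export
dropped_cells <- function(x) {
  led <- attr(x, "dropped", exact = TRUE)
  if (is.null(led)) tibble::tibble() else led
}

#' Skipped-panel ledger of an instability summary
#'
#' @param x a table returned by [summarize_panels()].
#' @return tibble of panels skipped because fewer than two values were
#'   available.
#' @export
skipped_panels <- function(x) {
  led <- attr(x, "skipped", exact = TRUE)
  if (is.null(led)) tibble::tibble() else led
}
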