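# End-to-end orchestration: ingest -> harmonize -> filter -> align ->
# instability metrics -> UI coverage -> ranks, written out as a tidy-CSV
# report bundle with a checksummed manifest.

#' Pipeline run configuration
#'
#' Collects every knob of a pipeline run. Thresholds default to the standard
#' interpretation cutoffs (R:M > 1 of concern, > 1.5 extremely high;
#' CV > 0.2 high, > 0.5 very high); nothing is hard-coded downstream.
#'
#' @param estimates path to the estimates CSV, or an in-memory canonical
#'   table.
#' @param harmonization_map path or tibble (raw_name, iteration, risk_id).
#' @param hierarchy path or tibble (risk_id, canonical_name, level,
#'   parent_id, group).
#' @param out_dir output directory for the report bundle.
#' @param schema optional column mapping for [read_estimates_csv()].
#' @param index_map iteration-to-index-year map.
#' @param drop_levels,exclude_risks,min_iterations filter rules for
#'   [filter_analysis_set()].
#' @param thresholds instability thresholds ([default_thresholds()]).
#' @param center,sd_denominator statistic options
#'   (see [range_to_mean()], [coefficient_of_variation()]).
#' @param ui_pairs list of `c(reference, comparison)` iteration pairs for the
#'   UI-consistency analysis; `NULL` skips it.
#' @param ui_risks risk_ids to restrict the UI analysis to (`NULL` = all).
#' @param rank_risk_set risk_ids to rank (`NULL` skips ranking).
#' @return a `run_config` list.
#' @export
run_config <- function(estimates, harmonization_map, hierarchy, out_dir,
                       schema = NULL,
                       index_map = default_iteration_index_map(),
                       drop_levels = 4L,
                       exclude_risks = default_exclusions(),
                       min_iterations = 2L,
                       thresholds = default_thresholds(),
                       center = "mean",
                       sd_denominator = "n-1",
                       ui_pairs = list(c(2019L, 2021L), c(2021L, 2023L)),
                       ui_risks = NULL,
                       rank_risk_set = NULL) {
  if (any(unlist(thresholds) <= 0)) {
    rs_abort("thresholds must be positive", "revstab_config_error")
  }
  if (thresholds$rm[["concern"]] >= thresholds$rm[["extreme"]] ||
      thresholds$cv[["high"]] >= thresholds$cv[["very_high"]]) {
    rs_abort("thresholds must be ordered (concern < extreme, high < very_high)",
             "revstab_config_error")
  }
  structure(list(
    estimates = estimates, harmonization_map = harmonization_map,
    hierarchy = hierarchy, out_dir = out_dir, schema = schema,
    index_map = index_map, drop_levels = drop_levels,
    exclude_risks = exclude_risks, min_iterations = min_iterations,
    thresholds = thresholds, center = center, sd_denominator = sd_denominator,
    ui_pairs = ui_pairs, ui_risks = ui_risks, rank_risk_set = rank_risk_set
  ), class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    rs_abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)),
             "revstab_pipeline_error", parent = e)
  })
}

#' Run the full instability pipeline
#'
#' Executes ingest, harmonization, analysis-set filtering, both alignments,
#' instability summaries (index-year and matched-year), group rollups, the
#' CV distribution, UI coverage for each configured iteration pair, and rank
#' trajectories, then writes the report bundle to `out_dir`:
#'
#' * `instability_summaries.csv` — one row per panel (the per-risk summary
#'   table analogue);
#' * `matched_year_rm_matrix.csv` — risks x calendar years matrix of
#'   matched-year R:M (heatmap analogue);
#' * `cv_distribution.csv` — all CV values with flags (box-plot analogue);
#' * `group_summaries.csv` — level-1 group rollups;
#' * `ui_comparisons.csv` / `coverage_summaries.csv` — UI consistency
#'   (stacked-bar analogue);
#' * `rank_trajectories.csv` — per-iteration ranks;
#' * `exclusions.csv`, `unmapped.csv`, `skipped_panels.csv` — the ledgers;
#' * `manifest.yaml` — config echo, input checksums, record reconciliation
#'   and an MD5 checksum for every output file.
#'
#' Any stage error aborts with a stage-named message and removes partial
#' outputs. Re-running the same configuration reproduces byte-identical
#' files.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the in-memory results (`table`,
#'   `summaries_index`, `summaries_matched`, `groups`, `coverage`, `ranks`,
#'   `manifest`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) {
    rs_abort("config must come from run_config()", "revstab_config_error")
  }
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character(0)
  emit <- function(df, file) {
    p <- file.path(out_dir, file)
    readr::write_csv(tibble::as_tibble(df), p, na = "", progress = FALSE)
    written <<- c(written, p)
    p
  }
  on_fail <- function(e) {
    unlink(written)
    stop(e)
  }

  tryCatch({
    input_paths <- Filter(is.character, list(
      estimates = config$estimates,
      harmonization_map = config$harmonization_map,
      hierarchy = config$hierarchy
    ))

    raw <- stage("ingest", {
      if (is.character(config$estimates)) {
        read_estimates_csv(config$estimates, schema = config$schema)
      } else as_estimate_table(config$estimates)
    })
    hierarchy <- stage("ingest", {
      if (is.character(config$hierarchy)) read_risk_hierarchy(config$hierarchy)
      else validate_risk_hierarchy(config$hierarchy)
    })
    map <- stage("ingest", {
      if (is.character(config$harmonization_map)) {
        read_harmonization_map(config$harmonization_map, hierarchy)
      } else validate_harmonization_map(config$harmonization_map, hierarchy)
    })

    harmonized <- stage("harmonize", harmonize(raw, map, hierarchy))
    unmapped <- unmapped_report(harmonized)

    analysis <- stage("filter", filter_analysis_set(
      harmonized, drop_levels = config$drop_levels,
      exclude_risks = config$exclude_risks,
      min_iterations = config$min_iterations
    ))
    exclusions <- exclusion_ledger(analysis)

    index_series <- stage("align", build_index_year_series(analysis, config$index_map))
    matched <- stage("align", build_matched_year_panels(analysis, config$min_iterations))

    sum_index <- stage("metrics", summarize_panels(
      index_series, "index_year", center = config$center,
      sd_denominator = config$sd_denominator, thresholds = config$thresholds))
    sum_matched <- stage("metrics", summarize_panels(
      matched, "matched_year", center = config$center,
      sd_denominator = config$sd_denominator, thresholds = config$thresholds))
    skipped <- dplyr::bind_rows(skipped_panels(sum_index), skipped_panels(sum_matched))
    all_sum <- dplyr::bind_rows(sum_index, sum_matched)

    groups <- stage("metrics", summarize_group(all_sum, hierarchy, by = "group",
                                               thresholds = config$thresholds))

    rm_matrix <- stage("metrics", tidyr::pivot_wider(
      sum_matched[, c("risk_id", "metric", "year", "rm")],
      names_from = "year", values_from = "rm", names_sort = TRUE))

    coverage <- NULL
    comparisons <- tibble::tibble()
    if (length(config$ui_pairs)) {
      ts <- stage("ui_coverage", build_time_series_panels(
        harmonized, risks = config$ui_risks))
      comp_list <- list()
      for (pair in config$ui_pairs) {
        cmp <- stage("ui_coverage", suppressWarnings(
          compare_iterations(ts, pair[1], pair[2])))
        if (nrow(cmp)) comp_list[[length(comp_list) + 1]] <- cmp
      }
      if (length(comp_list)) {
        comparisons <- dplyr::bind_rows(comp_list)
        coverage <- stage("ui_coverage", summarize_coverage(comparisons))
      }
    }

    ranks <- NULL
    if (!is.null(config$rank_risk_set)) {
      nm <- setNames(hierarchy$canonical_name, hierarchy$risk_id)
      ranks <- stage("ranks", rank_trajectories(index_series,
                                                config$rank_risk_set, names = nm))
    }

    stage("report", {
      emit(all_sum, "instability_summaries.csv")
      emit(rm_matrix, "matched_year_rm_matrix.csv")
      emit(all_sum[, c("risk_id", "metric", "context", "n", "cv", "cv_flag")],
           "cv_distribution.csv")
      emit(groups, "group_summaries.csv")
      if (nrow(comparisons)) emit(comparisons, "ui_comparisons.csv")
      if (!is.null(coverage)) emit(coverage, "coverage_summaries.csv")
      if (!is.null(ranks)) emit(ranks$ranks, "rank_trajectories.csv")
      emit(exclusions, "exclusions.csv")
      emit(unmapped, "unmapped.csv")
      emit(skipped, "skipped_panels.csv")
    })

    manifest <- stage("report", {
      cfg_echo <- config[setdiff(names(config), c("estimates", "harmonization_map",
                                                  "hierarchy"))]
      cfg_echo$index_map <- as.data.frame(config$index_map)
      m <- list(
        package = "revstab",
        version = as.character(utils::packageVersion("revstab")),
        config = cfg_echo,
        inputs = lapply(input_paths, function(p) list(
          path = p, md5 = unname(tools::md5sum(p)))),
        records = list(
          input = nrow(raw),
          unmapped = sum(unmapped$n_records %||% 0L),
          excluded = nrow(exclusions),
          analyzed = nrow(analysis)
        ),
        outputs = lapply(written, function(p) list(
          file = basename(p), md5 = unname(tools::md5sum(p))))
      )
      stopifnot(m$records$input == m$records$analyzed + m$records$excluded +
                  m$records$unmapped)
      mp <- file.path(out_dir, "manifest.yaml")
      yaml::write_yaml(m, mp)
      written <<- c(written, mp)
      m
    })

    invisible(list(table = analysis, summaries_index = sum_index,
                   summaries_matched = sum_matched, groups = groups,
                   coverage = coverage, comparisons = comparisons,
                   ranks = ranks, manifest = manifest, files = written))
  }, error = on_fail)
}

`%||%` <- function(a, b) if (is.null(a) || !length(a)) b else a
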