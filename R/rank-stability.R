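# Ranking churn: rank risks by attributable burden within each release
# iteration and quantify how long ranks persist across iterations.

#' Rank risks within one iteration
#'
#' Rank 1 is the largest burden. Ties are broken deterministically by
#' lexicographic order of the display name (canonical_name when present,
#' otherwise risk_id), so the ranks are always a permutation of 1..K.
#'
#' @param values tibble with columns `risk_id`, `value` and optionally
#'   `canonical_name`.
#' @return the input with a `rank` column added, sorted by rank.
#' @export
rank_within_iteration <- function(values) {
  values <- tibble::as_tibble(values)
  if (!nrow(values)) {
    rs_abort("rank_within_iteration: empty input", "revstab_parameter_error")
  }
  if (any(values$value < 0)) {
    rs_abort("rank_within_iteration: values must be nonnegative", "revstab_data_error")
  }
  name <- if ("canonical_name" %in% names(values)) values$canonical_name else values$risk_id
  ord <- order(-values$value, name)
  out <- values[ord, ]
  out$rank <- seq_len(nrow(out))
  out
}

#' Rank trajectories across iterations
#'
#' Ranks a fixed, comparable risk set within every iteration of an index-year
#' alignment and summarizes each risk's trajectory: the longest run of
#' consecutive iterations with an unchanged rank, and the range of ranks
#' visited. Rank numbers are only comparable across iterations when the risk
#' set is identical, so iterations missing any member of `risk_set` are
#' excluded from the ranking (and listed in the `dropped_iterations`
#' element) rather than ranked on a shrunken set.
#'
#' @param series tidy index-year series from [build_index_year_series()].
#' @param risk_set character vector of risk_ids to rank (must be nonempty);
#'   ranking across hierarchy levels is the caller's responsibility to avoid.
#' @param names optional named character vector (risk_id -> display name)
#'   used for tie-breaking and output.
#' @return object of class `rank_trajectories`: list with
#'   * `ranks` — tibble (risk_id, metric, iteration, rank);
#'   * `summary` — tibble (risk_id, metric, n_iterations,
#'     max_consecutive_constant, range_of_ranks, first_rank, last_rank);
#'   * `dropped_iterations` — tibble (metric, iteration, missing) of
#'     iterations excluded for incomplete membership.
#' @export
rank_trajectories <- function(series, risk_set, names = NULL) {
  if (length(risk_set) == 0) {
    rs_abort("rank_trajectories: empty risk_set", "revstab_parameter_error")
  }
  series <- tibble::as_tibble(series)
  sub <- series[series$risk_id %in% risk_set, ]
  if (!is.null(names)) {
    sub$canonical_name <- unname(names[sub$risk_id])
  }

  ranks <- tibble::tibble()
  dropped <- tibble::tibble()
  for (m in sort(unique(sub$metric))) {
    dm <- sub[sub$metric == m, ]
    for (it in sort(unique(dm$iteration))) {
      di <- dm[dm$iteration == it, ]
      missing <- setdiff(risk_set, di$risk_id)
      if (length(missing)) {
        dropped <- dplyr::bind_rows(dropped, tibble::tibble(
          metric = m, iteration = it, missing = paste(sort(missing), collapse = ";")
        ))
        next
      }
      r <- rank_within_iteration(di[, intersect(c("risk_id", "canonical_name", "value"),
                                                names(di))])
      ranks <- dplyr::bind_rows(ranks, tibble::tibble(
        risk_id = r$risk_id, metric = m, iteration = it, rank = r$rank
      ))
    }
  }

  if (nrow(ranks)) {
    summary <- dplyr::summarise(
      dplyr::group_by(dplyr::arrange(ranks, .data$iteration),
                      .data$risk_id, .data$metric),
      n_iterations = dplyr::n(),
      max_consecutive_constant = max(rle(.data$rank)$lengths),
      range_of_ranks = max(.data$rank) - min(.data$rank),
      first_rank = dplyr::first(.data$rank),
      last_rank = dplyr::last(.data$rank),
      .groups = "drop"
    )
  } else {
    summary <- tibble::tibble()
  }
  structure(list(ranks = ranks, summary = summary, dropped_iterations = dropped),
            class = "rank_trajectories")
}

#' @export
print.rank_trajectories <- function(x, ...) {
  cat("Rank trajectories:", nrow(x$summary), "risk-metric trajectories over",
      length(unique(x$ranks$iteration)), "iterations\n")
  if (nrow(x$dropped_iterations)) {
    cat("Dropped iterations (incomplete risk set):",
        nrow(x$dropped_iterations), "\n")
  }
  print(x$summary, ...)
  invisible(x)
}
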