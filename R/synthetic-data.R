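# Seeded lognormal revision-process generator.
#
# Model for the value a release iteration i publishes for risk r in calendar
# year y:
#
#   V_{r,i,y} = A_r * exp(g_r * (y - y0)) * exp(delta_{r,i}) * exp(eps_{r,i,y})
#
#   A_r      baseline burden, log-uniform over baseline_range
#   g_r      per-year log-linear growth (a smooth true trend)
#   delta    per-iteration systematic revision shift ~ N(0, tau^2);
#            independent per iteration, or a random walk of N(0, tau^2)
#            increments when shift_mode = "random_walk"
#   eps      per-record observation noise ~ N(0, sigma^2), iid
#
# Published 95% UI: [V * exp(-z * s_ui), V * exp(+z * s_ui)].
#
# All draws come from one seeded generator in a fixed, documented order —
# baselines and growths (per risk x metric), then shifts (per risk x metric x
# iteration), then noise (per record) — so a given seed reproduces the table
# bit-for-bit.

#' Configuration for the synthetic revision process
#'
#' @param n_risks number of synthetic risk factors (default 50).
#' @param iterations tibble (iteration, index_year) of release cycles;
#'   default the eight cycles 2010-2023 ([default_iteration_index_map()]).
#' @param year_min first calendar year every iteration estimates
#'   (default 2010); iteration i covers `year_min:index_year(i)`.
#' @param metrics metrics to emit (default deaths and DALYs; draws are
#'   independent between metrics).
#' @param baseline_range range of the log-uniform baseline burden `A_r`, in
#'   arbitrary burden units (default 1e4 to 1e7 — the span from small
#'   individual risks to large aggregates).
#' @param growth_range range of the uniform per-year log slope `g_r`
#'   (default -0.02 to 0.02, i.e. up to ~2%/year true trend).
#' @param tau SD of the per-iteration log-scale revision shift (default 0.3 —
#'   iteration-to-iteration fold-changes of the size seen in volatile
#'   behavioral-risk estimates).
#' @param sigma SD of per-record log-scale observation noise (default 0.1).
#' @param shift_mode "independent" (default) or "random_walk" cumulative
#'   drift across iterations.
#' @param s_ui log-scale half-width multiplier of the published UI: bounds
#'   are `V * exp(+/- z * s_ui)` (default 0.1).
#' @param z normal quantile scaling the UI half-width (default 1.96, a
#'   nominal 95% interval).
#' @param seed integer seed; the same seed reproduces the table exactly.
#' @return validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_risks = 50L,
                             iterations = default_iteration_index_map(),
                             year_min = 2010L,
                             metrics = c("deaths", "dalys"),
                             baseline_range = c(1e4, 1e7),
                             growth_range = c(-0.02, 0.02),
                             tau = 0.3,
                             sigma = 0.1,
                             shift_mode = c("independent", "random_walk"),
                             s_ui = 0.1,
                             z = 1.96,
                             seed = 1L) {
  shift_mode <- match.arg(shift_mode)
  iterations <- validate_index_map(iterations)
  if (n_risks < 1) rs_abort("n_risks must be >= 1", "revstab_config_error")
  if (tau < 0 || sigma < 0 || s_ui < 0) {
    rs_abort("tau, sigma and s_ui must be nonnegative", "revstab_config_error")
  }
  if (z <= 0) rs_abort("z must be positive", "revstab_config_error")
  if (any(!metrics %in% METRIC_LEVELS)) {
    rs_abort("metrics must be a subset of deaths/dalys", "revstab_config_error")
  }
  if (any(iterations$index_year < year_min)) {
    rs_abort("year_min exceeds an iteration's index year", "revstab_config_error")
  }
  structure(list(
    n_risks = as.integer(n_risks), iterations = iterations,
    year_min = as.integer(year_min), metrics = metrics,
    baseline_range = baseline_range, growth_range = growth_range,
    tau = tau, sigma = sigma, shift_mode = shift_mode,
    s_ui = s_ui, z = z, seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Simulate a multi-iteration estimate table with known truth
#'
#' Draws a synthetic panel of burden estimates under the lognormal revision
#' model (see the package vignette): a smooth true trend per risk, a
#' systematic per-iteration revision shift of log-SD `tau`, observation noise
#' of log-SD `sigma`, and published UIs of log-half-width `z * s_ui`. The
#' generator also emits a matching three-level risk hierarchy (risks assigned
#' round-robin to behavioral / metabolic / environmental-occupational
#' level-2 parents) and an identity harmonization map, so the full pipeline
#' can run on the output unchanged.
#'
#' @param config a [synthetic_config()].
#' @return list with elements
#'   * `table` — canonical estimate table (raw `risk` names `risk_001`, ...);
#'   * `truth` — list of `risks` (risk_id, metric, baseline, growth),
#'     `shifts` (risk_id, metric, iteration, delta) and `noise` (per-record
#'     eps), enough to reconstruct every value exactly in
#'     parameter-recovery tests;
#'   * `hierarchy` — risk hierarchy tibble covering the synthetic risks;
#'   * `map` — identity harmonization map for the synthetic names.
#' @export
simulate_estimates <- function(config = synthetic_config()) {
  if (!inherits(config, "synthetic_config")) {
    rs_abort("config must come from synthetic_config()", "revstab_config_error")
  }
  cfg <- config
  set.seed(cfg$seed)
  risk_ids <- sprintf("risk_%03d", seq_len(cfg$n_risks))
  n_units <- cfg$n_risks * length(cfg$metrics)

  # draw order 1: per risk x metric baselines and growths (metric fastest)
  units <- tidyr::expand_grid(risk_id = risk_ids, metric = cfg$metrics)
  units$baseline <- exp(runif(n_units, log(cfg$baseline_range[1]),
                              log(cfg$baseline_range[2])))
  units$growth <- runif(n_units, cfg$growth_range[1], cfg$growth_range[2])

  # draw order 2: per-iteration shifts
  iters <- cfg$iterations$iteration
  shifts <- tidyr::expand_grid(units[, c("risk_id", "metric")],
                               iteration = iters)
  incr <- rnorm(nrow(shifts), 0, cfg$tau)
  if (cfg$shift_mode == "random_walk") {
    shifts$delta <- as.vector(stats::ave(incr,
                                         paste(shifts$risk_id, shifts$metric, sep = "\r"),
                                         FUN = cumsum))
  } else {
    shifts$delta <- incr
  }

  # draw order 3: per-record noise, records laid out unit x iteration x year
  years_per_iter <- lapply(seq_along(iters), function(i) {
    cfg$year_min:cfg$iterations$index_year[i]
  })
  iter_block <- tibble::tibble(
    iteration = rep(iters, lengths(years_per_iter)),
    year = unlist(years_per_iter)
  )
  recs <- tidyr::expand_grid(units, iter_block)
  recs$eps <- rnorm(nrow(recs), 0, cfg$sigma)

  k <- match(paste(recs$risk_id, recs$metric, recs$iteration, sep = "\r"),
             paste(shifts$risk_id, shifts$metric, shifts$iteration, sep = "\r"))
  recs$delta <- shifts$delta[k]
  recs$value <- recs$baseline *
    exp(recs$growth * (recs$year - cfg$year_min)) *
    exp(recs$delta) * exp(recs$eps)
  half <- exp(cfg$z * cfg$s_ui)

  table <- tibble::tibble(
    risk = recs$risk_id,
    metric = recs$metric,
    iteration = as.integer(recs$iteration),
    year = as.integer(recs$year),
    sex = "both", location = "global", cause_group = "all",
    value = recs$value,
    ui_lower = recs$value / half,
    ui_upper = recs$value * half
  )

  hierarchy <- synthetic_hierarchy(risk_ids)
  map <- tibble::tibble(raw_name = risk_ids, iteration = NA_integer_,
                        risk_id = risk_ids)
  list(
    table = table,
    truth = list(
      risks = units,
      shifts = shifts[, c("risk_id", "metric", "iteration", "delta")],
      noise = recs[, c("risk_id", "metric", "iteration", "year", "eps")]
    ),
    hierarchy = hierarchy,
    map = map
  )
}

# three-level synthetic hierarchy: root, three level-1 groups, one level-2
# parent per group, level-3 risks assigned round-robin
synthetic_hierarchy <- function(risk_ids) {
  groups <- c("behavioral", "metabolic", "environmental_occupational")
  l2_ids <- paste0("synthetic_", c("behavioral_sub", "metabolic_sub", "environmental_sub"))
  base <- tibble::tibble(
    risk_id = c("all_risk", groups, l2_ids),
    canonical_name = c("All risk factors", "Behavioral risks", "Metabolic risks",
                       "Environmental/occupational risks",
                       "Behavioral subgroup", "Metabolic subgroup",
                       "Environmental subgroup"),
    level = c(0L, 1L, 1L, 1L, 2L, 2L, 2L),
    parent_id = c(NA, "all_risk", "all_risk", "all_risk", groups),
    group = c("all_risks", groups, groups)
  )
  assign <- rep_len(seq_along(groups), length(risk_ids))
  leaves <- tibble::tibble(
    risk_id = risk_ids,
    canonical_name = paste("Synthetic risk", sub("risk_", "", risk_ids)),
    level = 3L,
    parent_id = l2_ids[assign],
    group = groups[assign]
  )
  validate_risk_hierarchy(dplyr::bind_rows(base, leaves))
}

#' Population CV of the synthetic revision process
#'
#' In independent-shift mode, the values a matched-year panel collects for
#' one (risk, year) are lognormal with total log-SD `sqrt(tau^2 + sigma^2)`
#' around the (fixed) true value, so their population coefficient of
#' variation has the closed form `sqrt(exp(tau^2 + sigma^2) - 1)`. Used as a
#' calibration target for the whole pipeline.
#'
#' @param tau,sigma nonnegative log-scale SDs of the revision shift and the
#'   observation noise.
#' @return the population CV (dimensionless).
#' @export
theoretical_cv <- function(tau, sigma) {
  if (tau < 0 || sigma < 0) {
    rs_abort("tau and sigma must be nonnegative", "revstab_config_error")
  }
  sqrt(exp(tau^2 + sigma^2) - 1)
}

#' Probability a revised point falls inside an earlier UI
#'
#' In independent-shift mode the log-difference between a later iteration's
#' point and the earlier iteration's point is normal with SD
#' `sqrt(2 * (tau^2 + sigma^2))`; the earlier UI has log-half-width
#' `z * s_ui`, so the within-probability is
#' `2 * pnorm(z * s_ui / sqrt(2 * (tau^2 + sigma^2))) - 1`. With no noise at
#' all the point reproduces exactly and the probability is 1. Setting
#' `s_ui = sqrt(2 * (tau^2 + sigma^2))` makes the nominal level `2*pnorm(z)-1`
#' (0.95 at z = 1.96).
#'
#' @param tau,sigma nonnegative log-scale SDs.
#' @param s_ui UI log-half-width multiplier (>= 0).
#' @param z normal quantile scaling the UI (default 1.96).
#' @return probability in `[0, 1]`.
#' @export
theoretical_ui_within <- function(tau, sigma, s_ui, z = 1.96) {
  if (tau < 0 || sigma < 0 || s_ui < 0) {
    rs_abort("tau, sigma and s_ui must be nonnegative", "revstab_config_error")
  }
  if (z <= 0) rs_abort("z must be positive", "revstab_config_error")
  total <- sqrt(2 * (tau^2 + sigma^2))
  if (total == 0) return(1)
  2 * pnorm(z * s_ui / total) - 1
}

#' Write the synthetic truth alongside the estimates
#'
#' Emits the generator's truth as two CSVs next to the estimate CSV:
#' `<stem>_truth_risks.csv` (baseline and growth per risk and metric) and
#' `<stem>_truth_shifts.csv` (per-iteration revision shifts).
#'
#' @param sim result of [simulate_estimates()].
#' @param path path for the estimate CSV; truth files are derived from it.
#' @return invisibly, the paths written.
#' @export
write_synthetic_csv <- function(sim, path) {
  write_estimates_csv(sim$table, path)
  stem <- sub("\\.csv$", "", path)
  p1 <- paste0(stem, "_truth_risks.csv")
  p2 <- paste0(stem, "_truth_shifts.csv")
  readr::write_csv(sim$truth$risks, p1, progress = FALSE)
  readr::write_csv(sim$truth$shifts, p2, progress = FALSE)
  invisible(c(path, p1, p2))
}
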