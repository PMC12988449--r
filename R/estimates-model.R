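# Data model: long-format estimate tables, risk hierarchy, harmonization map.
#
# Canonical long schema (one row per published estimate):
#   risk        raw risk-factor name as printed by the release
#   metric      "deaths" or "dalys"
#   iteration   release year of the iteration that published the estimate
#   year        calendar year the estimate refers to (year <= iteration)
#   sex         "both" / "male" / "female"        (default "both")
#   location    stratum label                      (default "global")
#   cause_group cause aggregate label              (default "all")
#   value       point estimate, persons or person-years (>= 0)
#   ui_lower, ui_upper   optional 95% uncertainty interval bounds
#
# Values are kept in raw units; any scaling to thousands/millions happens only
# in the report layer.

CANONICAL_COLUMNS <- c(
  "risk", "metric", "iteration", "year", "sex", "location", "cause_group",
  "value", "ui_lower", "ui_upper"
)
REQUIRED_COLUMNS <- c("risk", "metric", "iteration", "year", "value")
RECORD_KEY <- c("risk", "metric", "iteration", "year", "sex", "location", "cause_group")
HARMONIZED_KEY <- c("risk_id", "metric", "iteration", "year", "sex", "location", "cause_group")
METRIC_LEVELS <- c("deaths", "dalys")
SEX_LEVELS <- c("both", "male", "female")
GROUP_LEVELS <- c("behavioral", "metabolic", "environmental_occupational", "all_risks")

#' Read a long-format estimate table from CSV
#'
#' Reads and validates the canonical long-format table of published estimates,
#' one row per (risk, metric, iteration, year, stratum). Column names in the
#' file can be mapped onto the canonical schema via `schema`; optional strata
#' columns default to the global/both-sex/all-cause slice; a missing
#' uncertainty interval is an empty field.
#'
#' Validation is strict: rows with a negative or missing value, an unknown
#' metric or sex, `ui_lower > ui_upper`, or `year > iteration` are rejected
#' with row-numbered diagnostics, and duplicate records on the full key are an
#' integrity error. Rows whose point estimate falls outside its own published
#' interval are legal (intervals are recorded as published) but are flagged in
#' the `ui_point_outside` attribute.
#'
#' @param path path to a UTF-8 CSV file with a header row.
#' @param schema optional named character vector mapping canonical column
#'   names to the file's column names, e.g. `c(risk = "rei_name", value = "val")`.
#' @return a validated tibble in the canonical schema. Attribute
#'   `ui_point_outside` holds the row numbers (in the returned table) whose
#'   point lies outside its own UI.
#' @seealso [write_estimates_csv()], [harmonize()], [filter_analysis_set()]
#' @export
read_estimates_csv <- function(path, schema = NULL) {
  if (!file.exists(path)) {
    rs_abort(paste0("estimate file not found: ", path), "revstab_schema_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!is.null(schema)) {
    bad <- setdiff(names(schema), CANONICAL_COLUMNS)
    if (length(bad)) {
      rs_abort(paste0("schema maps unknown canonical columns: ",
                      paste(bad, collapse = ", ")), "revstab_schema_error")
    }
    missing_src <- setdiff(unname(schema), names(raw))
    if (length(missing_src)) {
      rs_abort(paste0("schema refers to columns absent from file: ",
                      paste(missing_src, collapse = ", ")), "revstab_schema_error")
    }
    for (canon in names(schema)) {
      names(raw)[names(raw) == schema[[canon]]] <- canon
    }
  }
  missing <- setdiff(REQUIRED_COLUMNS, names(raw))
  if (length(missing)) {
    rs_abort(paste0("required columns missing: ", paste(missing, collapse = ", ")),
             "revstab_schema_error")
  }
  as_estimate_table(raw)
}

#' Validate a data frame as a canonical estimate table
#'
#' Applies the same validation as [read_estimates_csv()] to an in-memory data
#' frame: fills stratum defaults, coerces types, checks ranges and the
#' full-key uniqueness invariant.
#'
#' @param x data frame with at least the required canonical columns
#'   (risk, metric, iteration, year, value).
#' @return validated tibble in the canonical schema.
#' @export
as_estimate_table <- function(x) {
  x <- tibble::as_tibble(x)
  missing <- setdiff(REQUIRED_COLUMNS, names(x))
  if (length(missing)) {
    rs_abort(paste0("required columns missing: ", paste(missing, collapse = ", ")),
             "revstab_schema_error")
  }
  if (!"sex" %in% names(x)) x$sex <- "both"
  if (!"location" %in% names(x)) x$location <- "global"
  if (!"cause_group" %in% names(x)) x$cause_group <- "all"
  if (!"ui_lower" %in% names(x)) x$ui_lower <- NA_real_
  if (!"ui_upper" %in% names(x)) x$ui_upper <- NA_real_
  x$sex[is.na(x$sex) | x$sex == ""] <- "both"
  x$location[is.na(x$location) | x$location == ""] <- "global"
  x$cause_group[is.na(x$cause_group) | x$cause_group == ""] <- "all"

  n <- nrow(x)
  suppressWarnings({
    iteration <- as.integer(x$iteration)
    year <- as.integer(x$year)
    value <- as.numeric(x$value)
    ui_lower <- as.numeric(x$ui_lower)
    ui_upper <- as.numeric(x$ui_upper)
  })
  metric <- tolower(trimws(as.character(x$metric)))
  sex <- tolower(trimws(as.character(x$sex)))

  problems <- character(0)
  flag <- function(rows, what) {
    if (any(rows, na.rm = TRUE)) {
      idx <- which(rows)
      problems <<- c(problems, paste0(
        what, " (row", if (length(idx) > 1) "s" else "", " ",
        paste(head(idx, 10), collapse = ", "),
        if (length(idx) > 10) ", ..." else "", ")"
      ))
    }
  }
  flag(is.na(x$risk) | trimws(as.character(x$risk)) == "", "empty risk name")
  flag(!metric %in% METRIC_LEVELS, "metric not one of deaths/dalys")
  flag(is.na(iteration), "non-integer iteration")
  flag(is.na(year), "non-integer year")
  flag(is.na(value), "missing or non-numeric value")
  flag(value < 0, "negative value")
  flag(!sex %in% SEX_LEVELS, "sex not one of both/male/female")
  flag(!is.na(ui_lower) & is.na(ui_upper) | is.na(ui_lower) & !is.na(ui_upper),
       "one-sided uncertainty interval")
  flag(!is.na(ui_lower) & !is.na(ui_upper) & ui_lower > ui_upper,
       "ui_lower > ui_upper")
  flag(ui_lower < 0, "negative ui_lower")
  flag(!is.na(year) & !is.na(iteration) & year > iteration,
       "year later than its release iteration")
  if (length(problems)) {
    rs_abort(paste0("invalid estimate rows rejected:\n  - ",
                    paste(problems, collapse = "\n  - ")),
             "revstab_integrity_error")
  }

  out <- tibble::tibble(
    risk = trimws(as.character(x$risk)),
    metric = metric,
    iteration = iteration,
    year = year,
    sex = sex,
    location = as.character(x$location),
    cause_group = as.character(x$cause_group),
    value = value,
    ui_lower = ui_lower,
    ui_upper = ui_upper
  )

  dup <- duplicated(out[RECORD_KEY]) | duplicated(out[RECORD_KEY], fromLast = TRUE)
  if (any(dup)) {
    rs_abort(paste0("duplicate records on (",
                    paste(RECORD_KEY, collapse = ", "), ") at rows ",
                    paste(which(dup), collapse = ", ")),
             "revstab_integrity_error")
  }

  outside <- which(!is.na(out$ui_lower) &
                     (out$value < out$ui_lower | out$value > out$ui_upper))
  attr(out, "ui_point_outside") <- outside
  out
}

#' Write an estimate table back to CSV
#'
#' Serializes the canonical long table at full double precision so that
#' `read_estimates_csv(write_estimates_csv(x))` round-trips the validated
#' rows exactly. Missing UI bounds are written as empty fields.
#'
#' @param table canonical estimate table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_estimates_csv <- function(table, path) {
  cols <- intersect(c(CANONICAL_COLUMNS,
                      setdiff(names(table), CANONICAL_COLUMNS)), names(table))
  readr::write_csv(table[cols], path, na = "", progress = FALSE)
  invisible(path)
}

#' Read the risk hierarchy
#'
#' The hierarchy file has one row per canonical risk:
#' `risk_id, canonical_name, level, parent_id, group`, where `level` 0 is the
#' all-risk aggregate, level 1 the broad groups (behavioral, metabolic,
#' environmental/occupational), level 2 subgroups (e.g. dietary risks) and
#' level 3+ individual risks. Every level-k risk (k >= 1) must name a parent
#' of level k-1, and a risk's group must equal its level-1 ancestor's group.
#'
#' @param path CSV path.
#' @return validated hierarchy tibble.
#' @export
read_risk_hierarchy <- function(path) {
  h <- readr::read_csv(path, col_types = readr::cols(
    risk_id = readr::col_character(),
    canonical_name = readr::col_character(),
    level = readr::col_integer(),
    parent_id = readr::col_character(),
    group = readr::col_character()
  ), progress = FALSE)
  validate_risk_hierarchy(h)
}

#' Validate a risk hierarchy table
#'
#' @param h data frame with columns risk_id, canonical_name, level,
#'   parent_id, group.
#' @return the validated tibble.
#' @export
validate_risk_hierarchy <- function(h) {
  h <- tibble::as_tibble(h)
  need <- c("risk_id", "canonical_name", "level", "parent_id", "group")
  missing <- setdiff(need, names(h))
  if (length(missing)) {
    rs_abort(paste0("hierarchy columns missing: ", paste(missing, collapse = ", ")),
             "revstab_schema_error")
  }
  if (anyDuplicated(h$risk_id)) {
    rs_abort("duplicate risk_id in hierarchy", "revstab_integrity_error")
  }
  if (any(!h$group %in% GROUP_LEVELS)) {
    rs_abort(paste0("unknown group label(s): ",
                    paste(setdiff(unique(h$group), GROUP_LEVELS), collapse = ", ")),
             "revstab_integrity_error")
  }
  if (any(h$level < 0 | h$level > 4)) {
    # levels 0-3 are the analytic hierarchy; level 4 rows may be present in
    # raw data and are dropped by filter_analysis_set() by default
    rs_abort("levels must lie in 0..4", "revstab_integrity_error")
  }
  root_bad <- h$level == 0 & !is.na(h$parent_id)
  if (any(root_bad)) {
    rs_abort("level-0 risks must have no parent", "revstab_integrity_error")
  }
  child <- h[h$level >= 1, ]
  if (nrow(child)) {
    if (any(is.na(child$parent_id))) {
      rs_abort("every level >= 1 risk needs a parent_id", "revstab_integrity_error")
    }
    parent_level <- h$level[match(child$parent_id, h$risk_id)]
    if (any(is.na(parent_level))) {
      rs_abort("parent_id not found in hierarchy", "revstab_integrity_error")
    }
    if (any(parent_level != child$level - 1)) {
      rs_abort("parent of a level-k risk must be level k-1", "revstab_integrity_error")
    }
  }
  # group consistency: walk each risk up to its level-1 ancestor
  lvl1 <- level1_ancestor(h)
  anc_group <- h$group[match(lvl1, h$risk_id)]
  chk <- h$level >= 1 & !is.na(anc_group) & h$group != anc_group
  if (any(chk)) {
    rs_abort(paste0("group differs from level-1 ancestor for: ",
                    paste(h$risk_id[chk], collapse = ", ")),
             "revstab_integrity_error")
  }
  h
}

# risk_id of the level-1 ancestor for every hierarchy row (NA for level 0)
level1_ancestor <- function(h) {
  anc <- h$risk_id
  lev <- h$level
  repeat {
    up <- lev > 1
    if (!any(up)) break
    anc[up] <- h$parent_id[match(anc[up], h$risk_id)]
    lev[up] <- lev[up] - 1
  }
  anc[h$level < 1] <- NA_character_
  anc
}

#' Read a harmonization map
#'
#' The map translates iteration-specific raw risk names into canonical risk
#' identifiers: `raw_name, iteration, risk_id`. An empty `iteration` field
#' means the entry applies to any iteration; an iteration-specific entry takes
#' precedence over the any-iteration entry for the same raw name.
#'
#' @param path CSV path.
#' @param hierarchy optional validated hierarchy; if supplied, every mapped
#'   `risk_id` must exist in it.
#' @return validated map tibble (raw_name, iteration, risk_id).
#' @export
read_harmonization_map <- function(path, hierarchy = NULL) {
  m <- readr::read_csv(path, col_types = readr::cols(
    raw_name = readr::col_character(),
    iteration = readr::col_integer(),
    risk_id = readr::col_character()
  ), progress = FALSE)
  validate_harmonization_map(m, hierarchy)
}

#' Validate a harmonization map
#'
#' @param m data frame with columns raw_name, iteration, risk_id.
#' @inheritParams read_harmonization_map
#' @return the validated tibble.
#' @export
validate_harmonization_map <- function(m, hierarchy = NULL) {
  m <- tibble::as_tibble(m)
  need <- c("raw_name", "iteration", "risk_id")
  missing <- setdiff(need, names(m))
  if (length(missing)) {
    rs_abort(paste0("map columns missing: ", paste(missing, collapse = ", ")),
             "revstab_schema_error")
  }
  m$iteration <- as.integer(m$iteration)
  key <- paste(m$raw_name, m$iteration, sep = "\r")
  if (anyDuplicated(key)) {
    rs_abort("duplicate (raw_name, iteration) entries in harmonization map",
             "revstab_integrity_error")
  }
  if (!is.null(hierarchy)) {
    unknown <- setdiff(unique(m$risk_id), hierarchy$risk_id)
    if (length(unknown)) {
      rs_abort(paste0("map references risk_id absent from hierarchy: ",
                      paste(unknown, collapse = ", ")),
               "revstab_integrity_error")
    }
  }
  m
}

#' Harmonize raw risk names onto canonical identifiers
#'
#' Attaches a canonical `risk_id` (plus `canonical_name`, `level`, `group`,
#' `parent_id` when a hierarchy is given) to every record. Resolution order:
#' an entry keyed to the record's iteration wins over an any-iteration entry
#' for the same raw name. Records whose raw name has no mapping are excluded
#' from the returned table and collected in the [unmapped_report()] attribute
#' rather than silently dropped. Applying the same map twice is a no-op.
#'
#' @param table canonical estimate table (raw names in `risk`).
#' @param map validated harmonization map.
#' @param hierarchy optional validated risk hierarchy to join descriptors from.
#' @return harmonized table; attribute `unmapped` lists unmatched raw names
#'   with record counts.
#' @export
harmonize <- function(table, map, hierarchy = NULL) {
  table <- tibble::as_tibble(table)
  if ("risk_id" %in% names(table)) {
    # already harmonized: idempotent re-application re-resolves from raw names
    table <- table[setdiff(names(table),
                           c("risk_id", "canonical_name", "level", "group", "parent_id"))]
  }
  map <- tibble::as_tibble(map)
  specific <- map[!is.na(map$iteration), c("raw_name", "iteration", "risk_id")]
  generic <- map[is.na(map$iteration), c("raw_name", "risk_id")]

  out <- table
  out$risk_id <- NA_character_
  if (nrow(specific)) {
    i <- match(paste(out$risk, out$iteration, sep = "\r"),
               paste(specific$raw_name, specific$iteration, sep = "\r"))
    out$risk_id <- specific$risk_id[i]
  }
  if (nrow(generic)) {
    j <- match(out$risk, generic$raw_name)
    fill <- is.na(out$risk_id) & !is.na(j)
    out$risk_id[fill] <- generic$risk_id[j[fill]]
  }

  unmapped <- out[is.na(out$risk_id), ]
  out <- out[!is.na(out$risk_id), ]
  if (!is.null(hierarchy)) {
    k <- match(out$risk_id, hierarchy$risk_id)
    out$canonical_name <- hierarchy$canonical_name[k]
    out$level <- hierarchy$level[k]
    out$group <- hierarchy$group[k]
    out$parent_id <- hierarchy$parent_id[k]
  }
  dup <- duplicated(out[HARMONIZED_KEY])
  if (any(dup)) {
    rs_abort(paste0("harmonization collapsed distinct raw names onto duplicate keys: ",
                    paste(unique(out$risk_id[dup]), collapse = ", ")),
             "revstab_integrity_error")
  }
  report <- dplyr::count(unmapped, .data$risk, .data$iteration, name = "n_records")
  names(report)[names(report) == "risk"] <- "raw_name"
  set_ledger(out, "unmapped", report)
}

#' Default named exclusion list
#'
#' Risks excluded from the analysis set by name. The defaults approximate the
#' exclusions applied in published instability analyses (items around
#' childhood sexual abuse and bullying, and the combined alcohol-and-drug-use
#' aggregate); the list is fully configurable and should be adapted to the
#' hierarchy in use.
#'
#' @return character vector of risk_ids.
#' @export
default_exclusions <- function() {
  c("childhood_sexual_abuse", "bullying_victimization", "alcohol_and_drug_use")
}

#' Build the analysis set
#'
#' Applies the standard analysis-set filters to a harmonized table:
#' named exclusions, hierarchy levels that are not analyzed (default: level 4,
#' the most granular risks, which are excluded from instability analyses),
#' and risks whose estimates appear in only a single release iteration. Every removed record lands in
#' the [exclusion_ledger()] with a reason, so
#' `nrow(input) == nrow(output) + nrow(ledger)` always holds.
#'
#' @param table harmonized estimate table (must carry `risk_id`).
#' @param drop_levels integer vector of hierarchy levels to drop
#'   (default `4`).
#' @param exclude_risks character vector of risk_ids to drop by name
#'   (default [default_exclusions()]).
#' @param min_iterations risks present in fewer distinct iterations than this
#'   are dropped (default 2, i.e. single-iteration risks go).
#' @return filtered table with an `exclusions` ledger attribute
#'   (columns of the input plus `reason`).
#' @export
filter_analysis_set <- function(table,
                                drop_levels = 4L,
                                exclude_risks = default_exclusions(),
                                min_iterations = 2L) {
  if (!"risk_id" %in% names(table)) {
    rs_abort("filter_analysis_set needs a harmonized table (risk_id column)",
             "revstab_schema_error")
  }
  tab <- tibble::as_tibble(table)
  reason <- rep(NA_character_, nrow(tab))

  if (length(exclude_risks)) {
    hit <- is.na(reason) & tab$risk_id %in% exclude_risks
    reason[hit] <- "named-exclusion"
  }
  if (length(drop_levels) && "level" %in% names(tab)) {
    hit <- is.na(reason) & !is.na(tab$level) & tab$level %in% drop_levels
    reason[hit] <- "level-excluded"
  }
  keep_mask <- is.na(reason)
  n_iter <- tapply(tab$iteration[keep_mask], tab$risk_id[keep_mask],
                   function(v) length(unique(v)))
  few <- names(n_iter)[n_iter < min_iterations]
  hit <- is.na(reason) & tab$risk_id %in% few
  reason[hit] <- "single-iteration"

  ledger <- tab[!is.na(reason), ]
  if (nrow(ledger)) ledger$reason <- reason[!is.na(reason)] else ledger$reason <- character(0)
  out <- tab[is.na(reason), ]
  set_ledger(out, "exclusions", ledger)
}
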