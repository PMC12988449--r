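# Ingest, validation, harmonization and analysis-set filtering.

test_that("a well-formed CSV ingests identically and round-trips at full precision", {
  df <- tibble::tibble(
    risk = c("Smoking", "Smoking", "Lead exposure"),
    metric = "deaths",
    iteration = c(2019L, 2021L, 2021L),
    year = c(2019L, 2019L, 2021L),
    value = c(7700123.456789, 6200000.1, 1/3 * 1e6),
    ui_lower = c(7000000, NA, 900000.25),
    ui_upper = c(8400000, NA, 1100000.75)
  )
  p <- write_tmp_csv(df)
  tab <- read_estimates_csv(p)
  expect_equal(nrow(tab), 3)
  expect_identical(tab$value, df$value)
  expect_equal(tab$sex, rep("both", 3))
  expect_equal(tab$location, rep("global", 3))

  # write -> read reproduces the validated value fields bit-identically
  p2 <- file.path(withr::local_tempdir(), "rt.csv")
  write_estimates_csv(tab, p2)
  back <- read_estimates_csv(p2)
  expect_identical(back$value, tab$value)
  expect_identical(back$ui_lower, tab$ui_lower)
  expect_identical(back, tab, ignore_attr = TRUE)
})

test_that("schema mapping renames file columns onto the canonical names", {
  df <- tibble::tibble(rei = "Smoking", measure = "deaths", gbd = 2019L,
                       yr = 2019L, val = 100)
  p <- write_tmp_csv(df)
  tab <- read_estimates_csv(p, schema = c(risk = "rei", metric = "measure",
                                          iteration = "gbd", year = "yr",
                                          value = "val"))
  expect_equal(tab$risk, "Smoking")
  expect_error(read_estimates_csv(p), class = "revstab_schema_error")
  expect_error(read_estimates_csv(p, schema = c(risk = "nope")),
               class = "revstab_schema_error")
})

test_that("duplicate full keys are an integrity error naming both rows", {
  df <- tibble::tibble(risk = "Smoking", metric = "deaths",
                       iteration = 2019L, year = c(2019L, 2018L, 2019L),
                       value = c(1, 2, 3))
  err <- expect_error(as_estimate_table(df), class = "revstab_integrity_error")
  expect_match(conditionMessage(err), "1")
  expect_match(conditionMessage(err), "3")
})

test_that("rows violating range and ordering invariants are rejected with row numbers", {
  base <- tibble::tibble(risk = "Smoking", metric = "deaths",
                         iteration = 2019L, year = 2019L, value = 1)
  bad_ui <- base
  bad_ui$ui_lower <- 10; bad_ui$ui_upper <- 5
  expect_error(as_estimate_table(bad_ui), "ui_lower > ui_upper",
               class = "revstab_integrity_error")

  bad_year <- base; bad_year$year <- 2022L
  expect_error(as_estimate_table(bad_year), "later than its release",
               class = "revstab_integrity_error")

  bad_val <- base; bad_val$value <- -4
  expect_error(as_estimate_table(bad_val), "negative value",
               class = "revstab_integrity_error")

  bad_metric <- base; bad_metric$metric <- "cases"
  expect_error(as_estimate_table(bad_metric), "metric",
               class = "revstab_integrity_error")
})

test_that("a point outside its own published UI is recorded as-is but flagged", {
  df <- tibble::tibble(risk = "Smoking", metric = "deaths", iteration = 2019L,
                       year = 2019L, value = 100, ui_lower = 150, ui_upper = 200)
  tab <- as_estimate_table(df)
  expect_equal(nrow(tab), 1)
  expect_equal(attr(tab, "ui_point_outside"), 1L)
})

test_that("harmonization applies the map, reports unmapped names, and is idempotent", {
  tab <- tiny_table()
  extra <- as_estimate_table(tibble::tibble(
    risk = "Totally unknown factor", metric = "deaths",
    iteration = 2019L, year = 2019L, value = 5))
  tab2 <- dplyr::bind_rows(tab, extra)
  h <- harmonize(tab2, tiny_map(), tiny_hierarchy())
  expect_true(all(!is.na(h$risk_id)))
  expect_false("Totally unknown factor" %in% h$risk)
  rep <- unmapped_report(h)
  expect_equal(rep$raw_name, "Totally unknown factor")
  expect_equal(rep$n_records, 1L)
  expect_equal(nrow(h) + sum(rep$n_records), nrow(tab2))

  h2 <- harmonize(h, tiny_map(), tiny_hierarchy())
  expect_equal(h2, h, ignore_attr = TRUE)
})

test_that("two iteration spellings map to a single canonical risk", {
  df <- as_estimate_table(tibble::tibble(
    risk = c("Diet high in red meat consumption", "Diet high in red meat"),
    metric = "deaths", iteration = c(2015L, 2017L), year = c(2015L, 2017L),
    value = c(1, 2)))
  h <- harmonize(df, tiny_map(), tiny_hierarchy())
  expect_equal(unique(h$risk_id), "diet_red_meat")
  expect_equal(h$canonical_name, rep("Diet high in red meat", 2))
})

test_that("iteration-specific map entries win over any-iteration entries", {
  # oracle: resolve by (raw_name, iteration) first, then (raw_name, any)
  map <- validate_harmonization_map(tibble::tibble(
    raw_name = c("Alcohol", "Alcohol"),
    iteration = c(2015L, NA),
    risk_id = c("smoking", "high_ldl")  # ids only need to exist
  ), tiny_hierarchy())
  df <- as_estimate_table(tibble::tibble(
    risk = "Alcohol", metric = "deaths",
    iteration = c(2015L, 2019L), year = c(2015L, 2019L), value = c(1, 2)))
  h <- harmonize(df, map, tiny_hierarchy())
  expect_equal(h$risk_id[h$iteration == 2015], "smoking")
  expect_equal(h$risk_id[h$iteration == 2019], "high_ldl")
})

test_that("hierarchy validation enforces parent levels and group inheritance", {
  h <- tiny_hierarchy()
  bad <- h; bad$parent_id[bad$risk_id == "diet_red_meat"] <- "behavioral"
  expect_error(validate_risk_hierarchy(bad), "k-1",
               class = "revstab_integrity_error")
  bad2 <- h; bad2$group[bad2$risk_id == "diet_red_meat"] <- "metabolic"
  expect_error(validate_risk_hierarchy(bad2), "ancestor",
               class = "revstab_integrity_error")
  bad3 <- h; bad3$parent_id[bad3$level == 0] <- "behavioral"
  expect_error(validate_risk_hierarchy(bad3), "level-0",
               class = "revstab_integrity_error")
})

test_that("single-iteration risks are excluded with a ledger reason", {
  tab <- harmonized_tiny()
  solo <- harmonize(as_estimate_table(tibble::tibble(
    risk = "Lead exposure", metric = "deaths", iteration = 2019L,
    year = 2019L, value = 7)), tiny_map(), tiny_hierarchy())
  full <- dplyr::bind_rows(tab, solo)
  out <- filter_analysis_set(full, exclude_risks = character(0))
  led <- exclusion_ledger(out)
  expect_false("lead_exposure" %in% out$risk_id)
  expect_equal(unique(led$reason[led$risk_id == "lead_exposure"]),
               "single-iteration")
})

test_that("no applicable rules leave a multi-iteration table unchanged", {
  tab <- harmonized_tiny()
  out <- filter_analysis_set(tab, drop_levels = integer(0),
                             exclude_risks = character(0))
  expect_equal(nrow(out), nrow(tab))
  expect_equal(nrow(exclusion_ledger(out)), 0)
})

test_that("filtering 10 risks with 3 single-iteration and 2 named leaves 5, conserving records", {
  mk <- function(id, iters) {
    tibble::tibble(risk = id, metric = "deaths", iteration = iters,
                   year = iters, value = 1, risk_id = id)
  }
  ids <- sprintf("r%02d", 1:10)
  tab <- dplyr::bind_rows(c(
    lapply(ids[1:3], mk, iters = 2019L),                 # single-iteration
    lapply(ids[4:10], mk, iters = c(2019L, 2021L))       # multi-iteration
  ))
  out <- filter_analysis_set(tab, drop_levels = integer(0),
                             exclude_risks = c("r04", "r05"))
  led <- exclusion_ledger(out)
  expect_equal(sort(unique(out$risk_id)), ids[6:10])
  expect_equal(nrow(out) + nrow(led), nrow(tab))
  expect_setequal(led$reason[led$risk_id %in% ids[1:3]], "single-iteration")
  expect_setequal(led$reason[led$risk_id %in% c("r04", "r05")], "named-exclusion")
})
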