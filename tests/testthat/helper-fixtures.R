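# In-code fixtures shared across test files.

# minimal realistic hierarchy: root, 3 level-1 groups, 2 level-2 subgroups,
# level-3 risks under the behavioral branch
tiny_hierarchy <- function() {
  validate_risk_hierarchy(tibble::tibble(
    risk_id = c("all_risk", "behavioral", "metabolic", "environmental_occupational",
                "dietary_risks", "tobacco",
                "diet_red_meat", "diet_processed_meat", "smoking",
                "high_ldl", "lead_exposure"),
    canonical_name = c("All risk factors", "Behavioral risks", "Metabolic risks",
                       "Environmental/occupational risks", "Dietary risks",
                       "Tobacco", "Diet high in red meat",
                       "Diet high in processed meat", "Smoking",
                       "High LDL cholesterol", "Lead exposure"),
    level = c(0L, 1L, 1L, 1L, 2L, 2L, 3L, 3L, 3L, 2L, 2L),
    parent_id = c(NA, "all_risk", "all_risk", "all_risk",
                  "behavioral", "behavioral",
                  "dietary_risks", "dietary_risks", "tobacco",
                  "metabolic", "environmental_occupational"),
    group = c("all_risks", "behavioral", "metabolic", "environmental_occupational",
              "behavioral", "behavioral", "behavioral", "behavioral", "behavioral",
              "metabolic", "environmental_occupational")
  ))
}

tiny_map <- function() {
  validate_harmonization_map(tibble::tibble(
    raw_name = c("Diet high in red meat", "Diet high in red meat consumption",
                 "Diet high in processed meat", "Smoking",
                 "High LDL cholesterol", "Lead exposure"),
    iteration = c(NA, 2015L, NA, NA, NA, NA),
    risk_id = c("diet_red_meat", "diet_red_meat", "diet_processed_meat",
                "smoking", "high_ldl", "lead_exposure")
  ), tiny_hierarchy())
}

# small deterministic estimate table covering several iterations and revisits
tiny_table <- function() {
  grid <- expand.grid(
    risk = c("Diet high in red meat", "Diet high in processed meat",
             "Smoking", "High LDL cholesterol"),
    metric = c("deaths", "dalys"),
    iteration = c(2015L, 2017L, 2019L, 2021L),
    stringsAsFactors = FALSE
  )
  rows <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    years <- c(2015L, 2017L, 2019L, 2021L)
    years <- years[years <= g$iteration]
    data.frame(risk = g$risk, metric = g$metric, iteration = g$iteration,
               year = years,
               value = 1e5 + 1e3 * (match(g$risk, unique(grid$risk)) +
                                      0.1 * g$iteration + 0.01 * years),
               stringsAsFactors = FALSE)
  }))
  as_estimate_table(rows)
}

harmonized_tiny <- function() {
  harmonize(tiny_table(), tiny_map(), tiny_hierarchy())
}

write_tmp_csv <- function(df, name = "x.csv") {
  path <- file.path(withr::local_tempdir(.local_envir = parent.frame()), name)
  readr::write_csv(df, path, na = "", progress = FALSE)
  path
}

# independent brute-force oracles for the core statistics
oracle_rm <- function(x) {
  s <- sort(x)
  (s[length(s)] - s[1]) / (sum(x) / length(x))
}
oracle_cv <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  sqrt(sum((x - m)^2) / (n - 1)) / m
}
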