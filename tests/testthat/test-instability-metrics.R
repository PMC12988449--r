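# Range-to-mean, coefficient of variation, classification, rollups.

test_that("range_to_mean matches hand arithmetic and handles degenerate input", {
  expect_equal(range_to_mean(c(5, 5, 5)), 0)
  expect_equal(range_to_mean(c(2, 27, 97)), (97 - 2) / 42)
  expect_equal(range_to_mean(c(0, 0, 0)), 0)
  expect_error(range_to_mean(5), class = "revstab_insufficient_data")
  expect_error(range_to_mean(c(-1, 2)), class = "revstab_data_error")
})

test_that("a published summary row is inverse-consistent with the mean denominator", {
  # a series with min 25, max 896 and R:M 3.8 implies mean 871/3.8;
  # construct such a vector and check the statistic recovers 3.8
  target_mean <- (896 - 25) / 3.8
  filler <- rep((8 * target_mean - 25 - 896) / 6, 6)
  v <- c(25, 896, filler)
  expect_true(all(v >= 25 - 1e-9 & v <= 896))
  expect_equal(range_to_mean(v), 3.8)
  # a median denominator could not print 3.8 for a median near 73
  expect_equal(round_half_up((896 - 25) / 73, 1), 11.9)
})

test_that("coefficient_of_variation matches hand arithmetic and denominator options", {
  expect_equal(coefficient_of_variation(c(4, 4, 4, 4)), 0)
  expect_equal(coefficient_of_variation(c(1, 2, 3)), 0.5)
  expect_equal(coefficient_of_variation(c(1, 2, 3), sd_denominator = "n"),
               sqrt(2 / 3) / 2)
  expect_error(coefficient_of_variation(7), class = "revstab_insufficient_data")
})

test_that("both statistics agree with brute-force oracles on 1000 random vectors", {
  set.seed(101)
  for (i in 1:1000) {
    x <- runif(sample(2:8, 1), 0, 1e6)
    expect_lt(abs(range_to_mean(x) - oracle_rm(x)), 1e-12)
    expect_lt(abs(coefficient_of_variation(x) - oracle_cv(x)), 1e-12)
  }
})

test_that("two-value panels follow the closed form 2(b-a)/(a+b)", {
  set.seed(7)
  for (i in 1:200) {
    ab <- sort(runif(2, 0, 1e6))
    expect_equal(range_to_mean(ab), 2 * (ab[2] - ab[1]) / (ab[1] + ab[2]))
  }
})

test_that("both statistics are invariant to positive rescaling", {
  set.seed(13)
  for (i in 1:100) {
    x <- runif(sample(2:8, 1), 0, 100)
    c_ <- runif(1, 1e-6, 1e6)
    expect_equal(range_to_mean(c_ * x), range_to_mean(x), tolerance = 1e-12)
    expect_equal(coefficient_of_variation(c_ * x), coefficient_of_variation(x),
                 tolerance = 1e-12)
  }
})

test_that("rm and cv vanish together exactly on constant vectors", {
  set.seed(5)
  for (i in 1:50) {
    x <- runif(sample(2:8, 1), 0, 100)
    rm_v <- range_to_mean(x)
    cv_v <- coefficient_of_variation(x)
    expect_equal(rm_v == 0, cv_v == 0)
    k <- rep(runif(1, 0, 100), sample(2:8, 1))
    expect_identical(range_to_mean(k), 0)
    expect_identical(coefficient_of_variation(k), 0)
  }
})

test_that("classification uses strict greater-than at every boundary", {
  eps <- 1e-9
  expect_equal(as.character(classify_rm(c(0.3, 1, 1 + eps, 1.5, 1.5 + eps, 1.7))),
               c("low", "low", "concern", "concern", "extreme", "extreme"))
  expect_equal(as.character(classify_cv(c(0.1, 0.2, 0.2 + eps, 0.5, 0.5 + eps, 0.6))),
               c("low", "low", "high", "high", "very_high", "very_high"))
  both <- classify_instability(rm = 1.7, cv = 0.6)
  expect_equal(as.character(both$rm_flag), "extreme")
  expect_equal(as.character(both$cv_flag), "very_high")
})

test_that("summarize_panel populates all fields and ignores order", {
  s <- summarize_panel(c(10, 20, 30))
  expect_equal(s$n, 3)
  expect_equal(s$min, 10); expect_equal(s$max, 30)
  expect_equal(s$mean, 20); expect_equal(s$median, 20)
  expect_equal(s$rm, 1); expect_equal(s$cv, 0.5)
  expect_equal(as.character(s$rm_flag), "low")
  expect_equal(as.character(s$cv_flag), "high")
  expect_equal(summarize_panel(c(30, 10, 20)), s)
  k <- summarize_panel(c(7, 7, 7))
  expect_equal(k$rm, 0); expect_equal(k$cv, 0)
  expect_equal(as.character(k$rm_flag), "low")
  expect_equal(as.character(k$cv_flag), "low")
})

test_that("summarize_panels skips short panels into a ledger, never as zeros", {
  panels <- tibble::tibble(
    risk_id = c("a", "a", "a", "b"),
    metric = "deaths",
    year = c(2015L, 2015L, 2015L, 2016L),
    iteration = c(2015L, 2017L, 2019L, 2019L),
    value = c(1, 2, 3, 9)
  )
  s <- summarize_panels(panels, "matched_year")
  expect_equal(nrow(s), 1)
  expect_equal(s$risk_id, "a")
  skipped <- skipped_panels(s)
  expect_equal(skipped$risk_id, "b")
  expect_equal(skipped$n, 1L)
})

test_that("group rollups reproduce report-style counting and percentages", {
  h <- tiny_hierarchy()
  mk_sum <- function(n, n_hot, risk_id) {
    tibble::tibble(risk_id = risk_id, metric = "deaths",
                   context = "index_year",
                   rm = c(rep(1.2, n_hot), rep(0.4, n - n_hot)),
                   cv = 0.1)
  }
  # 34 behavioral summaries, 17 above 1 -> 50%
  s <- mk_sum(34, 17, "diet_red_meat")
  g <- summarize_group(s, h, by = "group")
  expect_equal(g$n_risks, 34)
  expect_equal(g$n_flagged_rm_gt1, 17)
  expect_equal(g$pct_rm_gt1, 50)
  # 675 summaries, 145 above 1 -> 21% by round-half-up of 21.48
  s2 <- mk_sum(675, 145, "smoking")
  g2 <- summarize_group(s2, h, by = "group")
  expect_equal(g2$pct_rm_gt1, 21)
  expect_equal(g2$proportion_rm_gt1, 145 / 675)
})

test_that("level-2 rollup attributes risks to their level-2 ancestor", {
  h <- tiny_hierarchy()
  s <- tibble::tibble(
    risk_id = c("diet_red_meat", "diet_processed_meat", "smoking"),
    metric = "deaths", context = "index_year",
    rm = c(2, 0.5, 0.2), cv = c(0.6, 0.3, 0.1))
  g <- summarize_group(s, h, by = "level2")
  expect_setequal(g$grouping, c("dietary_risks", "tobacco"))
  diet <- g[g$grouping == "dietary_risks", ]
  expect_equal(diet$n_risks, 2)
  expect_equal(diet$n_flagged_rm_gt1, 1)
})

test_that("round-half-up follows the reporting convention, not banker's rounding", {
  expect_equal(round_half_up(21.48), 21)
  expect_equal(round_half_up(0.5), 1)
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(1.25, 1), 1.3)
  expect_equal(percent_of(17, 34), 50)
  expect_equal(percent_of(145, 675), 21)
  expect_equal(percent_of(1209, 1260), 96)
})
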