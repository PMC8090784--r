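test_that("paired Cohen's d follows the mean/SD formula", {
  es <- paired_cohens_d(c(2, 4, 6), c(1, 2, 3)) # diffs 1, 2, 3
  expect_equal(es$d, 2)
  expect_equal(es$n, 3)
  se <- sqrt(1 / 3 + 4 / 6)
  expect_equal(es$ci_low, 2 - 1.96 * se, tolerance = 1e-12)
  expect_equal(es$ci_high, 2 + 1.96 * se, tolerance = 1e-12)

  x <- c(1.5, 2.5, 3)
  expect_equal(paired_cohens_d(x, x)$d, 0)
  expect_error(paired_cohens_d(c(2, 3), c(1, 2)), "zero SD")
  expect_error(paired_cohens_d(1, 1), "at least 2")
})

test_that("paired Cohen's d is antisymmetric and its CI shrinks with n", {
  set.seed(40)
  x <- rnorm(15); y <- rnorm(15)
  expect_equal(paired_cohens_d(x, y)$d, -paired_cohens_d(y, x)$d)

  widths <- vapply(c(10, 100, 1000), function(n) {
    d <- 0.5
    2 * 1.96 * sqrt(1 / n + d^2 / (2 * n))
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_equal(widths[1] / widths[3], sqrt(100), tolerance = 1e-12)
})

test_that("within-group comparisons mirror the 15 region pairs per group", {
  co <- generate_cohort(separated_config(seed = 51))
  rates <- annualized_rates(exclusion_filter(co$visits))
  part <- cluster_cohort(co, k = 4)
  tab <- within_group_structure_comparisons(rates, part)
  expect_equal(nrow(tab), k_effective(part) * 15)
  expect_true(all(tab$ci_low <= tab$mean_diff &
                    tab$mean_diff <= tab$ci_high))
  expect_true(all(tab$d_ci_low <= tab$d & tab$d <= tab$d_ci_high,
                  na.rm = TRUE))
})

test_that("a planted spinal-cord-dominant group shows large negative contrasts", {
  # emulate a pattern like the most aggressive reference group: spinal
  # cord loss far exceeding every other region
  set.seed(52)
  n <- 14
  rates <- tibble::tibble(
    patient_id = paste0("P", 1:n),
    sc = rnorm(n, -3.8, 0.5), striatum = rnorm(n, -1.3, 0.5),
    gp = rnorm(n, -1.6, 0.5), thalamus = rnorm(n, -2.6, 0.5),
    cgm = rnorm(n, -1.0, 0.5), wm = rnorm(n, -1.5, 0.5)
  )
  part <- tibble::tibble(patient_id = rates$patient_id, group = 1L,
                         outlier = FALSE)
  tab <- within_group_structure_comparisons(rates, part)
  sc_rows <- tab[tab$region_a == "sc" & tab$region_b != "thalamus", ]
  expect_true(all(sc_rows$mean_diff < 0))
  expect_true(all(abs(sc_rows$d) > 1))
})

test_that("identical regions give zero difference and effect size", {
  rates <- tibble::tibble(
    patient_id = paste0("P", 1:5),
    sc = 1:5, striatum = 1:5, gp = 1:5, thalamus = 1:5,
    cgm = 1:5, wm = 1:5
  )
  part <- tibble::tibble(patient_id = rates$patient_id, group = 1L,
                         outlier = FALSE)
  tab <- suppressWarnings(within_group_structure_comparisons(rates, part))
  expect_equal(tab$mean_diff, rep(0, 15))
  expect_equal(tab$d, rep(0, 15))
})

test_that("undersized groups are skipped with a warning", {
  rates <- tibble::tibble(
    patient_id = paste0("P", 1:3),
    sc = c(1, 2, 3), striatum = c(2, 1, 3), gp = c(1, 3, 2),
    thalamus = c(3, 1, 2), cgm = c(2, 3, 1), wm = c(3, 2, 1)
  )
  part <- tibble::tibble(patient_id = rates$patient_id,
                         group = c(1L, 1L, 2L), outlier = FALSE)
  expect_warning(tab <- within_group_structure_comparisons(rates, part),
                 "fewer than 2")
  expect_equal(unique(tab$group), 1L)
})

test_that("clinical transforms match their definitions and preserve order", {
  expect_equal(transform_clinical(0, "EDSS"), 0)
  expect_equal(transform_clinical(c(10, 100), "D9HPT"),
               c(log(10), log(100)))
  expect_equal(diff(transform_clinical(c(10, 100), "D9HPT")), log(10))
  expect_equal(transform_clinical(1, "T25fwt"), 1)

  v <- c(0.5, 2, 4, 6.5)
  expect_true(all(diff(transform_clinical(v, "EDSS")) > 0))
  expect_true(all(diff(transform_clinical(v, "ND9HPT")) > 0))
  expect_true(all(diff(transform_clinical(v, "T25fwt")) < 0))

  expect_error(transform_clinical(-1, "EDSS"), ">= 0")
  expect_error(transform_clinical(0, "D9HPT"), "> 0")
  expect_error(transform_clinical(0, "T25fwt"), "> 0")
})

test_that("relapse rates annualize per patient, not pooled", {
  expect_equal(annual_relapse_rate(0, 2), 0)
  expect_equal(annual_relapse_rate(3, 2), 1.5)
  expect_error(annual_relapse_rate(1, 0), "> 0")

  v <- dplyr::bind_rows(
    make_visits("P1", 0:2, matrix(1, 3, 6)),
    make_visits("P2", 0:1, matrix(1, 2, 6))
  )
  v$relapses_since_last_visit <- c(NA, 2, 2, NA, 1)
  part <- tibble::tibble(patient_id = c("P1", "P2"), group = 1L,
                         outlier = FALSE)
  s <- relapse_rate_summary(v, part)
  expect_equal(s$arr_mean, mean(c(4 / 2, 1 / 1)))
})

test_that("progression events follow the EDSS step rule with relapse guard", {
  # flat series: censored at last visit
  flat <- progression_events(c(0, 1, 2), c(3, 3, 3))
  expect_false(flat$event)
  expect_equal(flat$time_years, 2)

  # baseline 4.0 rising by half-points: event at the 1-point mark
  ev <- progression_events(c(0, 1, 2), c(4.0, 4.5, 5.0))
  expect_true(ev$event)
  expect_equal(ev$time_years, 2)

  # high baseline: 0.5-point rule, but a relapse 6 months before blocks it
  blocked <- progression_events(c(0, 1), c(6.0, 6.5),
                                relapse_times = 0.5)
  expect_false(blocked$event)

  # same series without the relapse qualifies
  free <- progression_events(c(0, 1), c(6.0, 6.5))
  expect_true(free$event)
  expect_equal(free$time_years, 1)
})

test_that("non-qualifying intermediate visits do not change the event", {
  base <- progression_events(c(0, 2), c(3.0, 4.0))
  padded <- progression_events(c(0, 0.5, 1, 1.5, 2),
                               c(3.0, 3.0, 3.5, 3.5, 4.0))
  expect_equal(base$event, padded$event)
  expect_equal(base$time_years, padded$time_years)

  expect_warning(
    skipped <- progression_events(c(0, 1, 2), c(3.0, NA, 4.0)),
    "skipped"
  )
  expect_true(skipped$event)
  expect_equal(skipped$time_years, 2)
})

test_that("the cohort progression table runs per patient", {
  v <- dplyr::bind_rows(
    make_visits("P1", 0:2, matrix(1, 3, 6)),
    make_visits("P2", 0:1, matrix(1, 2, 6))
  )
  v$edss <- c(3, 3, 4.5, 6, 6.5)
  v$relapses_since_last_visit <- c(NA, 0, 0, NA, 0)
  tab <- progression_table(v)
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$event))
  expect_equal(tab$time_years, c(2, 1))
})
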