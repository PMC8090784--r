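test_that("weight sampling assigns the scheme's counts exactly", {
  set.seed(1)
  w <- sample_weights(10)
  expect_equal(sum(w == 0.0001), 1)
  expect_equal(sum(w == 2), 1)
  expect_equal(sum(w == 1), 8)

  expect_equal(sample_weights(10, weight_scheme(frac_down = 0,
                                                frac_up = 0)),
               rep(1, 10))
  expect_error(weight_scheme(frac_down = 0.6, frac_up = 0.6), "sum")
  expect_error(weight_scheme(w_down = 0), "> 0")
  expect_error(sample_weights(2), ">= 3")
})

test_that("each patient is down-weighted at the nominal frequency", {
  set.seed(2)
  n <- 225
  draws <- 400
  hits <- numeric(n)
  for (i in seq_len(draws)) {
    hits <- hits + (sample_weights(n) == 0.0001)
  }
  freq <- hits / draws
  p_nominal <- round(0.1 * n) / n
  expect_equal(mean(freq), p_nominal, tolerance = 1e-9)
  se <- sqrt(p_nominal * (1 - p_nominal) / draws)
  expect_true(all(abs(freq - p_nominal) < 5 * se))
})

test_that("ARI matches pair counting and its invariances", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 3), c(1, 1, 2, 3)), 1)
  # relabeling one partition changes nothing
  expect_equal(adjusted_rand_index(c(1, 1, 2, 3), c(9, 9, 7, 5)), 1)
  # symmetry, exactly
  set.seed(10)
  for (i in 1:20) {
    a <- random_partition(30); b <- random_partition(30)
    expect_identical(adjusted_rand_index(a, b),
                     adjusted_rand_index(b, a))
  }
  # both trivial -> 1 by convention
  expect_equal(adjusted_rand_index(rep(1, 5), rep(2, 5)), 1)
  expect_error(adjusted_rand_index(1, 1), "at least 2")
})

test_that("ARI agrees with an established implementation", {
  skip_if_not_installed("mclust")
  set.seed(11)
  for (i in 1:20) {
    a <- random_partition(40); b <- random_partition(40)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})

test_that("VI attains its printed extremes in base 10", {
  expect_equal(variation_of_information(1:225, rep(1, 225)), log10(225),
               tolerance = 1e-12)
  p <- rep(1:4, c(14, 59, 141, 11))
  expect_equal(variation_of_information(p, p), 0, tolerance = 1e-12)
})

test_that("VI matches a direct contingency-table computation", {
  p <- c("A", "A", "B", "B")
  q <- c("A", "A", "A", "B")
  # independent oracle: explicit entropies of the 2x2 table
  tab <- matrix(c(2, 0, 1, 1), 2, byrow = TRUE) / 4
  hp <- -sum(rowSums(tab) * log10(rowSums(tab)))
  hq <- -sum(colSums(tab) * log10(colSums(tab)))
  nz <- tab > 0
  mi <- sum(tab[nz] * log10(tab[nz] /
                              outer(rowSums(tab), colSums(tab))[nz]))
  expect_equal(variation_of_information(p, q), hp + hq - 2 * mi,
               tolerance = 1e-12)
})

test_that("VI is a bounded metric on partitions", {
  skip_if_not_installed("igraph")
  set.seed(12)
  for (i in 1:100) {
    a <- random_partition(30); b <- random_partition(30)
    c_ <- random_partition(30)
    vab <- variation_of_information(a, b)
    expect_identical(vab, variation_of_information(b, a))
    expect_lte(vab, log10(30) + 1e-12)
    expect_gte(vab, 0)
    # triangle inequality
    expect_lte(vab, variation_of_information(a, c_) +
                 variation_of_information(c_, b) + 1e-12)
  }
  # cross-check base conversion against igraph's natural-log VI
  set.seed(13)
  a <- random_partition(50); b <- random_partition(50)
  expect_equal(variation_of_information(a, b) * log(10),
               igraph::compare(a, b, method = "vi"), tolerance = 1e-10)
})

test_that("partition tibbles are aligned on shared non-outlier items", {
  p <- tibble::tibble(patient_id = paste0("P", 1:6),
                      group = c(1, 1, 2, 2, 3, NA),
                      outlier = c(rep(FALSE, 5), TRUE))
  q <- tibble::tibble(patient_id = paste0("P", c(1:5, 7)),
                      group = c(1, 1, 2, 2, 3, 1),
                      outlier = FALSE)
  expect_equal(adjusted_rand_index(p, q), 1)
  expect_equal(variation_of_information(p, q), 0)
})

test_that("an unperturbed scheme reproduces the reference exactly", {
  co <- generate_cohort(separated_config(seed = 21))
  rates <- annualized_rates(exclusion_filter(co$visits))
  res <- age_residuals(rates, co$patients)
  ref <- cluster_cohort(co, k = 4)
  st <- run_stability(res, ref, n_reps = 20,
                      scheme = weight_scheme(frac_down = 0, frac_up = 0),
                      seed = 3)
  expect_equal(st$summary$ari_mean, 1)
  expect_equal(st$summary$ari_sd, 0)
  expect_equal(st$summary$vi_mean, 0)
})

test_that("well-separated planted groups stay stable under perturbation", {
  co <- generate_cohort(separated_config(seed = 42))
  rates <- annualized_rates(exclusion_filter(co$visits))
  res <- age_residuals(rates, co$patients)
  ref <- cluster_cohort(co, k = 4)
  st <- run_stability(res, ref, n_reps = 200, seed = 5)
  expect_gte(st$summary$ari_mean, 0.9)
  expect_equal(st$summary$n_failed, 0)
})

test_that("stability runs are reproducible and splittable by repetition", {
  co <- generate_cohort(separated_config(seed = 33))
  rates <- annualized_rates(exclusion_filter(co$visits))
  res <- age_residuals(rates, co$patients)
  ref <- cluster_cohort(co, k = 4)

  full <- run_stability(res, ref, n_reps = 20, seed = 9)
  again <- run_stability(res, ref, n_reps = 20, seed = 9)
  expect_identical(full$reps, again$reps)

  first <- run_stability(res, ref, n_reps = 20, seed = 9,
                         rep_range = 1:10)
  second <- run_stability(res, ref, n_reps = 20, seed = 9,
                          rep_range = 11:20)
  expect_equal(dplyr::bind_rows(first$reps, second$reps), full$reps)

  one <- run_stability(res, ref, n_reps = 1, seed = 9)
  expect_equal(one$summary$ari_sd, 0)
  expect_equal(one$summary$vi_sd, 0)
})
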