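# Shared fixtures and independent oracles.

# Build a visit tibble for one patient from a time vector and a volume
# matrix (rows = visits, cols = 6 regions in canonical order).
make_visits <- function(patient_id, t, vols) {
  vols <- matrix(vols, nrow = length(t))
  stopifnot(ncol(vols) == 6)
  tibble::tibble(
    patient_id = patient_id, t_years = t,
    sc_vol = vols[, 1], striatum_vol = vols[, 2], gp_vol = vols[, 3],
    thalamus_vol = vols[, 4], cgm_vol = vols[, 5], wm_vol = vols[, 6]
  )
}

# Constant-volume visits for a set of patients (handy filler).
flat_visits <- function(ids, n_visits = 3) {
  dplyr::bind_rows(lapply(ids, function(id) {
    make_visits(id, seq_len(n_visits) - 1,
                matrix(rep(c(2.4, 21, 3.2, 13, 645, 733), each = n_visits),
                       nrow = n_visits))
  }))
}

# Independent Ward oracle: greedy agglomeration that at each step merges
# the pair of clusters with the smallest increase in total within-cluster
# sum of squares. Returns the sequence of partitions (one per merge) and
# the ward.D2-style heights sqrt(2 * delta-ESS).
brute_ward <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  clusters <- as.list(seq_len(n))
  partitions <- list()
  heights <- numeric(0)
  delta_ess <- function(a, b) {
    na <- length(a); nb <- length(b)
    ca <- colMeans(X[a, , drop = FALSE])
    cb <- colMeans(X[b, , drop = FALSE])
    na * nb / (na + nb) * sum((ca - cb)^2)
  }
  while (length(clusters) > 1) {
    best <- NULL; best_cost <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        cost <- delta_ess(clusters[[i]], clusters[[j]])
        if (cost < best_cost) { best_cost <- cost; best <- c(i, j) }
      }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
    heights <- c(heights, sqrt(2 * best_cost))
    lab <- integer(n)
    for (ci in seq_along(clusters)) lab[clusters[[ci]]] <- ci
    partitions[[length(partitions) + 1]] <- lab
  }
  list(partitions = partitions, heights = heights)
}

# Random partition labels of n items into at most kmax groups.
random_partition <- function(n, kmax = 5) {
  sample.int(kmax, n, replace = TRUE)
}

# A well-separated four-group profile set (large mean gaps, small SDs)
# for tests that need a recoverable planted structure.
separated_profiles <- function() {
  list(
    group_profile("W", 20, rate_mean = c(-8, -8, -8, -8, -8, -8),
                  rate_sd = rep(0.3, 6), mean_followups = 4),
    group_profile("X", 30, rate_mean = c(0, 0, 0, 0, 0, 0),
                  rate_sd = rep(0.3, 6), mean_followups = 4),
    group_profile("Y", 25, rate_mean = c(8, 8, -8, -8, 0, 0),
                  rate_sd = rep(0.3, 6), mean_followups = 4),
    group_profile("Z", 15, rate_mean = c(8, 8, 8, 8, 8, 8),
                  rate_sd = rep(0.3, 6), mean_followups = 4)
  )
}

separated_config <- function(seed = 42) {
  cohort_config(group_profiles = separated_profiles(),
                noise_cv = 0.001, age_slope = 0,
                p_session_missing = 0, seed = seed)
}

# Planted-label recovery ARI for one generated cohort and a fitted
# partition, over the patients present in both.
recovery_ari <- function(partition, truth) {
  m <- dplyr::inner_join(
    partition[!partition$outlier & !is.na(partition$group),
              c("patient_id", "group")],
    truth[, c("patient_id", "group")],
    by = "patient_id", suffix = c("_fit", "_true")
  )
  adjusted_rand_index(m$group_fit, m$group_true)
}

# Full rates -> residuals -> PCA -> Ward pipeline at a fixed k, returning
# the outlier-flagged partition.
cluster_cohort <- function(cohort, k, min_size = 2) {
  filtered <- exclusion_filter(cohort$visits)
  rates <- annualized_rates(filtered)
  res <- age_residuals(rates, cohort$patients)
  pca <- weighted_pca(res)
  sel <- suppressWarnings(select_components(pca))
  scores <- pca$scores[, c("patient_id", paste0("PC", sel$retained))]
  flag_outliers(cut_dendrogram(ward_linkage(scores), k), min_size)
}
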