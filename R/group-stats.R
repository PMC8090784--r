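#' Paired Cohen's d with normal-approximation confidence interval
#'
#' `d = mean(x - y) / sd(x - y)` with the sample SD (n - 1 denominator);
#' the 95% interval is `d +/- 1.96 * sqrt(1/n + d^2 / (2n))`. When all
#' paired differences are identical the effect size is undefined unless
#' the common difference is zero, in which case `d = 0`.
#'
#' @param x,y Equal-length numeric vectors paired by patient (n >= 2).
#' @return Tibble with `d`, `ci_low`, `ci_high`, `n`.
#' @export
#' @examples
#' paired_cohens_d(c(2, 4, 6), c(1, 2, 3)) # d = 2
paired_cohens_d <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  n <- length(x)
  if (n < 2) abort("need at least 2 pairs")
  diffs <- x - y
  s <- sd(diffs)
  if (s == 0) {
    if (mean(diffs) == 0) {
      return(tibble::tibble(d = 0, ci_low = 0, ci_high = 0, n = n))
    }
    abort("paired differences have zero SD with nonzero mean; effect size undefined")
  }
  d <- mean(diffs) / s
  se <- sqrt(1 / n + d^2 / (2 * n))
  tibble::tibble(d = d, ci_low = d - 1.96 * se, ci_high = d + 1.96 * se,
                 n = n)
}

#' Within-group comparisons between CNS structures
#'
#' For every non-outlier group and each of the 15 unordered region pairs,
#' compares the two regions' atrophy rates across the group's patients
#' with a paired t-test (mean difference, 95% CI, t, p) and a paired
#' Cohen's d with its 95% CI. Differences are `region_a - region_b` in the
#' canonical region order. Groups with fewer than 2 patients are skipped
#' with a warning.
#'
#' @param rates Rate (or residual) tibble with `patient_id` and the six
#'   region columns.
#' @param partition Partition tibble (`patient_id`, `group`, `outlier`).
#' @return Tidy tibble: `group`, `region_a`, `region_b`, `n`, `mean_diff`,
#'   `ci_low`, `ci_high`, `t`, `df`, `p_value`, `d`, `d_ci_low`,
#'   `d_ci_high` — `k_effective * 15` rows.
#' @export
within_group_structure_comparisons <- function(rates, partition) {
  keys <- region_keys()
  pairs <- combn(keys, 2)
  d <- dplyr::inner_join(
    rates,
    partition[!partition$outlier & !is.na(partition$group),
              c("patient_id", "group")],
    by = "patient_id"
  )
  groups <- sort(unique(d$group))
  rows <- list()
  for (g in groups) {
    dg <- d[d$group == g, ]
    if (nrow(dg) < 2) {
      warn(paste0("group ", g, " has fewer than 2 patients; skipped"))
      next
    }
    for (j in seq_len(ncol(pairs))) {
      a <- dg[[pairs[1, j]]]
      b <- dg[[pairs[2, j]]]
      # constant differences make the paired t statistic undefined; the
      # mean difference itself is still reported
      tt <- tryCatch(t.test(a, b, paired = TRUE), error = function(e) {
        list(estimate = mean(a - b),
             conf.int = c(mean(a - b), mean(a - b)),
             statistic = NA_real_, parameter = length(a) - 1,
             p.value = NA_real_)
      })
      es <- tryCatch(paired_cohens_d(a, b), error = function(e) {
        tibble::tibble(d = NA_real_, ci_low = NA_real_,
                       ci_high = NA_real_, n = length(a))
      })
      rows[[length(rows) + 1]] <- tibble::tibble(
        group = g, region_a = pairs[1, j], region_b = pairs[2, j],
        n = nrow(dg),
        mean_diff = unname(tt$estimate),
        ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
        t = unname(tt$statistic), df = unname(tt$parameter),
        p_value = tt$p.value,
        d = es$d, d_ci_low = es$ci_low, d_ci_high = es$ci_high
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Normalizing transforms for clinical measures
#'
#' EDSS is log-transformed with a +1 offset (the scale includes 0); the
#' 9-hole peg test times are log-transformed; the timed 25-foot walk is
#' inverse-transformed (so larger transformed values mean better
#' performance).
#'
#' @param values Numeric vector.
#' @param kind One of `"EDSS"`, `"D9HPT"`, `"ND9HPT"`, `"T25fwt"`.
#' @return Transformed numeric vector.
#' @export
#' @examples
#' transform_clinical(0, "EDSS")   # 0
#' transform_clinical(1, "T25fwt") # 1
transform_clinical <- function(values, kind = c("EDSS", "D9HPT",
                                                "ND9HPT", "T25fwt")) {
  kind <- match.arg(kind)
  switch(kind,
    EDSS = {
      if (any(values < 0, na.rm = TRUE)) abort("EDSS must be >= 0")
      log(values + 1)
    },
    D9HPT = ,
    ND9HPT = {
      if (any(values <= 0, na.rm = TRUE)) abort("9HPT times must be > 0")
      log(values)
    },
    T25fwt = {
      if (any(values <= 0, na.rm = TRUE)) abort("T25fwt must be > 0")
      1 / values
    }
  )
}

#' Annualized relapse rate
#'
#' Total relapses divided by the follow-up span, per patient.
#'
#' @param relapse_counts Total relapse count per patient (vector).
#' @param followup_years Follow-up span per patient (> 0).
#' @return Numeric vector of relapses per year.
#' @export
annual_relapse_rate <- function(relapse_counts, followup_years) {
  if (any(followup_years <= 0, na.rm = TRUE)) {
    abort("`followup_years` must be > 0")
  }
  relapse_counts / followup_years
}

#' Per-group relapse-rate summary
#'
#' Sums each patient's interval relapse counts, divides by the follow-up
#' span, and summarizes per group as mean and SD of the per-patient rates
#' (not pooled counts).
#'
#' @param visits Visit tibble with `patient_id`, `t_years`,
#'   `relapses_since_last_visit`.
#' @param partition Partition tibble.
#' @return Tibble: `group`, `n`, `arr_mean`, `arr_sd`.
#' @export
relapse_rate_summary <- function(visits, partition) {
  per_patient <- visits |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      relapses = sum(.data$relapses_since_last_visit, na.rm = TRUE),
      followup = max(.data$t_years) - min(.data$t_years),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$followup > 0) |>
    dplyr::mutate(arr = annual_relapse_rate(.data$relapses, .data$followup))
  per_patient |>
    dplyr::inner_join(
      partition[!partition$outlier & !is.na(partition$group),
                c("patient_id", "group")],
      by = "patient_id"
    ) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(), arr_mean = mean(.data$arr),
                     arr_sd = sd(.data$arr), .groups = "drop")
}

#' Detect a confirmed EDSS progression event
#'
#' Scans a time-ordered EDSS series for the first visit at which the score
#' has increased from baseline by at least 1.0 point (baseline EDSS <=
#' 5.5) or 0.5 point (baseline EDSS > 5.5), with no relapse in the 12
#' months preceding that visit. Visits with missing EDSS are skipped with
#' a warning. If no visit qualifies, the patient is censored at the last
#' visit.
#'
#' @param t_years Visit times (years, ascending, baseline first).
#' @param edss EDSS at each visit.
#' @param relapse_times Times (years) of relapses, if any.
#' @param baseline_edss Baseline score; defaults to the first visit's
#'   EDSS.
#' @return Tibble with `event` (logical) and `time_years`.
#' @export
#' @examples
#' progression_events(c(0, 1, 2), c(4.0, 4.5, 5.0)) # event at year 2
progression_events <- function(t_years, edss, relapse_times = numeric(0),
                               baseline_edss = NULL) {
  if (is.unsorted(t_years, strictly = TRUE)) {
    abort("`t_years` must be strictly increasing")
  }
  if (length(t_years) != length(edss)) {
    abort("`t_years` and `edss` must have equal length")
  }
  if (is.null(baseline_edss)) baseline_edss <- edss[1]
  if (is.na(baseline_edss)) abort("baseline EDSS is missing")
  threshold <- if (baseline_edss <= 5.5) 1.0 else 0.5
  for (i in seq_along(t_years)[-1]) {
    if (is.na(edss[i])) {
      warn(paste0("missing EDSS at t = ", t_years[i], "; visit skipped"))
      next
    }
    qualifying <- (edss[i] - baseline_edss) >= threshold
    recent_relapse <- any(relapse_times > t_years[i] - 1 &
                            relapse_times <= t_years[i])
    if (qualifying && !recent_relapse) {
      return(tibble::tibble(event = TRUE, time_years = t_years[i]))
    }
  }
  tibble::tibble(event = FALSE, time_years = t_years[length(t_years)])
}

#' Per-patient progression events for a cohort
#'
#' Applies [progression_events()] to every patient in a visit table.
#' Interval-reported relapse counts are converted to relapse times at the
#' midpoint of the reporting interval (the table records counts since the
#' previous visit, not dates).
#'
#' @param visits Visit tibble with `patient_id`, `t_years`, `edss` and
#'   `relapses_since_last_visit`.
#' @return Tibble: `patient_id`, `event`, `time_years`.
#' @export
progression_table <- function(visits) {
  visits |>
    dplyr::arrange(.data$patient_id, .data$t_years) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_modify(function(d, key) {
      counts <- d$relapses_since_last_visit
      mids <- (d$t_years + dplyr::lag(d$t_years)) / 2
      rel <- rep(mids[-1], pmax(counts[-1], 0, na.rm = TRUE))
      progression_events(d$t_years, d$edss, relapse_times = rel)
    }) |>
    dplyr::ungroup()
}

#' Per-group rate summary table
#'
#' Group-by-region mean, SD and range of the annualized rates, in the
#' layout of a cohort characteristics table.
#'
#' @param rates Rate tibble.
#' @param partition Partition tibble.
#' @return Tidy tibble: `group`, `region`, `n`, `mean`, `sd`, `min`,
#'   `max`.
#' @export
group_summary <- function(rates, partition) {
  keys <- region_keys()
  rates |>
    dplyr::inner_join(
      partition[!partition$outlier & !is.na(partition$group),
                c("patient_id", "group")],
      by = "patient_id"
    ) |>
    tidyr::pivot_longer(dplyr::all_of(keys), names_to = "region",
                        values_to = "rate") |>
    dplyr::group_by(.data$group, .data$region) |>
    dplyr::summarise(
      n = dplyr::n(), mean = mean(.data$rate), sd = sd(.data$rate),
      min = min(.data$rate), max = max(.data$rate), .groups = "drop"
    ) |>
    dplyr::mutate(region = factor(.data$region, levels = keys)) |>
    dplyr::arrange(.data$group, .data$region)
}
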