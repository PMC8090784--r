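#' Define a latent patient group for the cohort simulator
#'
#' A group profile describes one latent atrophy-pattern group: how many
#' patients it contains, the per-region mean and SD of the true annual
#' percent volume change, the typical number of MRI sessions, and the
#' annualized relapse rate used to simulate relapse counts.
#'
#' @param label Group label (single string).
#' @param n_patients Number of patients in the group.
#' @param rate_mean Numeric length-6 vector of mean annual percent volume
#'   change (%/year) in the order of [cns_regions()].
#' @param rate_sd Numeric length-6 vector of between-patient SDs (%/year),
#'   all non-negative.
#' @param mean_followups Mean number of MRI sessions per patient (>= 1).
#' @param relapse_rate Mean relapses per patient-year (>= 0).
#' @return A `group_profile` list.
#' @export
group_profile <- function(label, n_patients, rate_mean, rate_sd,
                          mean_followups = 4, relapse_rate = 0.2) {
  stopifnot(is.character(label), length(label) == 1)
  if (n_patients < 1) abort("`n_patients` must be >= 1")
  if (length(rate_mean) != 6 || length(rate_sd) != 6) {
    abort("`rate_mean` and `rate_sd` must have length 6 (one per region)")
  }
  if (any(rate_sd < 0)) abort("`rate_sd` must be non-negative")
  if (mean_followups < 1) abort("`mean_followups` must be >= 1")
  structure(
    list(
      label = label, n_patients = as.integer(n_patients),
      rate_mean = setNames(as.numeric(rate_mean), region_keys()),
      rate_sd = setNames(as.numeric(rate_sd), region_keys()),
      mean_followups = mean_followups, relapse_rate = relapse_rate
    ),
    class = "group_profile"
  )
}

#' Default group profiles of the reference MS cohort
#'
#' Four latent groups mirroring the published stratification of 225
#' relapse-onset and progressive MS patients: group A (n = 14, marked
#' spinal-cord and thalamic loss), group B (n = 59, predominant pallidal
#' loss), group C (n = 141, near-stable volumes) and group D (n = 11,
#' paradoxical spinal-cord and cortical volume increase with white-matter
#' loss). Rate means and SDs are the reported per-group annual volume
#' changes; follow-up counts are the reported per-group session means.
#'
#' @return A named list of four [group_profile()] objects.
#' @export
default_group_profiles <- function() {
  list(
    A = group_profile(
      "A", 14,
      rate_mean = c(-3.82, -1.27, -1.65, -2.65, -1.03, -1.50),
      rate_sd   = c(1.97, 1.04, 2.37, 1.59, 1.42, 1.61),
      mean_followups = 3.00, relapse_rate = 0.25
    ),
    B = group_profile(
      "B", 59,
      rate_mean = c(-0.67, -0.54, -1.61, -0.67, -1.28, -0.40),
      rate_sd   = c(0.97, 0.84, 1.09, 0.87, 1.05, 1.01),
      mean_followups = 4.19, relapse_rate = 0.20
    ),
    C = group_profile(
      "C", 141,
      rate_mean = c(-0.18, 0.15, -0.33, 0.05, -0.06, 0.03),
      rate_sd   = c(0.66, 0.53, 0.79, 0.57, 0.61, 0.54),
      mean_followups = 5.34, relapse_rate = 0.15
    ),
    D = group_profile(
      "D", 11,
      rate_mean = c(1.29, -0.58, -0.55, -0.28, 2.82, -1.37),
      rate_sd   = c(1.32, 0.80, 1.50, 1.10, 1.41, 1.02),
      mean_followups = 2.64, relapse_rate = 0.20
    )
  )
}

#' Configuration of the synthetic-cohort generator
#'
#' Collects every knob of the simulator. Baseline region volumes default to
#' the cohort-weighted means of the reference study's per-group baseline
#' volumes (cm^3). Measurement noise is multiplicative log-normal with
#' coefficient of variation `noise_cv`; the age effect adds
#' `age_slope * (age - age_mean)` %/year to every region's true rate.
#'
#' @param group_profiles List of [group_profile()] objects.
#' @param age_mean,age_sd Baseline age distribution (years).
#' @param baseline_volume_mean,baseline_volume_sd Length-6 per-region
#'   baseline volume mean and SD (cm^3), order of [cns_regions()].
#' @param noise_cv Coefficient of variation of the multiplicative
#'   measurement error on each observed volume (>= 0).
#' @param age_slope Added %/year of rate per year of age above `age_mean`,
#'   applied identically in every region.
#' @param visit_spacing Scheduled inter-visit interval (years).
#' @param max_followup Maximum follow-up span (years).
#' @param followup_sd SD of the per-patient session count around its group
#'   mean before rounding and clamping to `[2, max_followup/visit_spacing + 1]`.
#' @param p_session_missing Probability that a non-baseline session is
#'   unusable and removed (in `[0, 1)`). Defaults to the reference study's
#'   observed failed-session fraction (162/1271).
#' @param outlier_archetype If `TRUE`, inject a single extra patient whose
#'   true rates lie at least 4 SD below every group profile in every region
#'   (emulating an unclassifiable outlier).
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration and seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(group_profiles = default_group_profiles(),
                          age_mean = 44.7, age_sd = 10.7,
                          baseline_volume_mean =
                            c(2.38, 20.9, 3.21, 13.0, 645.5, 733.6),
                          baseline_volume_sd =
                            c(0.32, 2.40, 0.35, 2.00, 54.0, 50.0),
                          noise_cv = 0.005,
                          age_slope = -0.02,
                          visit_spacing = 1,
                          max_followup = 6,
                          followup_sd = 1.4,
                          p_session_missing = 162 / 1271,
                          outlier_archetype = FALSE,
                          seed = 1L) {
  if (noise_cv < 0) abort("`noise_cv` must be >= 0")
  if (p_session_missing < 0 || p_session_missing >= 1) {
    abort("`p_session_missing` must be in [0, 1)")
  }
  if (length(baseline_volume_mean) != 6 || length(baseline_volume_sd) != 6) {
    abort("baseline volume mean/sd must have length 6")
  }
  if (!all(vapply(group_profiles, inherits, logical(1), "group_profile"))) {
    abort("`group_profiles` must be a list of group_profile objects")
  }
  if (sum(vapply(group_profiles, `[[`, integer(1), "n_patients")) < 1) {
    abort("total number of patients must be positive")
  }
  structure(
    list(
      group_profiles = group_profiles,
      age_mean = age_mean, age_sd = age_sd,
      baseline_volume_mean = setNames(baseline_volume_mean, region_keys()),
      baseline_volume_sd = setNames(baseline_volume_sd, region_keys()),
      noise_cv = noise_cv, age_slope = age_slope,
      visit_spacing = visit_spacing, max_followup = max_followup,
      followup_sd = followup_sd,
      p_session_missing = p_session_missing,
      outlier_archetype = outlier_archetype,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

rhalf <- function(n, center, sd, lo, hi) {
  pmin(pmax(round(rnorm(n, center, sd) * 2) / 2, lo), hi)
}

draw_positive <- function(mean, sd, what, max_tries = 100) {
  for (i in seq_len(max_tries)) {
    v <- rnorm(1, mean, sd)
    if (v > 0) return(v)
  }
  abort(paste0("could not draw a positive ", what,
               " after ", max_tries, " tries (mean = ", mean,
               ", sd = ", sd, ")"))
}

#' Generate a synthetic longitudinal MS cohort
#'
#' Simulates per-visit region volumes with planted group structure. Each
#' patient receives a true per-region annual percent change drawn from its
#' group profile plus a linear age effect; observed volumes follow the
#' geometric trajectory `V0 * (1 + r/100)^t` perturbed by mean-one
#' log-normal noise with coefficient of variation `noise_cv`. Non-baseline
#' sessions are then removed independently with probability
#' `p_session_missing` (see [apply_missingness()]).
#'
#' @param config A [cohort_config()].
#' @return A list of class `ms_cohort` with tibbles:
#'   * `visits`: `patient_id`, `t_years`, six `<region>_vol` columns, and
#'     clinical fields (`edss`, `t25fwt`, `d9hpt`, `nd9hpt`, `snfl`,
#'     `t2lv`, `relapses_since_last_visit`);
#'   * `patients`: `patient_id`, `baseline_age`, `sex`, `disease_duration`,
#'     `phenotype`, `treated`;
#'   * `truth`: `patient_id`, `group`, and the six planted true rates.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 42))
#' dplyr::count(cohort$truth, group)
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  keys <- region_keys()

  labels <- unlist(lapply(config$group_profiles, function(p) {
    rep(p$label, p$n_patients)
  }), use.names = FALSE)
  n <- length(labels)
  profile_of <- setNames(
    config$group_profiles,
    vapply(config$group_profiles, `[[`, character(1), "label")
  )

  ids <- sprintf("P%03d", seq_len(n))
  n_visits_max <- floor(config$max_followup / config$visit_spacing) + 1

  # EDSS baseline medians by group of the reference cohort; unknown labels
  # fall back to the overall median.
  edss_center <- c(A = 3.75, B = 3.0, C = 2.5, D = 3.0)

  patients <- vector("list", n)
  truth <- vector("list", n)
  visits <- vector("list", n)

  for (i in seq_len(n)) {
    prof <- profile_of[[labels[i]]]
    age <- pmin(pmax(rnorm(1, config$age_mean, config$age_sd), 18), 80)
    sex <- if (runif(1) < 2 / 3) "F" else "M"
    dd <- pmin(pmax(rnorm(1, 12.9, 9), 0), 47)
    phenotype <- sample(c("RR", "SP", "PP", "transitional"), 1,
                        prob = c(0.69, 0.18, 0.05, 0.08))
    treated <- runif(1) < 0.649

    true_rate <- rnorm(6, prof$rate_mean, prof$rate_sd) +
      config$age_slope * (age - config$age_mean)
    v0 <- vapply(keys, function(k) {
      draw_positive(config$baseline_volume_mean[[k]],
                    config$baseline_volume_sd[[k]],
                    paste0("baseline ", k, " volume"))
    }, numeric(1))

    nv <- pmin(pmax(round(rnorm(1, prof$mean_followups, config$followup_sd)),
                    2), n_visits_max)
    t_years <- (seq_len(nv) - 1) * config$visit_spacing

    sigma <- sqrt(log(1 + config$noise_cv^2))
    vols <- outer(t_years, true_rate / 100, function(t, r) (1 + r)^t)
    vols <- sweep(vols, 2, v0, `*`)
    if (sigma > 0) {
      vols <- vols * exp(matrix(rnorm(length(vols), -sigma^2 / 2, sigma),
                                nrow = nv))
    }
    colnames(vols) <- volume_cols()

    ec <- if (labels[i] %in% names(edss_center)) {
      edss_center[[labels[i]]]
    } else 3.0
    edss0 <- rhalf(1, ec, 1.5, 0, 7.5)
    edss <- pmin(edss0 + cumsum(c(0, rbinom(nv - 1, 1, 0.12))) * 0.5, 10)
    t25 <- exp(rnorm(1, log(7), 0.45)) * (1.02^t_years) *
      exp(rnorm(nv, 0, 0.08))
    d9 <- exp(rnorm(1, log(22), 0.20)) * exp(rnorm(nv, 0, 0.05))
    nd9 <- exp(rnorm(1, log(23.5), 0.22)) * exp(rnorm(nv, 0, 0.05))
    snfl <- exp(rnorm(1, log(30), 0.5)) * exp(rnorm(nv, 0, 0.15))
    t2lv <- exp(rnorm(1, log(4000), 0.8)) * exp(rnorm(nv, 0, 0.1))
    gaps <- c(NA_real_, diff(t_years))
    relapses <- c(NA_integer_,
                  rpois(nv - 1, prof$relapse_rate * gaps[-1]))

    patients[[i]] <- tibble::tibble(
      patient_id = ids[i], baseline_age = age, sex = sex,
      disease_duration = dd, phenotype = phenotype, treated = treated
    )
    truth[[i]] <- tibble::tibble(
      patient_id = ids[i], group = labels[i],
      !!!setNames(as.list(true_rate), keys)
    )
    visits[[i]] <- tibble::tibble(
      patient_id = ids[i], t_years = t_years,
      !!!setNames(lapply(seq_along(keys), function(j) vols[, j]),
                  volume_cols()),
      edss = edss, t25fwt = t25, d9hpt = d9, nd9hpt = nd9,
      snfl = snfl, t2lv = t2lv,
      relapses_since_last_visit = relapses
    )
  }

  visits <- dplyr::bind_rows(visits)
  patients <- dplyr::bind_rows(patients)
  truth <- dplyr::bind_rows(truth)

  if (isTRUE(config$outlier_archetype)) {
    out <- make_outlier_patient(config)
    visits <- dplyr::bind_rows(visits, out$visits)
    patients <- dplyr::bind_rows(patients, out$patients)
    truth <- dplyr::bind_rows(truth, out$truth)
  }

  if (config$p_session_missing > 0) {
    visits <- apply_missingness(visits, config$p_session_missing)
  }

  structure(
    list(visits = visits, patients = patients, truth = truth,
         config = config),
    class = "ms_cohort"
  )
}

# One extreme patient whose true rates sit >= 4 SD below every profile.
make_outlier_patient <- function(config) {
  keys <- region_keys()
  floor_rate <- vapply(keys, function(k) {
    min(vapply(config$group_profiles, function(p) {
      p$rate_mean[[k]] - 4 * p$rate_sd[[k]]
    }, numeric(1)))
  }, numeric(1)) - 1
  id <- "P_OUTLIER"
  v0 <- config$baseline_volume_mean
  nv <- 4
  t_years <- (seq_len(nv) - 1) * config$visit_spacing
  vols <- sweep(outer(t_years, floor_rate / 100,
                      function(t, r) (1 + r)^t), 2, v0, `*`)
  colnames(vols) <- volume_cols()
  list(
    visits = tibble::tibble(
      patient_id = id, t_years = t_years,
      !!!setNames(lapply(seq_along(keys), function(j) vols[, j]),
                  volume_cols()),
      edss = 4, t25fwt = 8, d9hpt = 25, nd9hpt = 26, snfl = 60,
      t2lv = 8000,
      relapses_since_last_visit = c(NA_integer_, rep(0L, nv - 1))
    ),
    patients = tibble::tibble(
      patient_id = id, baseline_age = 21, sex = "M",
      disease_duration = 10, phenotype = "RR", treated = FALSE
    ),
    truth = tibble::tibble(
      patient_id = id, group = "OUTLIER_ARCHETYPE",
      !!!setNames(as.list(floor_rate), keys)
    )
  )
}

#' Remove non-baseline sessions at random
#'
#' Emulates session-level data loss (e.g. segmentation failures): every
#' non-baseline visit is removed independently with probability `p`; each
#' patient's baseline (earliest) visit is always kept. Patients left with
#' fewer than two visits stay in the table — filtering is the job of
#' [exclusion_filter()].
#'
#' @param visits Visit tibble (`patient_id`, `t_years`, ...).
#' @param p Removal probability in `[0, 1]`.
#' @param seed Optional seed; if `NULL` the current RNG stream is used.
#' @return The visit tibble with rows removed.
#' @export
apply_missingness <- function(visits, p, seed = NULL) {
  if (p < 0 || p > 1) abort("`p` must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  if (p == 0) return(visits)
  visits |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(.baseline = .data$t_years == min(.data$t_years)) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$.baseline | runif(dplyr::n()) >= p) |>
    dplyr::select(-".baseline")
}

#' @export
print.ms_cohort <- function(x, ...) {
  cat("<ms_cohort> ", nrow(x$patients), " patients, ",
      nrow(x$visits), " visits\n", sep = "")
  print(dplyr::count(x$truth, .data$group))
  invisible(x)
}
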