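#' Apply the cohort exclusion rules
#'
#' Removes MRI sessions that are incomplete (any of the six region volumes
#' missing) and then removes patients left with fewer than `min_visits`
#' complete sessions. Mirrors the study-entry rules of the reference
#' analysis: a session is unusable if any quantified CNS region failed, and
#' a rate needs at least two sessions.
#'
#' @param visits Visit tibble with `patient_id`, `t_years` and the six
#'   `<region>_vol` columns.
#' @param min_visits Minimum number of complete sessions per patient.
#' @return The filtered visit tibble, with an `exclusion_report` attribute
#'   (retrieve with [exclusion_report()]) counting dropped sessions and
#'   patients.
#' @export
exclusion_filter <- function(visits, min_visits = 2) {
  if (nrow(visits) == 0) abort("`visits` is empty")
  vc <- volume_cols()
  missing_cols <- setdiff(c("patient_id", "t_years", vc), names(visits))
  if (length(missing_cols) > 0) {
    abort(paste0("`visits` lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  complete <- !Reduce(`|`, lapply(visits[vc], is.na))
  kept <- visits[complete, , drop = FALSE]
  counts <- dplyr::count(kept, .data$patient_id)
  keep_ids <- counts$patient_id[counts$n >= min_visits]
  out <- kept[kept$patient_id %in% keep_ids, , drop = FALSE]
  dropped_patients <- setdiff(unique(visits$patient_id), keep_ids)
  if (nrow(out) == 0) {
    abort("no analyzable patients remain after exclusion")
  }
  attr(out, "exclusion_report") <- list(
    sessions_dropped = sum(!complete),
    patients_dropped = dropped_patients,
    n_patients_dropped = length(dropped_patients),
    n_patients_kept = length(keep_ids),
    n_sessions_kept = nrow(out)
  )
  out
}

#' Retrieve the exclusion report attached by [exclusion_filter()]
#' @param visits A visit tibble returned by [exclusion_filter()].
#' @return A list with counts of dropped sessions and patients.
#' @export
exclusion_report <- function(visits) {
  rep <- attr(visits, "exclusion_report")
  if (is.null(rep)) abort("no exclusion report attached; run exclusion_filter() first")
  rep
}

#' Per-patient mean annual percent volume change
#'
#' For every region and every consecutive pair of complete visits the
#' annualized percent change is
#' `100 * (V[i+1] - V[i]) / (V[i] * (t[i+1] - t[i]))`; a patient's rate is
#' the arithmetic mean of these pair rates (%/year). Under annual spacing
#' and a geometric trajectory `V0 * (1 + r/100)^t` this estimator returns
#' the true `r` exactly.
#'
#' @param visits Filtered visit tibble; every patient needs at least two
#'   complete visits (run [exclusion_filter()] first).
#' @return Tibble with `patient_id`, one rate column per region key, and
#'   `n_pairs` (number of consecutive pairs averaged).
#' @export
#' @examples
#' v <- tibble::tibble(
#'   patient_id = "P1", t_years = c(0, 2),
#'   sc_vol = c(100, 90), striatum_vol = 1, gp_vol = 1,
#'   thalamus_vol = 1, cgm_vol = 1, wm_vol = 1
#' )
#' annualized_rates(v) # sc = -5 %/year
annualized_rates <- function(visits) {
  vc <- volume_cols()
  keys <- region_keys()
  counts <- dplyr::count(visits, .data$patient_id)
  if (any(counts$n < 2)) {
    abort(paste0(
      "patient(s) with fewer than 2 visits: ",
      paste(counts$patient_id[counts$n < 2], collapse = ", "),
      "; run exclusion_filter() first"
    ))
  }
  visits |>
    dplyr::arrange(.data$patient_id, .data$t_years) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_modify(function(d, key) {
      dt <- diff(d$t_years)
      if (any(dt == 0)) {
        abort(paste0("duplicate timepoint for patient ", key$patient_id))
      }
      rates <- vapply(vc, function(col) {
        v <- d[[col]]
        mean(100 * diff(v) / (head(v, -1) * dt))
      }, numeric(1))
      tibble::tibble(!!!setNames(as.list(rates), keys),
                     n_pairs = length(dt))
    }) |>
    dplyr::ungroup()
}

#' Residualize atrophy rates on baseline age
#'
#' Per region, fits an ordinary least-squares regression of the rate on
#' baseline age and returns the residuals, removing the (linear) age effect
#' before pattern analysis. If age has zero variance the residuals are the
#' centered rates.
#'
#' @param rates Rate tibble from [annualized_rates()].
#' @param patients Patient tibble with `patient_id` and `baseline_age`.
#' @return Tibble with `patient_id` and one residual column per region;
#'   the per-region fitted intercept and slope are attached as a
#'   `residual_fits` attribute (retrieve with [residual_fits()]).
#' @export
age_residuals <- function(rates, patients) {
  if (nrow(rates) < 3) abort("need at least 3 patients to residualize on age")
  keys <- region_keys()
  d <- dplyr::left_join(rates, patients[, c("patient_id", "baseline_age")],
                        by = "patient_id")
  if (any(is.na(d$baseline_age))) {
    abort(paste0(
      "missing baseline_age for patient(s): ",
      paste(d$patient_id[is.na(d$baseline_age)], collapse = ", ")
    ))
  }
  age <- d$baseline_age
  degenerate <- var(age) == 0
  fits <- vector("list", length(keys))
  res <- d[, "patient_id"]
  for (j in seq_along(keys)) {
    y <- d[[keys[j]]]
    if (degenerate) {
      res[[keys[j]]] <- y - mean(y)
      fits[[j]] <- tibble::tibble(region = keys[j],
                                  intercept = mean(y), slope = 0)
    } else {
      fit <- lm(y ~ age)
      res[[keys[j]]] <- unname(stats::residuals(fit))
      fits[[j]] <- tibble::tibble(region = keys[j],
                                  intercept = unname(coef(fit)[1]),
                                  slope = unname(coef(fit)[2]))
    }
  }
  out <- tibble::as_tibble(res)
  attr(out, "residual_fits") <- dplyr::bind_rows(fits)
  out
}

#' Retrieve the per-region age-regression coefficients
#' @param residuals A residual tibble returned by [age_residuals()].
#' @return Tibble with `region`, `intercept`, `slope`.
#' @export
residual_fits <- function(residuals) {
  f <- attr(residuals, "residual_fits")
  if (is.null(f)) abort("no fits attached; run age_residuals() first")
  f
}
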