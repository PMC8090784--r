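#' Read a longitudinal cohort from CSV
#'
#' Reads the canonical long-format visit table (one row per MRI session)
#' and, optionally, the per-patient covariate table. Validates the schema,
#' volume positivity, and uniqueness/ordering of timepoints; row-level
#' problems are collected and reported together.
#'
#' @param visits_path Path to the visit CSV (`patient_id`, `t_years`, six
#'   `<region>_vol` columns, optional clinical columns).
#' @param patients_path Optional path to the covariate CSV (`patient_id`,
#'   `baseline_age`, ...).
#' @param mapping Optional named character vector renaming input columns
#'   to the canonical names, e.g. `c(sc_vol = "cord_volume")`.
#' @return A list with tibbles `visits` and (if given) `patients`.
#' @export
read_cohort_csv <- function(visits_path, patients_path = NULL,
                            mapping = NULL) {
  # base read.csv: its double parsing is correctly rounded, so values
  # written at full precision round-trip bit-exactly
  read_exact <- function(path) {
    tibble::as_tibble(utils::read.csv(path, na.strings = c("NA", ""),
                                      stringsAsFactors = FALSE))
  }
  visits <- read_exact(visits_path)
  if (!is.null(mapping)) {
    for (canonical in names(mapping)) {
      src <- mapping[[canonical]]
      if (!src %in% names(visits)) {
        abort(paste0("mapped column '", src, "' not found in ", visits_path))
      }
      names(visits)[names(visits) == src] <- canonical
    }
  }
  required <- c("patient_id", "t_years", volume_cols())
  missing_cols <- setdiff(required, names(visits))
  if (length(missing_cols) > 0) {
    abort(paste0("visit table lacks required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  visits$patient_id <- as.character(visits$patient_id)
  for (col in c("t_years", volume_cols())) {
    visits[[col]] <- as.double(visits[[col]])
  }

  problems <- character(0)
  for (vc in volume_cols()) {
    bad <- which(!is.na(visits[[vc]]) & visits[[vc]] <= 0)
    if (length(bad) > 0) {
      problems <- c(problems, paste0(
        "non-positive ", vc, " in row(s) ",
        paste(head(bad, 5), collapse = ", ")
      ))
    }
  }
  dup <- visits |>
    dplyr::count(.data$patient_id, .data$t_years) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    problems <- c(problems, paste0(
      "duplicated (patient_id, t_years): ",
      paste(paste0(dup$patient_id, "@", dup$t_years), collapse = ", ")
    ))
  }
  if (length(problems) > 0) {
    abort(paste0("cohort validation failed:\n  ",
                 paste(problems, collapse = "\n  ")))
  }
  visits <- dplyr::arrange(visits, .data$patient_id, .data$t_years)

  out <- list(visits = visits)
  if (!is.null(patients_path)) {
    patients <- read_exact(patients_path)
    if (!"patient_id" %in% names(patients)) {
      abort("patient table lacks `patient_id`")
    }
    patients$patient_id <- as.character(patients$patient_id)
    orphan <- setdiff(visits$patient_id, patients$patient_id)
    if (length(orphan) > 0) {
      abort(paste0("visit patient(s) missing from covariate table: ",
                   paste(head(orphan, 5), collapse = ", ")))
    }
    out$patients <- patients
  }
  out
}

#' Write a cohort (and truth labels) to CSV
#'
#' Doubles are serialized with 17 significant digits so that a
#' write-then-read round trip restores every finite value bit-exactly.
#'
#' @param cohort An `ms_cohort` from [generate_cohort()], or a list with
#'   `visits` / `patients` / optional `truth` tibbles.
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  full <- function(df) {
    dplyr::mutate(df, dplyr::across(
      dplyr::where(is.double),
      function(x) ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
    ))
  }
  readr::write_csv(full(cohort$visits), file.path(dir, "visits.csv"))
  if (!is.null(cohort$patients)) {
    readr::write_csv(full(cohort$patients), file.path(dir, "patients.csv"))
  }
  if (!is.null(cohort$truth)) {
    readr::write_csv(full(cohort$truth), file.path(dir, "truth.csv"))
  }
  invisible(dir)
}

#' Run the full stratification pipeline
#'
#' Executes, in order: session/patient exclusion, annualized rate
#' estimation, age residualization, uniform-weight PCA, component
#' retention, Ward clustering, the dendrogram cut (at `k`, or at the
#' max-gap `k` within `k_range`), singleton-outlier flagging, optional
#' stability validation, and the downstream group summaries. Fully
#' deterministic given `seed`.
#'
#' @param visits Visit tibble.
#' @param patients Patient covariate tibble (`patient_id`,
#'   `baseline_age`).
#' @param min_visits Minimum complete sessions per patient.
#' @param criteria A [retention_criteria()].
#' @param k Number of groups; if `NULL`, chosen by [choose_k()] over
#'   `k_range`.
#' @param k_range Candidate k values when `k` is `NULL`.
#' @param min_size Minimum cluster size before outlier flagging.
#' @param scheme [weight_scheme()] for the stability stage.
#' @param n_reps Stability repetitions; `0` skips the stability stage.
#' @param seed Seed for the stability resampling.
#' @param output_dir If non-`NULL`, all interface files (rates, residuals,
#'   PCA table, partition, Newick dendrogram, stability JSON, manifest)
#'   are written there.
#' @return An object of class `vlot_pipeline`: all intermediate results
#'   plus a run manifest.
#' @export
run_pipeline <- function(visits, patients, min_visits = 2,
                         criteria = retention_criteria(),
                         k = NULL, k_range = 2:8, min_size = 2,
                         scheme = weight_scheme(), n_reps = 0,
                         seed = 1, output_dir = NULL) {
  filtered <- exclusion_filter(visits, min_visits = min_visits)
  excl <- exclusion_report(filtered)
  rates <- annualized_rates(filtered)
  residuals <- age_residuals(rates, patients)
  pca <- weighted_pca(residuals)
  sel <- select_components(pca, criteria)
  scores <- pca$scores[, c("patient_id", paste0("PC", sel$retained))]
  tree <- ward_linkage(scores)
  k_used <- if (is.null(k)) choose_k(tree, k_range) else as.integer(k)
  partition <- flag_outliers(cut_dendrogram(tree, k_used), min_size)

  stability <- NULL
  if (n_reps > 0) {
    stability <- run_stability(residuals, partition,
                               k = k_effective(partition),
                               n_reps = n_reps, scheme = scheme,
                               criteria = criteria, min_size = min_size,
                               seed = seed)
  }

  comparisons <- within_group_structure_comparisons(rates, partition)
  summary_tbl <- group_summary(rates, partition)

  manifest <- list(
    n_patients_in = length(unique(visits$patient_id)),
    n_sessions_in = nrow(visits),
    sessions_dropped = excl$sessions_dropped,
    patients_dropped = excl$n_patients_dropped,
    dropped_patient_ids = excl$patients_dropped,
    n_patients_analyzed = nrow(rates),
    n_components_retained = sel$n_retained,
    k = k_used,
    k_effective = k_effective(partition),
    n_outliers = sum(partition$outlier),
    stability_skipped = n_reps == 0,
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )

  result <- structure(
    list(
      filtered_visits = filtered, exclusions = excl, rates = rates,
      residuals = residuals, pca = pca, selection = sel, tree = tree,
      partition = partition, stability = stability,
      comparisons = comparisons, group_summary = summary_tbl,
      manifest = manifest
    ),
    class = "vlot_pipeline"
  )
  if (!is.null(output_dir)) write_pipeline(result, output_dir)
  result
}

#' @export
print.vlot_pipeline <- function(x, ...) {
  m <- x$manifest
  cat("<vlot_pipeline> ", m$n_patients_analyzed, " patients analyzed (",
      m$patients_dropped, " excluded), ", m$n_components_retained,
      " components retained, k = ", m$k, " -> ", m$k_effective,
      " groups + ", m$n_outliers, " outlier(s)\n", sep = "")
  if (!is.null(x$stability)) print(x$stability)
  invisible(x)
}

# Table-shaped variable statistics: rows variable x statistic, columns
# PC1..PCm, preceded by eigenvalue / percent-variance rows.
pca_variable_table <- function(pca, retained = NULL) {
  if (is.null(retained)) retained <- seq_along(pca$eigenvalues)
  cols <- paste0("PC", retained)
  stats_long <- variable_stats(pca) |>
    dplyr::filter(.data$component %in% cols)
  wide <- stats_long |>
    tidyr::pivot_longer(c("coordinate", "cos2", "contribution"),
                        names_to = "statistic") |>
    tidyr::pivot_wider(names_from = "component", values_from = "value")
  header <- tibble::tibble(
    variable = ".spectrum",
    statistic = c("eigenvalue", "percent_variance"),
    !!!setNames(lapply(retained, function(k) {
      c(pca$eigenvalues[k], pca$percent_variance[k])
    }), cols)
  )
  dplyr::bind_rows(header, wide)
}

write_json_atomic <- function(x, path) {
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  file.rename(tmp, path)
}

#' Write every pipeline interface file
#'
#' @param result A `vlot_pipeline` object.
#' @param dir Output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_pipeline <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  keys <- region_keys()
  long <- function(x) {
    tidyr::pivot_longer(x, dplyr::all_of(keys), names_to = "region",
                        values_to = "value")
  }
  readr::write_csv(long(result$rates[, c("patient_id", keys)]),
                   file.path(dir, "rates_long.csv"))
  readr::write_csv(result$rates, file.path(dir, "rates_wide.csv"))
  readr::write_csv(long(result$residuals), file.path(dir, "residuals_long.csv"))
  readr::write_csv(result$residuals, file.path(dir, "residuals_wide.csv"))
  readr::write_csv(pca_variable_table(result$pca, result$selection$retained),
                   file.path(dir, "pca_table.csv"))
  readr::write_csv(result$partition, file.path(dir, "partition.csv"))
  readr::write_csv(tidy(result$tree), file.path(dir, "merges.csv"))
  readr::write_csv(result$comparisons, file.path(dir, "within_group_comparisons.csv"))
  readr::write_csv(result$group_summary, file.path(dir, "group_summary.csv"))
  if (requireNamespace("ape", quietly = TRUE)) {
    write_newick(result$tree, file.path(dir, "dendrogram.nwk"))
  }
  if (!is.null(result$stability)) {
    s <- result$stability
    write_json_atomic(
      list(ari_mean = s$summary$ari_mean, ari_sd = s$summary$ari_sd,
           vi_mean = s$summary$vi_mean, vi_sd = s$summary$vi_sd,
           n_reps = s$summary$n_reps, n_failed = s$summary$n_failed,
           seed = s$seed, k = s$k, log_base = s$log_base),
      file.path(dir, "stability.json")
    )
    readr::write_csv(s$reps, file.path(dir, "stability_reps.csv"))
  }
  write_json_atomic(result$manifest, file.path(dir, "manifest.json"))
  invisible(dir)
}
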