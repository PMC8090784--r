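#' Perturbation weight scheme for stability resampling
#'
#' Each stability repetition re-estimates the PCA after assigning a
#' near-zero contribution weight to a random fraction of patients and a
#' doubled weight to another disjoint random fraction, leaving the rest at
#' unit weight. The defaults mirror the published scheme: 10% at 0.0001,
#' 10% at 2, 80% at 1.
#'
#' @param frac_down,frac_up Fractions of patients down- and up-weighted
#'   (`frac_down + frac_up <= 1`).
#' @param w_down,w_up,w_base Strictly positive weights.
#' @return A `weight_scheme` list.
#' @export
weight_scheme <- function(frac_down = 0.10, w_down = 0.0001,
                          frac_up = 0.10, w_up = 2, w_base = 1) {
  if (frac_down < 0 || frac_up < 0 || frac_down + frac_up > 1) {
    abort("`frac_down` and `frac_up` must be >= 0 and sum to <= 1")
  }
  if (any(c(w_down, w_up, w_base) <= 0)) abort("weights must be > 0")
  structure(
    list(frac_down = frac_down, w_down = w_down,
         frac_up = frac_up, w_up = w_up, w_base = w_base),
    class = "weight_scheme"
  )
}

#' Draw one perturbation weight vector
#'
#' Two disjoint random subsets of sizes `round(frac_down * n)` and
#' `round(frac_up * n)` receive `w_down` and `w_up`; everyone else gets
#' `w_base`. Uses the current RNG stream.
#'
#' @param n Number of patients (>= 3).
#' @param scheme A [weight_scheme()].
#' @return Numeric weight vector of length `n`.
#' @export
sample_weights <- function(n, scheme = weight_scheme()) {
  if (n < 3) abort("`n` must be >= 3")
  n_down <- round(scheme$frac_down * n)
  n_up <- round(scheme$frac_up * n)
  if (n_down + n_up > n) abort("weight scheme fractions exhaust the cohort")
  w <- rep(scheme$w_base, n)
  idx <- sample.int(n, n_down + n_up)
  if (n_down > 0) w[idx[seq_len(n_down)]] <- scheme$w_down
  if (n_up > 0) w[idx[n_down + seq_len(n_up)]] <- scheme$w_up
  w
}

# Align two partitions: shared ids, outliers dropped from both.
# Accepts partition tibbles (patient_id, group, outlier) or plain label
# vectors of equal length.
align_partitions <- function(p, q) {
  if (is.data.frame(p) && is.data.frame(q)) {
    p2 <- p[!p$outlier & !is.na(p$group), c("patient_id", "group")]
    q2 <- q[!q$outlier & !is.na(q$group), c("patient_id", "group")]
    m <- dplyr::inner_join(p2, q2, by = "patient_id",
                           suffix = c("_p", "_q"))
    list(a = m$group_p, b = m$group_q)
  } else {
    a <- as.vector(p)
    b <- as.vector(q)
    if (length(a) != length(b)) {
      abort("label vectors must have equal length")
    }
    keep <- !is.na(a) & !is.na(b)
    list(a = a[keep], b = b[keep])
  }
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement,
#' `ARI = (S - E) / (M - E)` with `S = sum_ij C(n_ij, 2)`,
#' `E = sum_i C(a_i, 2) * sum_j C(b_j, 2) / C(n, 2)` and
#' `M = (sum_i C(a_i, 2) + sum_j C(b_j, 2)) / 2` from the contingency
#' table. 1 means identical partitions; values near 0 mean chance-level
#' agreement. Invariant to relabeling of either partition.
#'
#' @param p,q Partition tibbles (`patient_id`, `group`, `outlier`; outliers
#'   are dropped from both and ids aligned) or two equal-length label
#'   vectors.
#' @return The adjusted Rand index (a single number, at most 1).
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)) # -0.5
adjusted_rand_index <- function(p, q) {
  al <- align_partitions(p, q)
  n <- length(al$a)
  if (n < 2) abort("need at least 2 shared items to compare partitions")
  tab <- table(al$a, al$b)
  s <- sum(choose(tab, 2))
  ra <- sum(choose(rowSums(tab), 2))
  cb <- sum(choose(colSums(tab), 2))
  e <- ra * cb / choose(n, 2)
  m <- (ra + cb) / 2
  if (m == e) return(1) # both partitions trivial
  (s - e) / (m - e)
}

#' Variation of information between two partitions
#'
#' Meila's information-theoretic partition metric
#' `VI = H(P) + H(Q) - 2 I(P, Q)`, with entropies and mutual information
#' computed from empirical cluster proportions in the chosen logarithm
#' base. 0 means identical partitions; the maximum over partitions of `n`
#' items is `log_base(n)` (attained between the all-singletons and
#' one-cluster partitions). Base 10 is the default, matching the reference
#' analysis where the maximum for 225 patients is reported as 2.35 =
#' log10(225).
#'
#' @inheritParams adjusted_rand_index
#' @param log_base Logarithm base (default 10).
#' @return The VI distance (non-negative).
#' @export
#' @examples
#' variation_of_information(1:225, rep(1, 225)) # log10(225) = 2.352
variation_of_information <- function(p, q, log_base = 10) {
  al <- align_partitions(p, q)
  n <- length(al$a)
  if (n < 2) abort("need at least 2 shared items to compare partitions")
  tab <- table(al$a, al$b) / n
  pa <- rowSums(tab)
  pb <- colSums(tab)
  ent <- function(x) {
    x <- x[x > 0]
    -sum(x * log(x, base = log_base))
  }
  nz <- tab > 0
  mi <- sum(tab[nz] * log(tab[nz] /
                            (outer(pa, pb)[nz]), base = log_base))
  max(ent(pa) + ent(pb) - 2 * mi, 0)
}

#' Weighted-resampling stability validation of the clustering
#'
#' Repeats the full pattern analysis under randomly perturbed patient
#' weights: each repetition draws a weight vector from `scheme`, reruns the
#' weighted PCA, re-applies the component-retention rules, re-clusters with
#' Ward's criterion, cuts at the reference `k`, flags singleton outliers,
#' and scores agreement with the reference partition by adjusted Rand
#' index and variation of information (over the items non-outlier in
#' both). Per-repetition seeds are derived from `seed`, so any subset of
#' repetitions (`rep_range`) reproduces exactly the corresponding rows of
#' a full run.
#'
#' @param residuals Residual tibble from [age_residuals()].
#' @param reference Reference partition tibble (from the unweighted run).
#' @param k Number of clusters to cut at each repetition; defaults to the
#'   reference partition's effective group count.
#' @param n_reps Number of repetitions (the reference analysis used
#'   10,000).
#' @param scheme A [weight_scheme()].
#' @param criteria A [retention_criteria()].
#' @param min_size Minimum cluster size before outlier flagging.
#' @param seed Integer seed for the repetition substreams.
#' @param rep_range Optional integer vector of repetition indices to run
#'   (default `1:n_reps`).
#' @param log_base Logarithm base for VI.
#' @return An object of class `stability_result`: per-repetition tibble
#'   (`rep`, `ari`, `vi`, `n_retained`, `failed`) plus mean/SD summaries.
#' @export
run_stability <- function(residuals, reference, k = NULL, n_reps = 10000,
                          scheme = weight_scheme(),
                          criteria = retention_criteria(),
                          min_size = 2, seed = 1, rep_range = NULL,
                          log_base = 10) {
  if (is.null(k)) k <- k_effective(reference)
  if (is.null(rep_range)) rep_range <- seq_len(n_reps)
  rep_range <- as.integer(rep_range)
  stopifnot(all(rep_range >= 1))
  n <- nrow(residuals)

  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, max(rep_range))

  one_rep <- function(i) {
    set.seed(rep_seeds[i])
    w <- sample_weights(n, scheme)
    pca <- weighted_pca(residuals, row_weights = w)
    sel <- suppressWarnings(select_components(pca, criteria))
    scores <- pca$scores[, c("patient_id",
                             paste0("PC", sel$retained))]
    part <- ward_linkage(scores) |>
      cut_dendrogram(k) |>
      flag_outliers(min_size)
    tibble::tibble(
      rep = i,
      ari = adjusted_rand_index(reference, part),
      vi = variation_of_information(reference, part, log_base = log_base),
      n_retained = sel$n_retained,
      failed = FALSE
    )
  }

  reps <- purrr::map(rep_range, function(i) {
    tryCatch(one_rep(i), error = function(e) {
      tibble::tibble(rep = i, ari = NA_real_, vi = NA_real_,
                     n_retained = NA_integer_, failed = TRUE)
    })
  }) |> dplyr::bind_rows()

  n_failed <- sum(reps$failed)
  if (n_failed > 0.01 * length(rep_range)) {
    abort(paste0(n_failed, " of ", length(rep_range),
                 " repetitions failed (> 1%)"))
  }
  ok <- reps[!reps$failed, ]
  sd0 <- function(x) if (length(x) < 2) 0 else sd(x)
  structure(
    list(
      reps = reps,
      summary = tibble::tibble(
        ari_mean = mean(ok$ari), ari_sd = sd0(ok$ari),
        vi_mean = mean(ok$vi), vi_sd = sd0(ok$vi),
        n_reps = length(rep_range), n_failed = n_failed
      ),
      k = k, seed = seed, scheme = scheme, log_base = log_base
    ),
    class = "stability_result"
  )
}

#' @export
print.stability_result <- function(x, ...) {
  s <- x$summary
  cat("<stability_result> ", s$n_reps, " repetitions at k = ", x$k, "\n",
      sprintf("  ARI %.3f +/- %.3f ; VI %.3f +/- %.3f (base %g)\n",
              s$ari_mean, s$ari_sd, s$vi_mean, s$vi_sd, x$log_base),
      sep = "")
  if (s$n_failed > 0) cat("  failed repetitions:", s$n_failed, "\n")
  invisible(x)
}
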