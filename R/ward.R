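#' Ward hierarchical clustering of component scores
#'
#' Agglomerative clustering with Ward's minimum-variance criterion on
#' Euclidean distances (the Lance-Williams update on squared distances,
#' with merge heights stored as the square root of the updated squared
#' distance, so two singletons merge at their Euclidean distance). This is
#' the `"ward.D2"` dialect of [stats::hclust()], which genuinely minimizes
#' the within-cluster variance of the coordinates at each merge.
#'
#' @param scores Tibble with `patient_id` and numeric score columns (e.g.
#'   retained `PC` columns), or a numeric matrix with patient ids as row
#'   names.
#' @return An object of class `ward_tree` wrapping the `hclust` merge tree.
#' @export
ward_linkage <- function(scores) {
  if (is.data.frame(scores)) {
    num <- vapply(scores, is.numeric, logical(1))
    X <- as.matrix(scores[, num, drop = FALSE])
    rownames(X) <- as.character(scores$patient_id)
  } else {
    X <- as.matrix(scores)
    if (is.null(rownames(X))) rownames(X) <- seq_len(nrow(X))
  }
  if (nrow(X) < 2) abort("need at least 2 patients to cluster")
  if (any(!is.finite(X))) {
    bad <- rownames(X)[apply(!is.finite(X), 1, any)]
    abort(paste0("non-finite scores for patient(s): ",
                 paste(bad, collapse = ", ")))
  }
  hc <- hclust(dist(X), method = "ward.D2")
  hc$labels <- rownames(X)
  structure(list(hclust = hc, labels = rownames(X), n = nrow(X)),
            class = "ward_tree")
}

#' @export
print.ward_tree <- function(x, ...) {
  cat("<ward_tree> ", x$n, " patients, ", x$n - 1, " merges, max height ",
      signif(max(x$hclust$height), 4), "\n", sep = "")
  invisible(x)
}

#' @export
as.hclust.ward_tree <- function(x, ...) x$hclust

#' Cut the Ward tree into k groups
#'
#' Undoes the last `k - 1` merges and labels the resulting clusters in
#' decreasing size order (largest group = 1), breaking size ties by the
#' smallest patient id contained.
#'
#' @param tree A `ward_tree`.
#' @param k Number of groups (`1 <= k <= n`).
#' @return A partition tibble: `patient_id`, `group` (integer), `outlier`
#'   (logical, all `FALSE` here; see [flag_outliers()]).
#' @export
cut_dendrogram <- function(tree, k) {
  stopifnot(inherits(tree, "ward_tree"))
  if (k < 1 || k > tree$n) abort("`k` must be between 1 and n")
  raw <- cutree(tree$hclust, k = k)
  relabel_by_size(tibble::tibble(
    patient_id = tree$labels, group = as.integer(raw), outlier = FALSE
  ))
}

# Relabel non-outlier groups 1..k by decreasing size, ties by smallest id.
relabel_by_size <- function(partition) {
  d <- partition[!partition$outlier, ]
  info <- d |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(size = dplyr::n(),
                     min_id = min(as.character(.data$patient_id)),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$size), .data$min_id)
  map <- setNames(seq_len(nrow(info)), info$group)
  partition$group <- ifelse(
    partition$outlier, NA_integer_,
    map[as.character(partition$group)]
  )
  partition$group <- as.integer(partition$group)
  partition
}

#' Pick k from the largest merge-height gap
#'
#' Reproducible stand-in for the visual dendrogram cut: chooses the `k` in
#' `k_range` maximizing the gap between the merge heights crossed when
#' going from `k` to `k - 1` clusters; ties go to the smallest `k`. Always
#' overridable by passing an explicit `k` downstream.
#'
#' @param tree A `ward_tree`.
#' @param k_range Candidate values of k (within `2..n-1`).
#' @return The chosen integer k.
#' @export
choose_k <- function(tree, k_range = 2:10) {
  stopifnot(inherits(tree, "ward_tree"))
  n <- tree$n
  k_range <- sort(unique(as.integer(k_range)))
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (length(k_range) == 0) abort("`k_range` has no valid values")
  h <- tree$hclust$height # ascending
  gaps <- vapply(k_range, function(k) h[n - k + 1] - h[n - k], numeric(1))
  k_range[which.max(gaps)]
}

#' Flag undersized clusters as outliers
#'
#' Clusters smaller than `min_size` are marked as outliers (group `NA`),
#' emulating the exclusion of unclassifiable patients; remaining groups are
#' relabeled contiguously by decreasing size.
#'
#' @param partition Partition tibble from [cut_dendrogram()].
#' @param min_size Minimum cluster size to keep (default 2).
#' @return The updated partition tibble.
#' @export
flag_outliers <- function(partition, min_size = 2) {
  sizes <- partition[!partition$outlier, ] |>
    dplyr::count(.data$group)
  small <- sizes$group[sizes$n < min_size]
  if (length(small) == length(sizes$group)) {
    abort("all clusters are below `min_size`")
  }
  partition$outlier <- partition$outlier |
    (!is.na(partition$group) & partition$group %in% small)
  partition$group[partition$outlier] <- NA_integer_
  relabel_by_size(partition)
}

#' Number of non-outlier groups in a partition
#' @param partition Partition tibble.
#' @return Integer count of distinct non-outlier groups.
#' @export
k_effective <- function(partition) {
  length(unique(partition$group[!is.na(partition$group)]))
}

#' Export a Ward tree as Newick
#'
#' Branch lengths derive from the merge heights (ultrametric tree).
#'
#' @param tree A `ward_tree`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "ward_tree"))
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("package 'ape' is required for Newick export")
  }
  phy <- ape::as.phylo(tree$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}
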