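#' Tidy a weighted PCA
#'
#' Long table of per-variable, per-component statistics (coordinate, cos2,
#' contribution), as in a published PCA results table.
#'
#' @param x A `wpca` object.
#' @param ... Unused.
#' @return A tibble; see [variable_stats()].
#' @export
tidy.wpca <- function(x, ...) variable_stats(x)

#' One-row summary of a weighted PCA
#'
#' @param x A `wpca` object.
#' @param ... Unused.
#' @return Tibble with `n`, `p`, `total_variance` and the leading
#'   eigenvalue.
#' @export
glance.wpca <- function(x, ...) {
  tibble::tibble(
    n = x$n, p = length(x$eigenvalues),
    total_variance = sum(x$eigenvalues),
    lambda_1 = x$eigenvalues[1]
  )
}

#' Tidy a Ward merge tree
#'
#' One row per merge: the two merged nodes (negative = leaf index,
#' positive = earlier merge), the merge height, and the merged cluster
#' size.
#'
#' @param x A `ward_tree` object.
#' @param ... Unused.
#' @return Tibble with `step`, `node_a`, `node_b`, `height`, `size`.
#' @export
tidy.ward_tree <- function(x, ...) {
  hc <- x$hclust
  sizes <- numeric(nrow(hc$merge))
  node_size <- function(v) ifelse(v < 0, 1, sizes[v])
  for (i in seq_len(nrow(hc$merge))) {
    sizes[i] <- node_size(hc$merge[i, 1]) + node_size(hc$merge[i, 2])
  }
  tibble::tibble(
    step = seq_len(nrow(hc$merge)),
    node_a = hc$merge[, 1], node_b = hc$merge[, 2],
    height = hc$height, size = sizes
  )
}

#' Tidy a stability run
#'
#' @param x A `stability_result`.
#' @param ... Unused.
#' @return The per-repetition tibble (`rep`, `ari`, `vi`, `n_retained`,
#'   `failed`).
#' @export
tidy.stability_result <- function(x, ...) x$reps

#' One-row summary of a stability run
#'
#' @param x A `stability_result`.
#' @param ... Unused.
#' @return Tibble with ARI/VI means and SDs, repetition and failure
#'   counts, k and seed.
#' @export
glance.stability_result <- function(x, ...) {
  dplyr::mutate(x$summary, k = x$k, seed = x$seed)
}
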