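#' Scree plot with broken-stick overlay
#'
#' Bars show each component's variance share; points and line show the
#' broken-stick expectation for the same number of components.
#'
#' @param object A `wpca` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wpca <- function(object, ...) {
  p <- length(object$eigenvalues)
  d <- tibble::tibble(
    component = factor(seq_len(p)),
    share = object$percent_variance,
    stick = 100 * broken_stick(p)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$component)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$share), fill = "grey60") +
    ggplot2::geom_point(ggplot2::aes(y = .data$stick)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$stick, group = 1),
                       linetype = 2) +
    ggplot2::labs(x = "Principal component", y = "Variance share (%)",
                  title = "Scree plot (line: broken-stick expectation)")
}

# Segment coordinates for a dendrogram drawn from an hclust object.
dendro_segments <- function(hc) {
  n <- length(hc$order)
  leaf_x <- setNames(seq_len(n), hc$order)
  xs <- numeric(nrow(hc$merge))
  ys <- hc$height
  node_x <- function(v) if (v < 0) leaf_x[[as.character(-v)]] else xs[v]
  node_y <- function(v) if (v < 0) 0 else ys[v]
  segs <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    a <- hc$merge[i, 1]; b <- hc$merge[i, 2]
    xa <- node_x(a); xb <- node_x(b)
    xs[i] <- (xa + xb) / 2
    segs[[i]] <- tibble::tibble(
      x = c(xa, xa, xb), xend = c(xa, xb, xb),
      y = c(node_y(a), ys[i], ys[i]), yend = c(ys[i], ys[i], node_y(b))
    )
  }
  dplyr::bind_rows(segs)
}

#' Dendrogram plot of a Ward tree
#'
#' @param object A `ward_tree` object.
#' @param k Optional number of groups to mark with a cut line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ward_tree <- function(object, k = NULL, ...) {
  segs <- dendro_segments(object$hclust)
  g <- ggplot2::ggplot(segs) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$x, xend = .data$xend, y = .data$y, yend = .data$yend
    )) +
    ggplot2::labs(x = NULL, y = "Height",
                  title = "Ward dendrogram") +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank())
  if (!is.null(k)) {
    h <- object$hclust$height
    n <- object$n
    cut_h <- (h[n - k] + h[n - k + 1]) / 2
    g <- g + ggplot2::geom_hline(yintercept = cut_h, linetype = 2)
  }
  g
}

#' Histograms of per-repetition stability metrics
#'
#' @param object A `stability_result`.
#' @param ... Unused.
#' @return A ggplot object faceted by metric (ARI, VI).
#' @export
autoplot.stability_result <- function(object, ...) {
  d <- object$reps[!object$reps$failed, ] |>
    tidyr::pivot_longer(c("ari", "vi"), names_to = "metric")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = NULL, y = "Repetitions",
                  title = "Cluster-stability resampling")
}

#' Boxplots of rates by region and group
#'
#' @param rates Rate tibble.
#' @param partition Partition tibble.
#' @return A ggplot object.
#' @export
plot_rate_profiles <- function(rates, partition) {
  keys <- region_keys()
  d <- rates |>
    dplyr::inner_join(
      partition[!partition$outlier & !is.na(partition$group),
                c("patient_id", "group")],
      by = "patient_id"
    ) |>
    tidyr::pivot_longer(dplyr::all_of(keys), names_to = "region",
                        values_to = "rate") |>
    dplyr::mutate(region = factor(.data$region, levels = keys),
                  group = factor(.data$group))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$region, y = .data$rate,
                                  fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::labs(x = NULL, y = "Annual volume change (%/year)",
                  fill = "Group")
}
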