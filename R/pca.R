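#' Row-weighted principal component analysis of residual atrophy rates
#'
#' Covariance-metric (unstandardized) PCA with non-negative row weights,
#' computed by singular value decomposition of the weight-scaled centered
#' matrix. Weights are normalized to sum one; columns are centered at their
#' weighted means; the eigenvalues are those of the weighted covariance
#' matrix. Variable coordinates follow the convention
#' `c[j,k] = e[j,k] * sqrt(lambda[k])` with unit eigenvectors `e`, and each
#' eigenvector's sign is fixed so that its largest-magnitude loading is
#' positive.
#'
#' @param residuals Tibble with `patient_id` and the six region columns
#'   (typically from [age_residuals()]).
#' @param row_weights Optional non-negative weight per patient (default
#'   uniform). At least 3 rows must carry positive weight.
#' @return An object of class `wpca`: eigenvalues, percent variance,
#'   per-patient scores (`scores`, tibble with `PC1..PC6`), variable
#'   coordinates, squared cosines (`cos2`, quality of variable
#'   representation), contributions (%), normalized row weights, weighted
#'   column means, and the rotation matrix.
#' @export
weighted_pca <- function(residuals, row_weights = NULL) {
  X <- rate_matrix(residuals)
  n <- nrow(X)
  p <- ncol(X)
  if (is.null(row_weights)) row_weights <- rep(1, n)
  if (length(row_weights) != n) {
    abort("`row_weights` must have one entry per patient")
  }
  if (any(row_weights < 0)) abort("`row_weights` must be non-negative")
  if (sum(row_weights) <= 0) abort("`row_weights` must not all be zero")
  if (sum(row_weights > 0) < 3) {
    abort("need at least 3 patients with positive weight")
  }
  if (any(!is.finite(X))) {
    bad <- rownames(X)[apply(!is.finite(X), 1, any)]
    abort(paste0("non-finite residuals for patient(s): ",
                 paste(bad, collapse = ", ")))
  }

  w <- row_weights / sum(row_weights)
  center <- colSums(w * X)
  Xc <- sweep(X, 2, center)
  sv <- svd(sqrt(w) * Xc, nu = 0, nv = p)
  lambda <- c(sv$d^2, rep(0, p - length(sv$d)))[seq_len(p)]
  V <- sv$v

  # sign convention: largest-|loading| entry of each eigenvector positive
  for (k in seq_len(p)) {
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) V[, k] <- -V[, k]
  }
  dimnames(V) <- list(region_keys(), paste0("PC", seq_len(p)))

  scores_mat <- Xc %*% V
  coord <- V %*% diag(sqrt(lambda), p)
  dimnames(coord) <- dimnames(V)

  var_tot <- rowSums(coord^2) # per-variable weighted variance
  cos2 <- coord^2 / ifelse(var_tot > 0, var_tot, NA_real_)
  if (any(var_tot == 0)) {
    warn(paste0("zero-variance variable(s): ",
                paste(names(var_tot)[var_tot == 0], collapse = ", "),
                "; cos2 reported as NA"))
  }
  csum <- colSums(coord^2)
  contrib <- 100 * sweep(coord^2, 2, ifelse(csum > 0, csum, NA_real_), `/`)

  structure(
    list(
      eigenvalues = unname(lambda),
      percent_variance = unname(100 * lambda / sum(lambda)),
      scores = tibble::tibble(
        patient_id = rownames(X),
        !!!setNames(lapply(seq_len(p), function(k) unname(scores_mat[, k])),
                    colnames(V))
      ),
      var_coord = coord, cos2 = cos2, contrib = contrib,
      rotation = V, center = center, row_weights = w,
      n = n
    ),
    class = "wpca"
  )
}

#' @export
print.wpca <- function(x, ...) {
  cat("<wpca> ", x$n, " patients, 6 variables\n", sep = "")
  cat("eigenvalues:", format(round(x$eigenvalues, 3)), "\n")
  cat("% variance :", format(round(x$percent_variance, 1)), "\n")
  invisible(x)
}

#' Variable-level PCA statistics (coordinate, cos2, contribution)
#'
#' Computes, per variable and component, the coordinate, the squared cosine
#' (quality of variable representation: the share of the variable's total
#' squared coordinate captured by the component) and the contribution (the
#' percent share of the component's squared coordinates due to the
#' variable):
#' `cos2[j,k] = c[j,k]^2 / sum_k c[j,k]^2`,
#' `ctr[j,k] = 100 * c[j,k]^2 / sum_j c[j,k]^2`.
#'
#' @param x A `wpca` object, or a numeric matrix of variable coordinates
#'   (variables in rows, components in columns) from which the ratio
#'   formulas are evaluated directly.
#' @return A tibble with `variable`, `component`, `coordinate`, `cos2`,
#'   `contribution`.
#' @export
#' @examples
#' # recomputing published variable statistics from printed coordinates
#' coords <- rbind(sc = c(0.95, -0.16, -0.76, -0.48))
#' variable_stats(coords)
variable_stats <- function(x) {
  if (inherits(x, "wpca")) {
    coord <- x$var_coord
  } else if (is.matrix(x) && is.numeric(x)) {
    coord <- x
    if (is.null(rownames(coord))) {
      rownames(coord) <- paste0("var", seq_len(nrow(coord)))
    }
    if (is.null(colnames(coord))) {
      colnames(coord) <- paste0("PC", seq_len(ncol(coord)))
    }
  } else {
    abort("`x` must be a wpca object or a numeric coordinate matrix")
  }
  rtot <- rowSums(coord^2)
  ctot <- colSums(coord^2)
  cos2 <- coord^2 / ifelse(rtot > 0, rtot, NA_real_)
  contrib <- 100 * sweep(coord^2, 2, ifelse(ctot > 0, ctot, NA_real_), `/`)
  tibble::tibble(
    variable = rep(rownames(coord), times = ncol(coord)),
    component = rep(colnames(coord), each = nrow(coord)),
    coordinate = as.vector(coord),
    cos2 = as.vector(cos2),
    contribution = as.vector(contrib)
  )
}

#' Broken-stick expected variance shares
#'
#' Expected ordered segment lengths of a unit stick broken at `p - 1`
#' uniform points: `b[k] = (1/p) * sum_{i=k..p} 1/i`. A component is
#' noteworthy under the broken-stick rule when its variance share exceeds
#' `b[k]`.
#'
#' @param p Number of components (>= 1).
#' @return Decreasing numeric vector of length `p` summing to 1.
#' @export
#' @examples
#' broken_stick(2) # 0.75 0.25
broken_stick <- function(p) {
  if (p < 1) abort("`p` must be >= 1")
  p <- as.integer(p)
  rev(cumsum(1 / (p:1))) / p
}

#' Scree-plot elbow by maximum second difference
#'
#' Diagnostic elbow locator: returns the interior index `k` maximizing the
#' discrete curvature `lambda[k-1] - 2*lambda[k] + lambda[k+1]`; ties go to
#' the smallest `k`.
#'
#' @param eigenvalues Numeric vector of at least 3 eigenvalues.
#' @return Integer elbow index.
#' @export
scree_elbow <- function(eigenvalues) {
  if (length(eigenvalues) < 3) abort("need at least 3 eigenvalues")
  ks <- 2:(length(eigenvalues) - 1)
  d2 <- eigenvalues[ks - 1] - 2 * eigenvalues[ks] + eigenvalues[ks + 1]
  ks[which.max(d2)]
}

#' Component retention criteria
#'
#' @param cum_var_min Minimum cumulative variance fraction retained
#'   (default 0.90).
#' @param eigen_min Eigenvalue floor for the last retained component
#'   (default 0.7, applied to covariance eigenvalues as printed in the
#'   reference analysis).
#' @param broken_stick_diagnostic,elbow_diagnostic Whether to attach the
#'   broken-stick and scree-elbow diagnostics (never hard filters).
#' @return A `retention_criteria` list.
#' @export
retention_criteria <- function(cum_var_min = 0.90, eigen_min = 0.7,
                               broken_stick_diagnostic = TRUE,
                               elbow_diagnostic = TRUE) {
  if (cum_var_min <= 0 || cum_var_min > 1) {
    abort("`cum_var_min` must be in (0, 1]")
  }
  if (eigen_min < 0) abort("`eigen_min` must be >= 0")
  structure(
    list(cum_var_min = cum_var_min, eigen_min = eigen_min,
         broken_stick_diagnostic = broken_stick_diagnostic,
         elbow_diagnostic = elbow_diagnostic),
    class = "retention_criteria"
  )
}

#' Select principal components for clustering
#'
#' Retains the smallest leading set of components whose cumulative variance
#' share reaches `cum_var_min` and whose last member's eigenvalue exceeds
#' `eigen_min`. If no component count satisfies both rules, retention falls
#' back to the cumulative-variance rule alone with a warning. The
#' broken-stick and scree-elbow results are attached as diagnostics only.
#'
#' @param x A `wpca` object or a numeric vector of eigenvalues.
#' @param criteria A [retention_criteria()] object.
#' @return A list of class `component_selection`: `retained` (integer
#'   indices), `n_retained`, and `diagnostics` (cumulative variance,
#'   broken-stick comparison, elbow index).
#' @export
select_components <- function(x, criteria = retention_criteria()) {
  lambda <- if (inherits(x, "wpca")) x$eigenvalues else as.numeric(x)
  if (any(lambda < 0)) abort("eigenvalues must be non-negative")
  p <- length(lambda)
  pv <- lambda / sum(lambda)
  cum <- cumsum(pv)
  m <- which(cum >= criteria$cum_var_min - 1e-12)[1]
  eigen_ok <- lambda[m] > criteria$eigen_min
  if (!eigen_ok) {
    warn(paste0(
      "cumulative-variance rule retains ", m,
      " components but eigenvalue ", signif(lambda[m], 3),
      " does not exceed eigen_min = ", criteria$eigen_min,
      "; retaining by cumulative variance alone"
    ))
  }
  diagnostics <- list(cumulative_variance = cum)
  if (isTRUE(criteria$broken_stick_diagnostic)) {
    bs <- broken_stick(p)
    diagnostics$broken_stick <- tibble::tibble(
      component = seq_len(p), variance_share = pv,
      broken_stick = bs, exceeds = pv > bs
    )
  }
  if (isTRUE(criteria$elbow_diagnostic) && p >= 3) {
    diagnostics$elbow <- scree_elbow(lambda)
  }
  structure(
    list(retained = seq_len(m), n_retained = m,
         eigen_rule_satisfied = eigen_ok, diagnostics = diagnostics),
    class = "component_selection"
  )
}

#' @export
print.component_selection <- function(x, ...) {
  cat("<component_selection> retained ", x$n_retained, " components (",
      round(100 * x$diagnostics$cumulative_variance[x$n_retained], 1),
      "% of variance)\n", sep = "")
  invisible(x)
}
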