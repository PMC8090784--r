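# Weighted covariance of a centered matrix, independent of weighted_pca.
wcov_oracle <- function(X, w) {
  w <- w / sum(w)
  mu <- colSums(w * X)
  Xc <- sweep(X, 2, mu)
  t(Xc) %*% (w * Xc)
}

fake_residuals <- function(n, seed = 1, p_effective = 6) {
  set.seed(seed)
  base <- matrix(rnorm(n * p_effective), n)
  X <- base %*% matrix(rnorm(p_effective * 6), p_effective)
  tibble::tibble(patient_id = sprintf("P%02d", seq_len(n)),
                 !!!setNames(lapply(1:6, function(j) X[, j]),
                             names(cns_regions())))
}

test_that("uniform weights reproduce plain covariance PCA", {
  res <- fake_residuals(40, seed = 5)
  pca <- weighted_pca(res)
  X <- as.matrix(res[names(cns_regions())])
  ev <- eigen(wcov_oracle(X, rep(1, 40)), symmetric = TRUE)
  expect_equal(pca$eigenvalues, ev$values, tolerance = 1e-9)
  expect_equal(abs(pca$rotation), abs(ev$vectors), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(sum(pca$percent_variance), 100, tolerance = 1e-9)
})

test_that("collinear data yield a single nonzero eigenvalue", {
  dir <- c(1, 2, -1, 0.5, 3, -2)
  s <- seq(-2, 2, length.out = 9)
  res <- tibble::tibble(patient_id = paste0("P", 1:9),
                        !!!setNames(lapply(1:6, function(j) s * dir[j]),
                                    names(cns_regions())))
  pca <- weighted_pca(res)
  X <- as.matrix(res[names(cns_regions())])
  expect_equal(pca$eigenvalues[1], sum(diag(wcov_oracle(X, rep(1, 9)))),
               tolerance = 1e-9)
  expect_equal(pca$eigenvalues[-1], rep(0, 5), tolerance = 1e-9)
})

test_that("zero-weight rows are ignored exactly", {
  res <- fake_residuals(30, seed = 8)
  w <- rep(1, 30); w[c(3, 11, 25)] <- 0
  full <- weighted_pca(res, row_weights = w)
  sub <- weighted_pca(res[w > 0, ])
  expect_equal(full$eigenvalues, sub$eigenvalues, tolerance = 1e-9)
  expect_equal(full$var_coord, sub$var_coord, tolerance = 1e-8)
})

test_that("spectral reconstruction and score orthogonality hold", {
  res <- fake_residuals(50, seed = 13)
  set.seed(14)
  w <- runif(50, 0.5, 2)
  pca <- weighted_pca(res, row_weights = w)
  X <- as.matrix(res[names(cns_regions())])
  C <- wcov_oracle(X, w)
  recon <- pca$rotation %*% diag(pca$eigenvalues) %*% t(pca$rotation)
  expect_lt(norm(recon - C, "F") / norm(C, "F"), 1e-9)
  expect_equal(sum(pca$eigenvalues), sum(diag(C)), tolerance = 1e-9)

  S <- as.matrix(pca$scores[paste0("PC", 1:6)])
  wn <- w / sum(w)
  cs <- t(S) %*% (wn * sweep(S, 2, colSums(wn * S)))
  offdiag <- cs - diag(diag(cs))
  expect_lt(max(abs(offdiag)), 1e-9 * pca$eigenvalues[1])
})

test_that("eigenvalues are invariant to orthogonal rotation of the data", {
  res <- fake_residuals(35, seed = 20)
  X <- as.matrix(res[names(cns_regions())])
  set.seed(21)
  Q <- qr.Q(qr(matrix(rnorm(36), 6)))
  res_rot <- res
  res_rot[names(cns_regions())] <- as.data.frame(X %*% Q)
  expect_equal(weighted_pca(res)$eigenvalues,
               weighted_pca(res_rot)$eigenvalues, tolerance = 1e-8)
})

test_that("degenerate weight vectors are rejected", {
  res <- fake_residuals(10)
  expect_error(weighted_pca(res, row_weights = rep(0, 10)), "zero")
  expect_error(weighted_pca(res, row_weights = c(1, 1, rep(0, 8))),
               "at least 3")
  expect_error(weighted_pca(res, row_weights = rep(1, 9)), "one entry")
})

test_that("variable statistics follow the ratio formulas", {
  res <- fake_residuals(25, seed = 30)
  pca <- weighted_pca(res)
  vs <- variable_stats(pca)
  # contributions sum to 100 per component, cos2 to 1 per variable
  by_comp <- tapply(vs$contribution, vs$component, sum)
  expect_equal(as.vector(by_comp), rep(100, 6), tolerance = 1e-9)
  by_var <- tapply(vs$cos2, vs$variable, sum)
  expect_equal(as.vector(by_var), rep(1, 6), tolerance = 1e-9)
  # tidy() is the same table
  expect_equal(tidy(pca), vs)
})

test_that("published coordinates reproduce the published QoVR and contribution", {
  sc <- matrix(c(0.95, -0.16, -0.76, -0.48), nrow = 1,
               dimnames = list("sc", paste0("PC", 1:4)))
  vs <- variable_stats(sc)
  expect_equal(round(vs$cos2[vs$component == "PC1"], 2), 0.52)

  pc1 <- matrix(c(0.95, 0.43, 0.53, 0.80, 1.02, 0.14), ncol = 1,
                dimnames = list(names(cns_regions()), "PC1"))
  vs1 <- variable_stats(pc1)
  expect_equal(round(vs1$contribution[vs1$variable == "thalamus"], 1),
               20.9)
})

test_that("broken stick matches its closed form", {
  expect_equal(broken_stick(1), 1)
  expect_equal(broken_stick(2), c(0.75, 0.25))
  b6 <- broken_stick(6)
  expect_equal(b6[1], sum(1 / (1:6)) / 6, tolerance = 1e-12)
  expect_equal(sum(b6), 1, tolerance = 1e-12)
  expect_true(all(diff(b6) < 0))
  expect_error(broken_stick(0), ">= 1")
})

test_that("scree elbow maximizes the second difference", {
  expect_equal(scree_elbow(c(10, 1, 0.9, 0.8)), 2)
  expect_equal(scree_elbow(c(4, 3, 2, 1)), 2) # ties -> smallest k
  expect_equal(scree_elbow(c(5, 4, 1, 0.9, 0.8)), 3)
  expect_error(scree_elbow(c(2, 1)), "at least 3")
})

test_that("component retention follows the cumulative-variance + eigenvalue rule", {
  # published spectrum: four components, 92% cumulative
  lambda <- c(2.69, 1.81, 1.09, 0.77, 0.346, 0.208)
  sel <- select_components(lambda)
  expect_equal(sel$n_retained, 4)
  expect_true(sel$eigen_rule_satisfied)

  expect_equal(select_components(5)$n_retained, 1)

  # cumulative variance reached only where the eigenvalue floor fails
  expect_warning(
    sel2 <- select_components(c(5, 2, 1.6, 0.5, 0.5, 0.4)),
    "cumulative variance alone"
  )
  expect_equal(sel2$n_retained, 4)
  expect_false(sel2$eigen_rule_satisfied)
})

test_that("broken-stick and elbow are attached as diagnostics only", {
  lambda <- c(2.69, 1.81, 1.09, 0.77, 0.346, 0.208)
  sel <- select_components(lambda)
  bs <- sel$diagnostics$broken_stick
  # the first component's share (38.9%) is below the p=6 stick (~40.8%),
  # yet retention is unaffected
  expect_false(bs$exceeds[1])
  expect_equal(sel$n_retained, 4)
  expect_equal(sel$diagnostics$elbow, scree_elbow(lambda))
})
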