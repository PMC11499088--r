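test_that("compactness is the cumulative eigenvalue fraction", {
  model <- list(eigenvalues = c(0.6, 0.3, 0.1))
  class(model) <- "shape_model"
  expect_equal(compactness(model, 2), 0.9)
  expect_equal(compactness(model, 3), 1.0)
  expect_equal(compactness(model, 2, normalized = FALSE), 0.9)
  expect_error(compactness(model, 0), class = "morphodetail_invalid_spec")

  # brute-force cumulative-variance oracle on random cohorts
  for (seed in 1:3) {
    X <- random_corr_matrix(8, 10, seed = seed)
    m <- fit_pca(X)
    lam <- eigen(stats::cov(X), symmetric = TRUE)$values[1:7]
    for (k in 1:7) {
      expect_lt(abs(compactness(m, k, normalized = FALSE) - sum(lam[1:k])), 1e-10)
      expect_lt(abs(compactness(m, k) - sum(lam[1:k]) / sum(lam)), 1e-12)
    }
  }
  # telescoping: increments are the normalised eigenvalues
  X <- random_corr_matrix(8, 10, seed = 4)
  m <- fit_pca(X)
  inc <- diff(vapply(1:7, function(k) compactness(m, k), numeric(1)))
  expect_equal(inc, (m$eigenvalues / sum(m$eigenvalues))[2:7], tolerance = 1e-12)
  expect_true(all(inc >= 0))
})

test_that("generalisation matches a refit-from-scratch leave-one-out loop", {
  # identical shapes reconstruct exactly
  X0 <- matrix(rep(stats::rnorm(12), each = 5), 5, 12)
  expect_equal(generalisation(X0, 1), 0, tolerance = 1e-10)

  # shapes in an exact 2-mode affine family: zero error at n_m = 2
  set.seed(8)
  basis <- matrix(stats::rnorm(2 * 18), 2, 18)
  coef <- matrix(stats::rnorm(12), 6, 2)
  Xplane <- coef %*% basis + matrix(rep(stats::rnorm(18), each = 6), 6, 18)
  expect_lt(generalisation(Xplane, 2), 1e-9)

  # naive reimplementation oracle on a random 6-shape cohort
  X <- random_corr_matrix(6, 7, seed = 11)
  K <- 7
  for (n_m in c(1, 2, 4)) {
    oracle <- mean(vapply(1:6, function(j) {
      Xt <- X[-j, , drop = FALSE]
      mu <- colMeans(Xt)
      ev <- eigen(stats::cov(Xt), symmetric = TRUE)$vectors[, 1:n_m, drop = FALSE]
      rec <- mu + ev %*% crossprod(ev, X[j, ] - mu)
      d <- matrix(X[j, ] - rec, nrow = 3)
      mean(sqrt(colSums(d^2)))
    }, numeric(1)))
    expect_lt(abs(generalisation(X, n_m) - oracle), 1e-10)
  }
  expect_error(generalisation(X, 5), class = "morphodetail_invalid_spec")
})

test_that("specificity behaves as a Monte-Carlo nearest-training distance", {
  X0 <- matrix(rep(stats::rnorm(12), each = 5), 5, 12) +
    matrix(stats::rnorm(60, sd = 1e-9), 5, 12)
  m0 <- fit_pca(X0)
  expect_lt(specificity(m0, X0, 1, M = 50, seed = 1), 1e-6)

  X <- random_corr_matrix(8, 6, seed = 2)
  model <- fit_pca(X)
  # zero-variance draw equals the mean-to-nearest-training distance
  V <- model$eigenvectors[, 1, drop = FALSE]
  d_mean <- min(vapply(1:8, function(i) {
    d <- matrix(model$mean - X[i, ], nrow = 3)
    mean(sqrt(colSums(d^2)))
  }, numeric(1)))
  s1 <- specificity(model, X, 1, M = 1, seed = 999)
  z <- morphodetail:::with_seed(999, stats::rnorm(1))
  d_draw <- min(vapply(1:8, function(i) {
    y <- model$mean + z * sqrt(model$eigenvalues[1]) * as.numeric(V)
    d <- matrix(y - X[i, ], nrow = 3)
    mean(sqrt(colSums(d^2)))
  }, numeric(1)))
  expect_equal(s1, d_draw, tolerance = 1e-12)
  expect_gt(d_mean, 0)

  # two Monte-Carlo estimates at M = 2000 agree within 3 standard errors
  a <- specificity(model, X, 3, M = 2000, seed = 1)
  b <- specificity(model, X, 3, M = 2000, seed = 2)
  per_draw <- vapply(1:200, function(i)
    specificity(model, X, 3, M = 1, seed = 3000 + i), numeric(1))
  se <- stats::sd(per_draw) / sqrt(2000)
  expect_lt(abs(a - b), 3 * sqrt(2) * se + 1e-9)
})

test_that("specificity is invariant under a common rigid motion", {
  X <- random_corr_matrix(7, 5, seed = 6)
  model <- fit_pca(X)
  s0 <- specificity(model, X, 3, M = 200, seed = 4)
  R <- random_rotation(5)
  Rb <- kronecker(diag(5), R)
  Xr <- X %*% t(Rb)
  mr <- fit_pca(Xr)
  sr <- specificity(mr, Xr, 3, M = 200, seed = 4)
  expect_lt(abs(sr - s0), 1e-9)
})

test_that("evaluation curves difference against the reference level", {
  X1 <- random_corr_matrix(8, 6, seed = 21)
  out <- evaluation_suite(list(R1 = X1, R4 = X1), n_m_max = 4, M = 50, seed = 2)
  # a level differenced with itself gives all-zero difference curves
  d4 <- subset(out$diff, level == "R4")
  expect_equal(d4$d_compactness_norm, rep(0, 4), tolerance = 1e-12)
  expect_equal(d4$d_generalisation_mm, rep(0, 4), tolerance = 1e-12)
  expect_equal(d4$d_specificity_mm, rep(0, 4), tolerance = 1e-12)

  # generalisation decreases from 1 mode to the maximum, per cohort
  cur <- out$curves$R1
  expect_lte(cur$generalisation_mm[4], cur$generalisation_mm[1])

  # curves serialise losslessly
  f <- tempfile(fileext = ".csv")
  utils::write.csv(cur, f, row.names = FALSE)
  expect_equal(utils::read.csv(f), cur, tolerance = 1e-12)

  expect_error(evaluation_suite(list(R4 = X1)), class = "morphodetail_invalid_spec")
})
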