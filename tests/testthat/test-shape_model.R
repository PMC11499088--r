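test_that("identical shapes receive identical particle sets", {
  mesh <- quick_anatomy(3, detail = 0.3)
  meshes <- list(mesh, mesh, mesh)
  corr <- establish_correspondence(meshes, K = 64L, K_init = 32L, seed = 2)
  expect_equal(corr$K, 64L)
  for (i in 2:3)
    expect_lt(max(abs(corr$points[[i]] - corr$points[[1]])), 1e-6)
  # particles lie on the surface
  for (i in 1:3)
    expect_lt(max(closest_points(meshes[[i]], corr$points[[i]])$dist), 0.25)
})

test_that("a rigidly moved copy registered back shares its particles", {
  mesh <- quick_anatomy(6, detail = 0.3)
  g <- rigid_transform(random_rotation(4, max_angle = 0.3), c(3, -1, 2))
  moved <- transform_mesh(mesh, g$rotation, g$translation)
  back <- transform_mesh(moved, t(g$rotation),
                         as.numeric(-t(g$rotation) %*% g$translation))
  corr <- establish_correspondence(list(mesh, back), K = 64L, K_init = 32L,
                                   seed = 2)
  expect_lt(max(abs(corr$points[[1]] - corr$points[[2]])), 0.25)
})

test_that("particle coverage tightens when K doubles", {
  mesh <- quick_anatomy(9, detail = 0.2)
  probe <- sample_surface(mesh, 1500, seed = 11)$points
  cover <- vapply(c(32L, 64L, 128L), function(K) {
    corr <- establish_correspondence(list(mesh), K = K, K_init = K %/% 2L,
                                     seed = 5)
    nn <- morphodetail:::cpp_nn_points(probe, corr$points[[1]], 2, FALSE)
    max(nn$dist)
  }, numeric(1))
  expect_true(all(diff(cover) < 0))
  expect_error(establish_correspondence(list(mesh), K = 96L, K_init = 32L),
               class = "morphodetail_invalid_spec")
})

test_that("PCA matches the analytic two-shape case and a dense oracle", {
  # two shapes: one mode, mean at the midpoint, lambda = |x1 - x2|^2 / 2
  set.seed(1)
  x1 <- stats::rnorm(30)
  x2 <- stats::rnorm(30)
  model <- fit_pca(rbind(x1, x2))
  expect_equal(length(model$eigenvalues), 1L)
  expect_equal(model$mean, (x1 + x2) / 2, ignore_attr = TRUE)
  expect_equal(model$eigenvalues[1], sum((x1 - x2)^2) / 2, tolerance = 1e-12)

  # random 10-shape cohort: spectrum matches a dense covariance eigensolver
  X <- random_corr_matrix(10, 20, seed = 3)
  model10 <- fit_pca(X)
  oracle <- eigen(stats::cov(X), symmetric = TRUE)$values[1:9]
  expect_equal(model10$eigenvalues, oracle, tolerance = 1e-8)

  # orthonormal modes, zero-mean scores, variance conservation
  G <- crossprod(model10$eigenvectors)
  expect_equal(G, diag(ncol(G)), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(colMeans(model10$scores), rep(0, 9), tolerance = 1e-9)
  Xc <- sweep(X, 2, colMeans(X))
  expect_equal(sum(model10$eigenvalues), sum(Xc^2) / 9, tolerance = 1e-9)

  # full-mode reconstruction is exact
  for (j in c(1, 5, 10)) {
    rec <- reconstruct_shape(model10, X[j, ], n_m = 9)
    expect_lt(sqrt(sum((rec - X[j, ])^2)), 1e-8)
  }
})

test_that("PCA is equivariant under common translation", {
  X <- random_corr_matrix(8, 12, seed = 9)
  t3 <- rep(c(1.5, -2, 0.5), 12)
  m1 <- fit_pca(X)
  m2 <- fit_pca(sweep(X, 2, -t3))
  expect_equal(m2$mean, m1$mean + t3, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(m2$eigenvalues, m1$eigenvalues, tolerance = 1e-9)
})

test_that("reconstruction error is non-increasing in the mode count", {
  X <- random_corr_matrix(12, 15, seed = 5)
  model <- fit_pca(X)
  probe <- X[3, ] + stats::rnorm(45, sd = 0.2)
  errs <- vapply(1:11, function(m)
    sqrt(sum((reconstruct_shape(model, probe, m) - probe)^2)), numeric(1))
  expect_true(all(diff(errs) <= 1e-10))
  expect_error(reconstruct_shape(model, probe, 0), class = "morphodetail_invalid_spec")
  expect_error(reconstruct_shape(model, probe, 12), class = "morphodetail_invalid_spec")
})

test_that("model sampling is seeded and reproduces the spectrum", {
  X <- random_corr_matrix(6, 4, seed = 7)
  model <- fit_pca(X)
  expect_equal(sample_shape(model, 3, z = rep(0, 3)), model$mean,
               ignore_attr = TRUE)
  expect_identical(sample_shape(model, 3, seed = 42),
                   sample_shape(model, 3, seed = 42))

  draws <- t(vapply(1:10000, function(i)
    sample_shape(model, 2, seed = i), numeric(ncol(X))))
  sc <- sweep(draws, 2, model$mean) %*% model$eigenvectors[, 1:2]
  expect_equal(apply(sc, 2, stats::var), model$eigenvalues[1:2],
               tolerance = 0.05 * model$eigenvalues[1])
})

test_that("correspondence sets serialise to CSV and reload", {
  mesh <- quick_anatomy(2, detail = 0.2)
  corr <- establish_correspondence(list(mesh, mesh), K = 32L, K_init = 16L,
                                   seed = 1)
  dir <- file.path(tempdir(), "corr_test")
  write_correspondence(corr, dir)
  df <- utils::read.csv(file.path(dir, "shape_001_particles.csv"))
  expect_equal(as.matrix(df), corr$points[[1]], ignore_attr = TRUE)
  unlink(dir, recursive = TRUE)
})
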