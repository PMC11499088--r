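test_that("rigid transform algebra composes and inverts", {
  R1 <- random_rotation(1)
  R2 <- random_rotation(2)
  a <- rigid_transform(R1, c(1, 2, 3))
  b <- rigid_transform(R2, c(-4, 0, 2))
  p <- matrix(stats::rnorm(30), 10, 3)
  expect_equal(apply_rigid(compose_rigid(a, b), p),
               apply_rigid(a, apply_rigid(b, p)), tolerance = 1e-12)
  expect_equal(apply_rigid(invert_rigid(a), apply_rigid(a, p)), p,
               tolerance = 1e-12)
  expect_error(rigid_transform(matrix(1, 3, 3)), class = "morphodetail_invalid_spec")
})

test_that("coarse alignment recovers pose of elongated anatomies", {
  mesh <- quick_anatomy(31, bend = 70, detail = 0.3)

  # identical shapes: near-identity
  tf <- coarse_align(mesh, mesh)
  expect_lt(morphodetail:::rotation_angle(tf$rotation), 1e-6)

  # known 90-degree rotation about z is recovered within 5 degrees
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  target <- transform_mesh(mesh, Rz, c(5, -3, 2))
  tf2 <- coarse_align(mesh, target)
  err <- morphodetail:::rotation_angle(t(Rz) %*% tf2$rotation)
  expect_lt(err * 180 / pi, 5)

  # spherically symmetric input falls back to identity with a warning
  sp <- normalize_volume(icosphere(2, 3))
  expect_warning(tf3 <- coarse_align(sp, sp),
                 class = "morphodetail_degenerate_inertia")
  expect_equal(tf3$rotation, diag(3))
})

test_that("ICP recovers a known rigid perturbation precisely", {
  mesh <- quick_anatomy(12, bend = 55, detail = 0.3)
  ang <- 15 * pi / 180
  Rz <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  t_true <- c(3, -2, 3)
  target <- transform_mesh(mesh, Rz, t_true)

  res <- icp(mesh, target, init = coarse_align(mesh, target), seed = 4)
  expect_true(res$report$converged)
  rot_err <- morphodetail:::rotation_angle(t(Rz) %*% res$transform$rotation)
  expect_lt(rot_err * 180 / pi, 0.5)
  expect_lt(sqrt(sum((res$transform$translation - t_true)^2)), 0.1)

  # identical pre-aligned meshes converge immediately with fraction 1
  res0 <- icp(mesh, mesh, seed = 5)
  expect_true(res0$report$converged)
  expect_lte(res0$report$iterations, 2L)
  expect_equal(res0$report$fraction, 1.0)

  # defaults follow the alignment protocol
  expect_equal(formals(icp)$n_samples, 2000L)
  expect_equal(formals(icp)$d_start, 10)
  expect_equal(formals(icp)$d_target, 0.5)
  expect_equal(formals(icp)$q_target, 0.80)
})

test_that("registration is left-invariant under a common rigid motion", {
  mesh <- quick_anatomy(8, bend = 65, detail = 0.2)
  pert <- rigid_transform(random_rotation(3, max_angle = 0.3), c(2, 1, -1))
  src <- transform_mesh(mesh, pert$rotation, pert$translation)

  fit1 <- icp(src, mesh, init = coarse_align(src, mesh), seed = 6)
  g <- rigid_transform(random_rotation(9), c(10, -5, 4))
  src_g <- transform_mesh(src, g$rotation, g$translation)
  tgt_g <- transform_mesh(mesh, g$rotation, g$translation)
  fit2 <- icp(src_g, tgt_g, init = coarse_align(src_g, tgt_g), seed = 6)

  rel <- compose_rigid(invert_rigid(g), compose_rigid(fit2$transform, g))
  expect_equal(rel$rotation, fit1$transform$rotation, tolerance = 1e-6)
  expect_equal(rel$translation, fit1$transform$translation, tolerance = 1e-4)
})

test_that("multiview registration aligns perturbed copies perfectly", {
  mesh <- quick_anatomy(20, bend = 60, detail = 0.25)
  meshes <- list(
    mesh,
    transform_mesh(mesh, random_rotation(101, max_angle = 0.4), c(4, 2, -3)),
    transform_mesh(mesh, random_rotation(102, max_angle = 0.4), c(-2, 5, 1)))
  out <- multiview_register(meshes, seed = 3)
  expect_true(out$report$converged)
  expect_equal(min(out$report$pair_fractions), 1.0, tolerance = 0.01)

  single <- multiview_register(list(mesh))
  expect_true(single$report$converged)
  expect_equal(single$transforms[[1]]$rotation, diag(3))
})
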