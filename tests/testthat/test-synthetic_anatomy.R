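test_that("generation is deterministic and validates its spec", {
  sp <- anatomy_spec(seed = 5, mesh_resolution = 1.2)
  m1 <- generate_shape(sp)
  m2 <- generate_shape(sp)
  expect_identical(m1$vertices, m2$vertices)
  expect_identical(m1$faces, m2$faces)

  expect_error(anatomy_spec(bend_angle = 190), class = "morphodetail_invalid_spec")
  expect_error(anatomy_spec(length = -1), class = "morphodetail_invalid_spec")
  # displacement bound: detail amplitude must stay below the minimum radius
  expect_error(anatomy_spec(detail_amplitude = 5,
                            radius_profile = cbind(c(0, 1), c(4, 4))),
               class = "morphodetail_invalid_spec")
})

test_that("degenerate smooth spec gives a straight capped tube", {
  sp <- anatomy_spec(bend_angle = 0, n_lobes = 0L, detail_amplitude = 0,
                     radius_profile = cbind(c(0, 1), c(4, 4)),
                     length = 30, mesh_resolution = 0.8, seed = 3)
  m <- generate_shape(sp)
  expect_true(is_watertight(m))
  expect_equal(mesh_genus(m), 0L)
  # interior vertices (outside the end caps) sit at the profile radius
  z <- m$vertices[, 3]
  interior <- z > 0.15 * 30 & z < 0.85 * 30
  r <- sqrt(m$vertices[interior, 1]^2 + m$vertices[interior, 2]^2)
  expect_lt(max(abs(r - 4)), sp$mesh_resolution)
})

test_that("generated meshes are watertight genus-0 with positive volume", {
  set.seed(99)
  for (i in 1:200) {
    sp <- anatomy_spec(
      bend_angle = stats::runif(1, 0, 170),
      length = stats::runif(1, 20, 50),
      n_lobes = sample(0:3, 1),
      lobe_amplitude = stats::runif(1, 0.5, 3),
      detail_amplitude = stats::runif(1, 0, 1),
      detail_frequency = stats::runif(1, 0.2, 0.8),
      mesh_resolution = 2.0,
      seed = i)
    m <- generate_shape(sp)
    expect_true(is_watertight(m))
    expect_equal(mesh_genus(m), 0L)
    vol <- mesh_volume(m)
    expect_true(is.finite(vol) && vol > 0)
    expect_equal(mesh_volume(normalize_volume(m)), 6000, tolerance = 1e-6)
  }
})

test_that("detail energy recovers the construction amplitude", {
  # fine-detail tube: RMS radial residual close to the detail amplitude
  spf <- anatomy_spec(bend_angle = 0, n_lobes = 0L, detail_amplitude = 0.4,
                      detail_frequency = 1.0,
                      radius_profile = cbind(c(0, 1), c(4, 4)),
                      length = 20, mesh_resolution = 0.35, seed = 9)
  mf <- generate_shape(spf)
  smf <- smooth_counterpart(spf)
  rms <- detail_energy(mf, smf)
  expect_gt(rms, 0.3)
  expect_lt(rms, 0.5)
  expect_lt(abs(rms - 0.4) / 0.4, 0.25)

  # identity and constant-offset sanity
  expect_equal(detail_energy(smf, smf), 0, tolerance = 1e-12)
  s1 <- icosphere(3, 3)
  s2 <- icosphere(3.25, 3)
  expect_equal(detail_energy(s2, s1), 0.25, tolerance = 0.02)

  # monotone in amplitude at fixed seed
  prev <- -1
  for (a in c(0.1, 0.3, 0.6)) {
    sp <- anatomy_spec(detail_amplitude = a, mesh_resolution = 1.0, seed = 21)
    e <- detail_energy(generate_shape(sp), smooth_counterpart(sp))
    expect_gt(e, prev)
    prev <- e
  }

  open_mesh <- trimesh(s1$vertices, s1$faces[-1, ])
  expect_error(detail_energy(open_mesh, s1), class = "morphodetail_invalid_mesh")
})

test_that("cohort labels follow the prevalence with deterministic rounding", {
  drawn <- cohort_anatomy_specs(cohort_spec(n_shapes = 85L, master_seed = 2))
  expect_equal(sum(drawn$labels == "CW"), 21L)
  expect_equal(length(drawn$labels), 85L)

  # determinism of the full cohort
  small <- cohort_spec(n_shapes = 6L, mesh_resolution = 1.6, master_seed = 4)
  c1 <- generate_cohort(small)
  c2 <- generate_cohort(small)
  expect_identical(c1$labels, c2$labels)
  expect_identical(lapply(c1$meshes, `[[`, "vertices"),
                   lapply(c2$meshes, `[[`, "vertices"))

  # label proportions for other sizes round deterministically
  for (n in c(10L, 40L, 100L)) {
    d <- cohort_anatomy_specs(cohort_spec(n_shapes = n, master_seed = 1))
    expect_equal(sum(d$labels == "CW"), as.integer(round(n * 21 / 85)))
  }
})

test_that("zero detail-class coupling leaves detail distributions class-free", {
  # over 50 cohorts, per-class detail_frequency draws come from one
  # distribution: Kolmogorov-Smirnov should reject at alpha = 0.01 only at
  # the nominal rate
  pvals <- vapply(1:50, function(s) {
    d <- cohort_anatomy_specs(cohort_spec(n_shapes = 30L,
                                          detail_class_coupling = 0,
                                          master_seed = 1000L + s))
    freq <- vapply(d$specs, `[[`, numeric(1), "detail_frequency")
    suppressWarnings(stats::ks.test(freq[d$labels == "CW"],
                                    freq[d$labels == "NCW"])$p.value)
  }, numeric(1))
  expect_lt(sum(pvals < 0.01), 4)

  # with coupling the distributions must differ
  d1 <- cohort_anatomy_specs(cohort_spec(n_shapes = 60L,
                                         detail_class_coupling = 1,
                                         master_seed = 77))
  freq <- vapply(d1$specs, `[[`, numeric(1), "detail_frequency")
  expect_lt(suppressWarnings(
    stats::ks.test(freq[d1$labels == "CW"], freq[d1$labels == "NCW"])$p.value),
    0.01)
})

test_that("cohort round-trips to disk with labels and manifest", {
  ch <- generate_cohort(cohort_spec(n_shapes = 4L, mesh_resolution = 1.8,
                                    master_seed = 12))
  dir <- file.path(tempdir(), "cohort_test")
  write_cohort(ch, dir)
  expect_true(file.exists(file.path(dir, "labels.csv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  labs <- read_labels(file.path(dir, "labels.csv"))
  expect_equal(labs$label, ch$labels)
  m <- read_mesh(file.path(dir, "shape_001.ply"))
  expect_identical(unname(m$vertices), unname(ch$meshes[[1]]$vertices))
  unlink(dir, recursive = TRUE)
})
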