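test_that("volume, watertightness and genus are exact on reference solids", {
  cube <- unit_cube()
  expect_true(is_watertight(cube))
  expect_equal(mesh_genus(cube), 0L)
  expect_equal(mesh_volume(cube), 1.0)

  sp <- icosphere(2, 4)
  expect_true(is_watertight(sp))
  expect_equal(mesh_genus(sp), 0L)
  expect_lt(abs(mesh_volume(sp) - 4 / 3 * pi * 8) / (4 / 3 * pi * 8), 0.01)

  # scaling law: volume scales with s^3
  s <- 2.7
  scaled <- trimesh(cube$vertices * s, cube$faces)
  expect_equal(mesh_volume(scaled), s^3, tolerance = 1e-12)

  # an open mesh (one face removed) is rejected
  open_mesh <- trimesh(cube$vertices, cube$faces[-1, ])
  expect_false(is_watertight(open_mesh))
  expect_error(mesh_volume(open_mesh), class = "morphodetail_invalid_mesh")
})

test_that("volume is invariant under rigid motion", {
  sp <- icosphere(1.5, 3)
  v0 <- mesh_volume(sp)
  for (seed in 1:5) {
    R <- random_rotation(seed)
    t <- stats::rnorm(3, sd = 10)
    moved <- transform_mesh(sp, R, t)
    expect_lt(abs(mesh_volume(moved) - v0) / v0, 1e-9)
  }
})

test_that("normalize_volume hits the target exactly and is idempotent", {
  cube <- unit_cube()
  n <- normalize_volume(cube, 6000)
  expect_equal(mesh_volume(n), 6000, tolerance = 1e-9)
  # cube scaled to 6000 mm^3 has edge 6000^(1/3)
  expect_equal(max(n$vertices[, 1]) - min(n$vertices[, 1]), 6000^(1 / 3),
               tolerance = 1e-9)
  n2 <- normalize_volume(n, 6000)
  expect_equal(n2$vertices, n$vertices, tolerance = 1e-12)
  # the default target is 6000 mm^3
  expect_equal(mesh_volume(normalize_volume(cube)), 6000, tolerance = 1e-9)
  # commutes with rigid motion
  R <- random_rotation(42)
  a <- normalize_volume(transform_mesh(cube, R, c(1, 2, 3)), 500)
  b <- transform_mesh(normalize_volume(cube, 500), R, c(1, 2, 3))
  expect_equal(a$vertices, b$vertices, tolerance = 1e-9)
})

test_that("mesh IO round-trips across formats", {
  mesh <- normalize_volume(unit_cube(), 100)

  ply <- tempfile(fileext = ".ply")
  write_mesh(mesh, ply)
  back <- read_mesh(ply)
  expect_identical(unname(back$vertices), unname(mesh$vertices))  # bit-exact
  expect_equal(nrow(back$faces), 12L)
  expect_equal(mesh_volume(back), 100, tolerance = 1e-9)

  ply_ascii <- tempfile(fileext = ".ply")
  write_mesh(mesh, ply_ascii, ascii = TRUE)
  expect_equal(read_mesh(ply_ascii)$vertices, unname(mesh$vertices),
               tolerance = 1e-12)

  # STL duplicates vertices per facet; welding restores 8 vertices, 12 faces
  stl <- tempfile(fileext = ".stl")
  write_mesh(mesh, stl)
  back_stl <- read_mesh(stl)
  expect_equal(nrow(back_stl$vertices), 8L)
  expect_equal(nrow(back_stl$faces), 12L)
  expect_true(is_watertight(back_stl))
  expect_gt(mesh_volume(back_stl), 0)

  stl_ascii <- tempfile(fileext = ".stl")
  write_mesh(mesh, stl_ascii, ascii = TRUE)
  expect_equal(nrow(read_mesh(stl_ascii)$vertices), 8L)

  obj <- tempfile(fileext = ".obj")
  write_mesh(mesh, obj)
  expect_equal(mesh_volume(read_mesh(obj)), 100, tolerance = 1e-9)

  empty <- tempfile(fileext = ".ply")
  file.create(empty)
  expect_error(read_mesh(empty), class = "morphodetail_format_error")
  expect_error(read_mesh(tempfile(fileext = ".xyz")),
               class = "morphodetail_format_error")
})

test_that("orientation repair recovers consistent outward winding", {
  cube <- unit_cube()
  f <- cube$faces
  flip <- c(2, 5, 7, 11)
  f[flip, ] <- f[flip, c(1, 3, 2)]
  broken <- trimesh(cube$vertices, f)
  expect_false(is_watertight(broken))
  fixed <- repair_orientation(broken)
  expect_true(is_watertight(fixed))
  expect_equal(mesh_volume(fixed), 1.0)
})

test_that("surface sampling is area-uniform, on-surface and seeded", {
  mesh <- normalize_volume(unit_cube(), 1000)
  pc <- sample_surface(mesh, 500, seed = 3)
  expect_equal(nrow(pc$points), 500L)
  expect_equal(sqrt(rowSums(pc$normals^2)), rep(1, 500), tolerance = 1e-9)
  # every sample lies on the surface
  expect_lt(max(closest_points(mesh, pc$points)$dist), 1e-9)
  # determinism
  pc2 <- sample_surface(mesh, 500, seed = 3)
  expect_identical(pc$points, pc2$points)

  # two triangles with 9:1 area ratio: counts within the binomial 99% interval
  v <- rbind(c(0, 0, 0), c(9, 0, 0), c(0, 2, 0), c(11, 0, 0), c(11, 1, 0))
  tri2 <- trimesh(v, rbind(c(1, 2, 3), c(2, 4, 5)))   # areas 9 and 1
  n <- 10000
  pc3 <- sample_surface(tri2, n, seed = 7)
  n_big <- sum(pc3$points[, 1] < 9 - 1e-9)
  p <- 0.9
  expect_lt(abs(n_big - n * p), 2.58 * sqrt(n * p * (1 - p)) + 1)
})

test_that("mesh_info reports the meshinfo CLI fields", {
  info <- mesh_info(unit_cube())
  expect_equal(info$n_vertices, 8L)
  expect_equal(info$n_faces, 12L)
  expect_true(info$watertight)
  expect_equal(info$genus, 0L)
  expect_equal(info$volume_mm3, 1.0)
})
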