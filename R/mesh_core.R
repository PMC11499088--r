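#' Triangle mesh constructor
#'
#' A `trimesh` is the unit of all geometry in the package: an ordered vertex
#' matrix (mm), a face matrix of vertex-index triples, and optionally unit
#' per-vertex normals. Faces are validated for index range and duplicates;
#' orientation is the caller's responsibility (see [repair_orientation()]).
#'
#' @param vertices numeric matrix, n x 3, coordinates in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices.
#' @param normals optional numeric matrix, n x 3, unit vertex normals.
#' @return An object of class `trimesh`.
#' @export
trimesh <- function(vertices, faces, normals = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L || ncol(faces) != 3L)
    stop_md("invalid-mesh", "vertices and faces must have 3 columns")
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop_md("invalid-mesh", "face indices out of range")
  if (nrow(faces) > 1L) {
    lo <- pmin(faces[, 1], faces[, 2], faces[, 3])
    hi <- pmax(faces[, 1], faces[, 2], faces[, 3])
    mid <- faces[, 1] + faces[, 2] + faces[, 3] - lo - hi
    ord <- order(lo, mid, hi)
    same <- diff(lo[ord]) == 0 & diff(mid[ord]) == 0 & diff(hi[ord]) == 0
    if (any(same)) stop_md("invalid-mesh", "duplicated faces")
  }
  if (!is.null(normals)) {
    normals <- as.matrix(normals)
    storage.mode(normals) <- "double"
    stopifnot(nrow(normals) == nrow(vertices), ncol(normals) == 3L)
  }
  structure(list(vertices = vertices, faces = faces, normals = normals),
            class = "trimesh")
}

#' @export
print.trimesh <- function(x, ...) {
  wt <- tryCatch(is_watertight(x), error = function(e) NA)
  cat(sprintf("trimesh: %d vertices, %d faces, watertight: %s\n",
              nrow(x$vertices), nrow(x$faces), wt))
  invisible(x)
}

# undirected edges as a 2-column matrix (one row per half-edge)
mesh_halfedges <- function(mesh) {
  f <- mesh$faces
  cbind(c(f[, 1], f[, 2], f[, 3]), c(f[, 2], f[, 3], f[, 1]))
}

edge_keys <- function(he, nv) {
  a <- pmin(he[, 1], he[, 2])
  b <- pmax(he[, 1], he[, 2])
  (a - 1) * as.double(nv) + b
}

#' Watertightness test
#'
#' A mesh is watertight when every undirected edge is shared by exactly two
#' faces, traversed in opposite directions (consistent orientation).
#'
#' @param mesh a [trimesh()].
#' @return logical.
#' @export
is_watertight <- function(mesh) {
  he <- mesh_halfedges(mesh)
  nv <- nrow(mesh$vertices)
  k <- sort(edge_keys(he, nv))
  n <- length(k)
  if (n %% 2L != 0L) return(FALSE)
  odd <- seq(1L, n, by = 2L)
  # sorted keys must pair up exactly: positions 1-2 equal, 2-3 differ, ...
  if (any(k[odd] != k[odd + 1L])) return(FALSE)
  if (n > 2L && any(k[odd[-1]] == k[odd[-1] - 1L])) return(FALSE)
  # opposite traversal: each directed edge occurs exactly once
  dk <- (he[, 1] - 1) * as.double(nv) + he[, 2]
  !anyDuplicated(dk)
}

#' Mesh genus
#'
#' Genus from the Euler characteristic V - E + F = 2 - 2g of a closed
#' connected surface.
#'
#' @param mesh a watertight [trimesh()].
#' @return integer genus (0 for a topological sphere).
#' @export
mesh_genus <- function(mesh) {
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  ne <- length(unique(edge_keys(mesh_halfedges(mesh), nv)))
  as.integer((2L - (nv - ne + nf)) / 2L)
}

face_cross <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  e1 <- b - a
  e2 <- c_ - a
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

#' Face areas in mm^2
#' @param mesh a [trimesh()].
#' @export
face_areas <- function(mesh) {
  cr <- face_cross(mesh)
  0.5 * sqrt(rowSums(cr^2))
}

#' Outward unit face normals
#' @param mesh a consistently oriented [trimesh()].
#' @export
face_normals <- function(mesh) {
  cr <- face_cross(mesh)
  n <- sqrt(rowSums(cr^2))
  n[n == 0] <- 1
  cr / n
}

#' Area-weighted unit vertex normals
#' @param mesh a consistently oriented [trimesh()].
#' @export
vertex_normals <- function(mesh) {
  cr <- face_cross(mesh)  # area-weighted face normals (x2)
  f <- mesh$faces
  n <- matrix(0, nrow(mesh$vertices), 3)
  for (k in 1:3) {
    n[, 1] <- n[, 1] + tabulate_weighted(f[, k], cr[, 1], nrow(n))
    n[, 2] <- n[, 2] + tabulate_weighted(f[, k], cr[, 2], nrow(n))
    n[, 3] <- n[, 3] + tabulate_weighted(f[, k], cr[, 3], nrow(n))
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

tabulate_weighted <- function(idx, w, nbins) {
  out <- numeric(nbins)
  agg <- rowsum(w, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Enclosed volume of a closed mesh
#'
#' Signed-tetrahedron (divergence theorem) sum; positive when faces are
#' consistently outward-oriented. Volume is the quantity used for size
#' normalisation across a cohort.
#'
#' @param mesh a watertight [trimesh()].
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  if (!is_watertight(mesh))
    stop_md("invalid-mesh", "mesh_volume requires a watertight mesh")
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
      a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Surface centroid (area-weighted mean of face centroids)
#' @param mesh a [trimesh()].
#' @export
mesh_centroid <- function(mesh) {
  f <- mesh$faces
  v <- mesh$vertices
  cen <- (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
            v[f[, 3], , drop = FALSE]) / 3
  w <- face_areas(mesh)
  colSums(cen * w) / sum(w)
}

#' Scale a mesh to a target enclosed volume
#'
#' Uniform scaling about the surface centroid, so that the result encloses
#' exactly `target` mm^3. The default of 6000 mm^3 is the cohort-wide
#' normalisation volume used throughout the pipeline.
#'
#' @param mesh a watertight [trimesh()] with positive volume.
#' @param target target volume in mm^3.
#' @return the rescaled [trimesh()].
#' @export
normalize_volume <- function(mesh, target = 6000) {
  vol <- mesh_volume(mesh)
  if (!is.finite(vol) || vol <= 0)
    stop_md("invalid-mesh", "normalize_volume requires positive volume (got %g)", vol)
  s <- (target / vol)^(1 / 3)
  cen <- mesh_centroid(mesh)
  v <- sweep(sweep(mesh$vertices, 2, cen), 2, rep(s, 3), `*`)
  v <- sweep(v, 2, cen, `+`)
  trimesh(v, mesh$faces, mesh$normals)
}

#' Oriented point cloud constructor
#'
#' Surface sample points with outward unit normals; the input to point
#' thinning, implicit reconstruction and ICP.
#'
#' @param points numeric matrix, n x 3, mm.
#' @param normals numeric matrix, n x 3, unit vectors.
#' @export
oriented_point_cloud <- function(points, normals) {
  points <- as.matrix(points)
  normals <- as.matrix(normals)
  storage.mode(points) <- storage.mode(normals) <- "double"
  if (nrow(points) != nrow(normals) || ncol(points) != 3L || ncol(normals) != 3L)
    stop_md("invalid-mesh", "points and normals must be n x 3 with equal n")
  len <- sqrt(rowSums(normals^2))
  if (any(abs(len - 1) > 1e-6))
    stop_md("invalid-mesh", "normals must be unit length")
  structure(list(points = points, normals = normals), class = "opcloud")
}

#' @export
print.opcloud <- function(x, ...) {
  cat(sprintf("oriented point cloud: %d points\n", nrow(x$points)))
  invisible(x)
}

#' Area-uniform oriented surface sampling
#'
#' Draws `n` points with faces chosen proportionally to area and uniform
#' barycentric coordinates within each face; normals are taken from the face
#' normals.
#'
#' @param mesh a consistently oriented [trimesh()].
#' @param n number of samples (>= 1).
#' @param seed integer seed; identical seeds give identical clouds.
#' @return an [oriented_point_cloud()] of size `n`.
#' @export
sample_surface <- function(mesh, n, seed = 1L) {
  stopifnot(n >= 1)
  areas <- face_areas(mesh)
  fn <- face_normals(mesh)
  with_seed(seed, {
    fi <- sample.int(nrow(mesh$faces), n, replace = TRUE, prob = areas)
    r1 <- sqrt(stats::runif(n))
    r2 <- stats::runif(n)
    u <- 1 - r1
    v <- r1 * (1 - r2)
    w <- r1 * r2
    f <- mesh$faces[fi, , drop = FALSE]
    p <- mesh$vertices[f[, 1], , drop = FALSE] * u +
      mesh$vertices[f[, 2], , drop = FALSE] * v +
      mesh$vertices[f[, 3], , drop = FALSE] * w
    oriented_point_cloud(p, fn[fi, , drop = FALSE])
  })
}

#' Closest points on a mesh surface
#'
#' Exact closest-point projection of query points onto the triangles of a
#' mesh, grid-accelerated. The sign is positive on the outward side of the
#' nearest face.
#'
#' @param mesh a [trimesh()].
#' @param points numeric matrix, n x 3.
#' @return list with `point` (projections), `dist` (unsigned distances),
#'   `face` (1-based triangle ids), `sign` (+/-1).
#' @export
closest_points <- function(mesh, points) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  f0 <- mesh$faces - 1L
  cpp_closest_point_mesh(points, mesh$vertices, f0)
}

#' Mesh summary used by the command-line `meshinfo` tool
#' @param mesh a [trimesh()].
#' @return list with vertex/face counts, watertightness, genus and volume.
#' @export
mesh_info <- function(mesh) {
  wt <- is_watertight(mesh)
  list(
    n_vertices = nrow(mesh$vertices),
    n_faces = nrow(mesh$faces),
    watertight = wt,
    genus = if (wt) mesh_genus(mesh) else NA_integer_,
    volume_mm3 = if (wt) mesh_volume(mesh) else NA_real_
  )
}

#' Apply a rigid transform (or any 3x3 linear map + translation) to a mesh
#' @param mesh a [trimesh()].
#' @param rotation 3x3 matrix.
#' @param translation length-3 vector.
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  v <- mesh$vertices %*% t(rotation)
  v <- sweep(v, 2, translation, `+`)
  nrm <- if (!is.null(mesh$normals)) mesh$normals %*% t(rotation) else NULL
  trimesh(v, mesh$faces, nrm)
}
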