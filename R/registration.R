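# Rigid registration: coarse moment-based alignment to a reference, local
# point-to-surface ICP with per-iteration resampling and a geometrically
# shrinking correspondence-rejection distance, and multiview refinement in
# which each shape is re-registered against the pooled samples of all others
# until every pair meets the alignment criterion (a fixed fraction of surface
# samples within a fixed distance of the partner surface).

#' Rigid transform
#'
#' @param rotation 3x3 proper rotation matrix.
#' @param translation length-3 translation, mm.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 || det(rotation) < 0)
    stop_md("invalid-spec", "rotation must be proper orthonormal")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle(x$rotation) * 180 / pi
  cat(sprintf("rigid transform: rotation %.2f deg, translation %.3f mm\n",
              ang, sqrt(sum(x$translation^2))))
  invisible(x)
}

#' Compose two rigid transforms (apply `a` after `b`)
#' @param a,b [rigid_transform()] objects.
#' @export
compose_rigid <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param tf a [rigid_transform()].
#' @export
invert_rigid <- function(tf) {
  rigid_transform(t(tf$rotation), as.numeric(-t(tf$rotation) %*% tf$translation))
}

#' Apply a rigid transform to points (n x 3)
#' @param tf a [rigid_transform()].
#' @param points numeric matrix n x 3.
#' @export
apply_rigid <- function(tf, points) {
  sweep(points %*% t(tf$rotation), 2, tf$translation, `+`)
}

rotation_angle <- function(R) {
  acos(min(max((sum(diag(R)) - 1) / 2, -1), 1))
}

# area-weighted surface moments: centroid and principal axes (det +1)
surface_moments <- function(mesh) {
  f <- mesh$faces
  v <- mesh$vertices
  cen <- (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
            v[f[, 3], , drop = FALSE]) / 3
  w <- face_areas(mesh)
  w <- w / sum(w)
  mu <- colSums(cen * w)
  cc <- sweep(cen, 2, mu)
  cov <- crossprod(cc * sqrt(w))
  eig <- eigen(cov, symmetric = TRUE)
  axes <- eig$vectors
  if (det(axes) < 0) axes[, 3] <- -axes[, 3]
  list(centroid = mu, axes = axes, lambda = eig$values)
}

#' Coarse moment-based rigid alignment
#'
#' Aligns centroids and principal surface axes of `source` to `target`,
#' trying the four proper-rotation sign combinations and keeping the one with
#' the lowest sampled closest-point RMS. Falls back to the identity (with a
#' warning) for near-spherically-symmetric shapes, whose principal axes are
#' ill-defined.
#'
#' @param source,target volume-normalised [trimesh()] objects.
#' @param n_probe number of source samples used to score candidates.
#' @return a [rigid_transform()] mapping source into the target frame.
#' @export
coarse_align <- function(source, target, n_probe = 500L) {
  ms <- surface_moments(source)
  mt <- surface_moments(target)
  rel <- function(l) (l[1] - l[3]) / max(l[1], 1e-12)
  if (rel(ms$lambda) < 0.02 || rel(mt$lambda) < 0.02) {
    warn_md("degenerate-inertia",
            "near-isotropic shape: coarse alignment falls back to identity")
    return(rigid_transform(diag(3), mt$centroid - ms$centroid))
  }
  probes <- sample_surface(source, n_probe, seed = 421L)$points
  best <- NULL
  best_rms <- Inf
  for (signs in list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))) {
    R <- mt$axes %*% diag(signs) %*% t(ms$axes)
    tf <- rigid_transform(R, mt$centroid - as.numeric(R %*% ms$centroid))
    d <- closest_points(target, apply_rigid(tf, probes))$dist
    rms <- sqrt(mean(d^2))
    if (rms < best_rms) { best_rms <- rms; best <- tf }
  }
  best
}

#' Iterative closest point registration to a target surface
#'
#' Point-to-surface ICP with fresh area-uniform resampling of the source at
#' every iteration. Correspondences farther than a rejection distance are
#' dropped; the distance starts at `d_start` and shrinks geometrically (factor
#' 0.9) to a floor of `d_target`. The algorithm stops when a fraction
#' `q_target` of the samples lies within `d_target` of the target surface, or
#' at the iteration cap, returning the best transform either way.
#'
#' @param source,target [trimesh()] objects.
#' @param init initial [rigid_transform()] (e.g. from [coarse_align()]).
#' @param n_samples samples per iteration.
#' @param d_start starting rejection distance, mm.
#' @param d_target alignment distance of the convergence criterion, mm.
#' @param q_target required fraction of samples within `d_target`.
#' @param seed integer seed for the per-iteration resampling.
#' @param max_iter iteration cap.
#' @return list with `transform` ([rigid_transform()]) and `report` (fields
#'   `fraction`, `iterations`, `converged`).
#' @export
icp <- function(source, target, init = NULL, n_samples = 2000L, d_start = 10,
                d_target = 0.5, q_target = 0.80, seed = 1L, max_iter = 200L) {
  tf <- if (is.null(init)) rigid_transform() else init
  reject <- d_start
  frac <- 0
  best_tf <- tf
  best_frac <- -1
  it <- 0L
  converged <- FALSE
  stall <- 0L
  while (it < max_iter) {
    it <- it + 1L
    pts <- sample_surface(source, n_samples, seed = derive_seed(seed, it))$points
    moved <- apply_rigid(tf, pts)
    cp <- closest_points(target, moved)
    frac <- mean(cp$dist < d_target)
    if (frac > best_frac) { best_frac <- frac; best_tf <- tf }
    if (frac >= q_target) { converged <- TRUE; break }
    keep <- cp$dist <= reject
    if (sum(keep) >= 3L) {
      delta <- kabsch(moved[keep, , drop = FALSE], cp$point[keep, , drop = FALSE])
      tf <- compose_rigid(delta, tf)
      # once the rejection schedule has bottomed out, stop when the update
      # stalls: shapes that differ genuinely will never meet the criterion
      small <- rotation_angle(delta$rotation) < 2e-4 &&
        sqrt(sum(delta$translation^2)) < 2e-3
      stall <- if (small && reject <= d_target * 1.001) stall + 1L else 0L
      if (stall >= 3L) break
    }
    reject <- max(reject * 0.9, d_target)
  }
  list(transform = if (converged) tf else best_tf,
       report = list(fraction = if (converged) frac else best_frac,
                     iterations = it, converged = converged))
}

# least-squares rigid transform mapping P onto Q (Kabsch, SVD)
kabsch <- function(P, Q) {
  cp <- colMeans(P)
  cq <- colMeans(Q)
  H <- crossprod(sweep(P, 2, cp), sweep(Q, 2, cq))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, cq - as.numeric(R %*% cp))
}

# ICP against a fixed point cloud (multiview pooled target)
icp_to_cloud <- function(source, cloud_pts, init, n_samples = 2000L,
                         d_start = 10, d_target = 0.5, seed = 1L, max_iter = 50L) {
  tf <- init
  reject <- d_start
  ext <- max(apply(cloud_pts, 2, function(x) diff(range(x))))
  for (it in seq_len(max_iter)) {
    pts <- sample_surface(source, n_samples, seed = derive_seed(seed, 900L, it))$points
    moved <- apply_rigid(tf, pts)
    nn <- cpp_nn_points(moved, cloud_pts, max(ext / 50, 1e-6), FALSE)
    keep <- nn$dist <= reject
    if (sum(keep) >= 3L) {
      delta <- kabsch(moved[keep, , drop = FALSE],
                      cloud_pts[nn$idx[keep], , drop = FALSE])
      tf <- compose_rigid(delta, tf)
      if (rotation_angle(delta$rotation) < 1e-5 &&
          sqrt(sum(delta$translation^2)) < 1e-4) break
    }
    reject <- max(reject * 0.9, d_target)
  }
  tf
}

# directed pair fraction: samples of mesh i (under tf_i) within d_target of
# mesh j (under tf_j)
pair_fraction <- function(mesh_i, tf_i, mesh_j, tf_j, n_samples, d_target, seed) {
  pts <- apply_rigid(tf_i, sample_surface(mesh_i, n_samples, seed = seed)$points)
  back <- apply_rigid(invert_rigid(tf_j), pts)
  mean(closest_points(mesh_j, back)$dist < d_target)
}

#' Multiview rigid registration of a cohort
#'
#' Coarse alignment plus ICP of every mesh to a reference, followed by rounds
#' in which each mesh is re-registered against the pooled surface samples of
#' all the others. Stops when every unordered pair satisfies the criterion
#' (`q_target` of samples within `d_target` in both directions) or after
#' `max_rounds`; non-convergent pairs are listed in the report and the
#' pipeline proceeds with a warning.
#'
#' @param meshes list of volume-normalised [trimesh()] objects.
#' @param reference_index index of the reference shape.
#' @param max_rounds multiview refinement rounds cap.
#' @param n_samples ICP/criterion sample count per mesh.
#' @param d_target,q_target pair criterion (mm, fraction).
#' @param seed integer seed.
#' @return list with `transforms` (per-mesh [rigid_transform()]), `report`
#'   (`pair_fractions` matrix, `rounds`, `converged`, `unconverged_pairs`)
#'   and `meshes` (the transformed meshes).
#' @export
multiview_register <- function(meshes, reference_index = 1L, max_rounds = 10L,
                               n_samples = 2000L, d_target = 0.5,
                               q_target = 0.80, seed = 1L) {
  n <- length(meshes)
  if (n < 1L) stop_md("invalid-spec", "need at least one mesh")
  transforms <- rep(list(rigid_transform()), n)
  if (n == 1L)
    return(list(transforms = transforms,
                report = list(pair_fractions = matrix(1, 1, 1), rounds = 0L,
                              converged = TRUE, unconverged_pairs = integer(0)),
                meshes = meshes))
  ref <- meshes[[reference_index]]
  for (i in seq_len(n)) {
    if (i == reference_index) next
    init <- coarse_align(meshes[[i]], ref)
    transforms[[i]] <- icp(meshes[[i]], ref, init, n_samples = n_samples,
                           d_target = d_target, q_target = q_target,
                           seed = derive_seed(seed, 50L, i))$transform
  }

  fractions <- function() {
    fr <- matrix(1, n, n)
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (i != j)
          fr[i, j] <- pair_fraction(meshes[[i]], transforms[[i]],
                                    meshes[[j]], transforms[[j]],
                                    n_samples, d_target,
                                    derive_seed(seed, 60L, i, j))
    fr
  }

  rounds <- 0L
  fr <- fractions()
  while (min(fr) < q_target && rounds < max_rounds) {
    rounds <- rounds + 1L
    for (i in seq_len(n)) {
      pooled <- do.call(rbind, lapply(setdiff(seq_len(n), i), function(j)
        apply_rigid(transforms[[j]],
                    sample_surface(meshes[[j]],
                                   max(500L, n_samples %/% (n - 1L)),
                                   seed = derive_seed(seed, 70L, rounds, j))$points)))
      transforms[[i]] <- icp_to_cloud(meshes[[i]], pooled, transforms[[i]],
                                      n_samples = n_samples, d_target = d_target,
                                      seed = derive_seed(seed, 80L, rounds, i))
    }
    fr <- fractions()
  }
  converged <- min(fr) >= q_target
  bad <- which(fr < q_target, arr.ind = TRUE)
  bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
  if (!converged)
    warn_md("alignment-incomplete",
            "%d pair(s) below the %g%%-within-%g mm criterion after %d rounds",
            nrow(bad), 100 * q_target, d_target, rounds)
  list(transforms = transforms,
       report = list(pair_fractions = fr, rounds = rounds, converged = converged,
                     unconverged_pairs = bad),
       meshes = lapply(seq_len(n), function(i)
         transform_mesh(meshes[[i]], transforms[[i]]$rotation,
                        transforms[[i]]$translation)))
}
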