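# Point-distribution shape model: dense particle correspondence across an
# aligned cohort, then PCA of the flattened particle coordinates. The
# correspondence scheme is multiscale: particles are initialised on a template
# shape by farthest-point sampling, propagated to every shape by closest-point
# projection, then relaxed by alternating surface repulsion (uniform coverage)
# with ensemble-mean attraction (cross-shape correspondence), the balance
# shifting from coverage- to correspondence-dominated over the iterations;
# the particle count doubles between scales until the target K is reached.

#' Establish dense particle correspondence across aligned meshes
#'
#' @param aligned_meshes list of aligned, volume-normalised [trimesh()]
#'   objects.
#' @param K final particle count (power-of-two multiple of `K_init`).
#' @param K_init initial particle count.
#' @param seed integer seed.
#' @param n_iter relaxation iterations per scale.
#' @param eps_surf maximum tolerated particle-to-surface distance, mm.
#' @return object of class `correspondence_set`: list with `points` (per
#'   shape K x 3 matrices), `K`, `ids`.
#' @export
establish_correspondence <- function(aligned_meshes, K = 1024L, K_init = 128L,
                                     seed = 1L, n_iter = 14L, eps_surf = 0.25) {
  n <- length(aligned_meshes)
  if (n < 1L) stop_md("invalid-spec", "need at least one mesh")
  K <- as.integer(K)
  K_init <- as.integer(K_init)
  if (K < K_init || K %% K_init != 0L || bitwAnd(K / K_init, K / K_init - 1L) != 0L)
    stop_md("invalid-spec", "K must be K_init times a power of two")

  # template: the shape whose propagated particles land closest on the others
  dense <- lapply(seq_len(n), function(i)
    sample_surface(aligned_meshes[[i]], 3000L, seed = derive_seed(seed, 1L, i))$points)
  template <- if (n == 1L) 1L else {
    cand_res <- vapply(seq_len(n), function(i) {
      idx <- cpp_farthest_point_sampling(dense[[i]], min(K_init, 64L), 1L)
      probe <- dense[[i]][idx, , drop = FALSE]
      mean(vapply(setdiff(seq_len(n), i), function(j)
        mean(closest_points(aligned_meshes[[j]], probe)$dist), numeric(1)))
    }, numeric(1))
    which.min(cand_res)
  }

  idx0 <- cpp_farthest_point_sampling(dense[[template]], K_init, 1L)
  fnormals <- lapply(aligned_meshes, face_normals)
  parts <- vector("list", n)
  pnormals <- vector("list", n)
  for (i in seq_len(n)) {
    cp <- closest_points(aligned_meshes[[i]], dense[[template]][idx0, , drop = FALSE])
    parts[[i]] <- cp$point
    pnormals[[i]] <- fnormals[[i]][cp$face, , drop = FALSE]
  }

  area <- vapply(aligned_meshes, function(m) sum(face_areas(m)), numeric(1))
  Kc <- K_init
  repeat {
    sigma <- 1.5 * sqrt(mean(area) / Kc)
    for (it in seq_len(n_iter)) {
      lam <- 0.15 + 0.65 * (it / n_iter)     # correspondence weight ramps up
      eta <- 0.45 * (1 - it / n_iter) + 0.05 # repulsion step ramps down
      ens <- Reduce(`+`, parts) / n
      for (i in seq_len(n)) {
        # correspondence is where-on-the-surface: the ensemble-mean pull acts
        # in the tangent plane only, so rough surfaces cannot soak up the
        # radial component and deflate the apparent shape variance
        pull <- lam * (ens - parts[[i]])
        nh <- pnormals[[i]]
        pull <- pull - nh * rowSums(pull * nh)
        x <- parts[[i]] + pull + eta * repulsion_step(parts[[i]], sigma)
        cp <- closest_points(aligned_meshes[[i]], x)
        parts[[i]] <- cp$point
        pnormals[[i]] <- fnormals[[i]][cp$face, , drop = FALSE]
      }
    }
    if (Kc >= K) break
    # split: duplicate every particle with a small seeded tangential offset
    off <- with_seed(derive_seed(seed, 5L, Kc), {
      o <- matrix(stats::rnorm(3L * Kc), Kc, 3L)
      o / sqrt(rowSums(o^2)) * 0.3 * sigma
    })
    for (i in seq_len(n)) {
      cp <- closest_points(aligned_meshes[[i]], parts[[i]] + off)
      parts[[i]] <- interleave_rows(parts[[i]], cp$point)
      pnormals[[i]] <- interleave_rows(pnormals[[i]], fnormals[[i]][cp$face, , drop = FALSE])
    }
    Kc <- 2L * Kc
  }

  for (i in seq_len(n)) {
    resid <- closest_points(aligned_meshes[[i]], parts[[i]])$dist
    if (max(resid) > eps_surf)
      stop_md("correspondence-failure",
              "particle %g mm off surface on shape %d", max(resid), i)
  }
  structure(list(points = parts, K = K,
                 ids = names(aligned_meshes) %||% sprintf("shape_%03d", seq_len(n))),
            class = "correspondence_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Gaussian inter-particle repulsion displacement, capped at 0.5 sigma
repulsion_step <- function(x, sigma) {
  d <- as.matrix(stats::dist(x))
  w <- exp(-(d / sigma)^2)
  diag(w) <- 0
  disp <- (w %*% x) * -1 + rowSums(w) * x   # sum_j w_ij (x_i - x_j)
  nrm <- sqrt(rowSums(disp^2))
  scale <- pmin(1, 0.5 * sigma / pmax(nrm, 1e-12))
  disp * scale
}

interleave_rows <- function(a, b) {
  out <- matrix(0, 2L * nrow(a), 3L)
  out[seq(1, 2 * nrow(a), by = 2), ] <- a
  out[seq(2, 2 * nrow(a), by = 2), ] <- b
  out
}

#' Flatten a correspondence set to the n_s x 3K data matrix
#' @param corr a `correspondence_set`.
#' @export
correspondence_matrix <- function(corr) {
  do.call(rbind, lapply(corr$points, function(p) as.numeric(t(p))))
}

#' Fit the PCA shape model of a correspondence set
#'
#' Mean over shapes and eigendecomposition of the sample covariance (divisor
#' n_s - 1) of the centred 3K-vectors; modes sorted by descending eigenvalue,
#' at most n_s - 1 of them.
#'
#' @param corr a `correspondence_set`, or an n_s x 3K numeric matrix.
#' @return object of class `shape_model` with fields `mean`, `eigenvalues`
#'   (mm^2), `eigenvectors` (3K x n_modes, orthonormal), `scores`
#'   (n_s x n_modes, zero mean per mode), `n_s`, `K`.
#' @export
fit_pca <- function(corr) {
  X <- if (inherits(corr, "correspondence_set")) {
    Ks <- vapply(corr$points, nrow, integer(1))
    if (length(unique(Ks)) != 1L)
      stop_md("invalid-correspondence", "particle counts differ across shapes")
    correspondence_matrix(corr)
  } else as.matrix(corr)
  n_s <- nrow(X)
  if (n_s < 2L) stop_md("invalid-correspondence", "need at least 2 shapes")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0, nv = min(n_s - 1L, ncol(X)))
  m <- min(n_s - 1L, ncol(X))
  lambda <- (sv$d[seq_len(m)]^2) / (n_s - 1)
  V <- sv$v
  scores <- Xc %*% V
  # canonical mode signs: the largest-|score| shape scores positive on each
  # mode, so results are reproducible across LAPACK builds and exactly
  # equivariant under rigid motion of the input
  for (j in seq_len(ncol(scores))) {
    i_max <- which.max(abs(scores[, j]))
    if (scores[i_max, j] < 0) {
      scores[, j] <- -scores[, j]
      V[, j] <- -V[, j]
    }
  }
  structure(list(mean = mu, eigenvalues = lambda, eigenvectors = V,
                 scores = scores, n_s = n_s, K = ncol(X) %/% 3L),
            class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf("shape model: %d shapes, %d particles, %d modes (total var %.3g mm^2)\n",
              x$n_s, x$K, length(x$eigenvalues), sum(x$eigenvalues)))
  invisible(x)
}

#' Reconstruct a shape vector with the first n_m modes
#'
#' @param model a [fit_pca()] model.
#' @param shape_vector length-3K numeric vector.
#' @param n_m number of modes, 1 <= n_m <= available modes.
#' @return the reconstructed 3K-vector.
#' @export
reconstruct_shape <- function(model, shape_vector, n_m) {
  n_m <- as.integer(n_m)
  if (n_m < 1L || n_m > length(model$eigenvalues))
    stop_md("invalid-spec", "n_m must be in [1, %d]", length(model$eigenvalues))
  V <- model$eigenvectors[, seq_len(n_m), drop = FALSE]
  centred <- shape_vector - model$mean
  as.numeric(model$mean + V %*% crossprod(V, centred))
}

#' Sample a random shape from the model
#'
#' mean + sum of z_i sqrt(lambda_i) v_i with z standard normal.
#'
#' @param model a [fit_pca()] model.
#' @param n_m number of modes used.
#' @param seed integer seed.
#' @param z optional fixed coefficients (overrides the random draw).
#' @return a 3K shape vector.
#' @export
sample_shape <- function(model, n_m, seed = 1L, z = NULL) {
  n_m <- as.integer(n_m)
  if (n_m < 1L || n_m > length(model$eigenvalues))
    stop_md("invalid-spec", "n_m must be in [1, %d]", length(model$eigenvalues))
  if (is.null(z)) z <- with_seed(seed, stats::rnorm(n_m))
  V <- model$eigenvectors[, seq_len(n_m), drop = FALSE]
  as.numeric(model$mean + V %*% (z * sqrt(model$eigenvalues[seq_len(n_m)])))
}

#' Write a correspondence set as per-shape CSV files plus a manifest
#' @param corr a `correspondence_set`.
#' @param dir output directory.
#' @export
write_correspondence <- function(corr, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(corr$points)) {
    df <- as.data.frame(corr$points[[i]])
    names(df) <- c("x", "y", "z")
    utils::write.csv(df, file.path(dir, paste0(corr$ids[i], "_particles.csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(list(K = corr$K, ids = corr$ids),
                       file.path(dir, "correspondence_manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
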