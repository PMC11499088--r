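# The three point-distribution-model evaluation metrics as functions of the
# number of retained modes n_m: compactness (cumulative eigenvalue variance),
# generalisation (leave-one-out reconstruction error of held-out shapes, mm)
# and specificity (distance from randomly sampled model shapes to their
# nearest training shape, mm). "Euclidean distance" between two shape vectors
# is reported as the mean per-particle Euclidean distance, which is
# comparable across particle counts; the total 3K-vector norm is available
# behind `per_particle = FALSE`.

#' Compactness of a shape model
#'
#' Sum of the leading n_m eigenvalues; normalised form divides by the total
#' variance so the value is the fraction of variance captured.
#'
#' @param model a [fit_pca()] model.
#' @param n_m number of modes.
#' @param normalized return the variance fraction (default) rather than mm^2.
#' @export
compactness <- function(model, n_m, normalized = TRUE) {
  n_m <- as.integer(n_m)
  if (n_m < 1L || n_m > length(model$eigenvalues))
    stop_md("invalid-spec", "n_m must be in [1, %d]", length(model$eigenvalues))
  s <- sum(model$eigenvalues[seq_len(n_m)])
  if (normalized) s / sum(model$eigenvalues) else s
}

shape_vec_dist <- function(a, b, K, per_particle = TRUE) {
  if (!per_particle) return(sqrt(sum((a - b)^2)))
  d <- matrix(a - b, nrow = 3L)
  mean(sqrt(colSums(d^2)))
}

#' Generalisation error (leave-one-out)
#'
#' For each shape j, a model is refitted on the remaining n_s - 1 shapes
#' (reusing the frozen correspondence) and x_j is reconstructed with n_m
#' modes; the mean reconstruction distance over all j is returned, in mm.
#'
#' @param corr a `correspondence_set` or n_s x 3K matrix.
#' @param n_m number of modes; at most n_s - 2 (a model without shape j has
#'   n_s - 2 modes).
#' @param per_particle mean per-particle distance (default) or total norm.
#' @export
generalisation <- function(corr, n_m, per_particle = TRUE) {
  X <- if (inherits(corr, "correspondence_set")) correspondence_matrix(corr)
       else as.matrix(corr)
  n_s <- nrow(X)
  if (n_s < 3L) stop_md("invalid-spec", "generalisation needs >= 3 shapes")
  n_m <- as.integer(n_m)
  if (n_m < 1L || n_m > n_s - 2L)
    stop_md("invalid-spec", "n_m must be in [1, n_s - 2]")
  K <- ncol(X) %/% 3L
  errs <- vapply(seq_len(n_s), function(j) {
    fold <- fit_pca(X[-j, , drop = FALSE])
    rec <- reconstruct_shape(fold, X[j, ], n_m)
    shape_vec_dist(X[j, ], rec, K, per_particle)
  }, numeric(1))
  mean(errs)
}

#' Specificity error
#'
#' Mean distance (mm) from M randomly sampled model shapes to their nearest
#' training shape, where "nearest" minimises the same mean per-particle
#' distance that is reported.
#'
#' @param model a [fit_pca()] model.
#' @param corr the training `correspondence_set` or n_s x 3K matrix.
#' @param n_m number of modes used when sampling.
#' @param M number of random draws.
#' @param seed integer seed.
#' @param per_particle mean per-particle distance (default) or total norm.
#' @export
specificity <- function(model, corr, n_m, M = 1000L, seed = 1L,
                        per_particle = TRUE) {
  X <- if (inherits(corr, "correspondence_set")) correspondence_matrix(corr)
       else as.matrix(corr)
  n_m <- as.integer(n_m)
  M <- as.integer(M)
  if (M < 1L) stop_md("invalid-spec", "M must be >= 1")
  if (n_m < 1L || n_m > length(model$eigenvalues))
    stop_md("invalid-spec", "n_m out of range")
  V <- model$eigenvectors[, seq_len(n_m), drop = FALSE]
  sdv <- sqrt(model$eigenvalues[seq_len(n_m)])
  Z <- with_seed(seed, matrix(stats::rnorm(M * n_m), M, n_m))
  Y <- sweep(Z %*% (t(V) * sdv), 2, model$mean, `+`)
  if (per_particle) {
    D <- cpp_mean_particle_dist(Y, X, ncol(X) %/% 3L)
  } else {
    D <- outer(rowSums(Y^2), rowSums(X^2), `+`) - 2 * Y %*% t(X)
    D <- sqrt(pmax(D, 0))
  }
  mean(apply(D, 1L, min))
}

#' Metric curves for one dataset
#'
#' @param corr a `correspondence_set` (or matrix).
#' @param n_m_max largest mode count evaluated (capped at n_s - 2).
#' @param M specificity draws.
#' @param seed integer seed.
#' @return data.frame with columns `n_m`, `compactness_abs`,
#'   `compactness_norm`, `generalisation_mm`, `specificity_mm`.
#' @export
evaluation_curves <- function(corr, n_m_max = 15L, M = 250L, seed = 1L) {
  X <- if (inherits(corr, "correspondence_set")) correspondence_matrix(corr)
       else as.matrix(corr)
  model <- fit_pca(X)
  n_m_max <- min(as.integer(n_m_max), model$n_s - 2L)
  # one LOO sweep computing errors at every n_m (refit once per fold)
  K <- ncol(X) %/% 3L
  gen <- matrix(NA_real_, model$n_s, n_m_max)
  for (j in seq_len(model$n_s)) {
    fold <- fit_pca(X[-j, , drop = FALSE])
    centred <- X[j, ] - fold$mean
    coef <- crossprod(fold$eigenvectors, centred)
    for (m in seq_len(n_m_max)) {
      rec <- fold$mean + fold$eigenvectors[, seq_len(m), drop = FALSE] %*%
        coef[seq_len(m)]
      gen[j, m] <- shape_vec_dist(X[j, ], as.numeric(rec), K)
    }
  }
  data.frame(
    n_m = seq_len(n_m_max),
    compactness_abs = vapply(seq_len(n_m_max), function(m)
      compactness(model, m, normalized = FALSE), numeric(1)),
    compactness_norm = vapply(seq_len(n_m_max), function(m)
      compactness(model, m, normalized = TRUE), numeric(1)),
    generalisation_mm = colMeans(gen),
    specificity_mm = vapply(seq_len(n_m_max), function(m)
      specificity(model, X, m, M = M, seed = derive_seed(seed, 7L, m)),
      numeric(1))
  )
}

#' Evaluation suite across reduction levels
#'
#' Computes the metric curves for each level and the differences against the
#' reference level (R = 1) at matched n_m.
#'
#' @param corr_by_level named list of `correspondence_set`s (or matrices),
#'   names like "R1", "R4"; must contain the reference.
#' @param n_m_max,M,seed as in [evaluation_curves()].
#' @param reference name of the reference level (default "R1").
#' @return list with `curves` (named list of data.frames) and `diff`
#'   (data.frame of level, n_m, and metric differences vs the reference).
#' @export
evaluation_suite <- function(corr_by_level, n_m_max = 15L, M = 250L, seed = 1L,
                             reference = "R1") {
  if (!reference %in% names(corr_by_level))
    stop_md("invalid-spec", "reference level %s missing", reference)
  # one seed for every level: identical inputs give identical curves, so a
  # level differenced with itself is exactly zero
  curves <- lapply(corr_by_level, function(cl)
    evaluation_curves(cl, n_m_max = n_m_max, M = M,
                      seed = derive_seed(seed, 11L)))
  names(curves) <- names(corr_by_level)
  ref <- curves[[reference]]
  diffs <- do.call(rbind, lapply(names(curves), function(nm) {
    cur <- curves[[nm]]
    m <- min(nrow(cur), nrow(ref))
    data.frame(level = nm, n_m = cur$n_m[seq_len(m)],
               d_compactness_norm = cur$compactness_norm[seq_len(m)] -
                 ref$compactness_norm[seq_len(m)],
               d_generalisation_mm = cur$generalisation_mm[seq_len(m)] -
                 ref$generalisation_mm[seq_len(m)],
               d_specificity_mm = cur$specificity_mm[seq_len(m)] -
                 ref$specificity_mm[seq_len(m)])
  }))
  list(curves = curves, diff = diffs)
}
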