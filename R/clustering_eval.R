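# Unsupervised shape categorisation: retain the PCs covering a cumulative
# variance threshold, cluster the per-shape score vectors by complete-linkage
# agglomeration under correlation distance (anti-correlated score profiles --
# opposite macro-shapes -- are maximally distant), select the cluster count by
# the mean silhouette, and score the partition against reference labels with
# adjusted mutual information (AMI), whose chance correction uses the exact
# hypergeometric (permutation-model) expected mutual information.

#' Number of PCs covering a variance threshold
#'
#' Smallest n_m whose normalised compactness reaches `threshold`. When
#' `reference_n_m` is supplied (comparison datasets), that count is returned
#' instead, mirroring the use of the reference dataset's mode count for all
#' datasets under comparison.
#'
#' @param model a [fit_pca()] model.
#' @param threshold cumulative variance fraction, default 0.85.
#' @param reference_n_m optional externally fixed mode count.
#' @export
retain_pcs <- function(model, threshold = 0.85, reference_n_m = NULL) {
  if (!is.null(reference_n_m)) return(as.integer(reference_n_m))
  frac <- cumsum(model$eigenvalues) / sum(model$eigenvalues)
  as.integer(which(frac >= threshold - 1e-12)[1])
}

#' Correlation distance between two score vectors
#'
#' 1 - Pearson correlation; 0 for identical direction, 2 for perfect
#' anti-correlation.
#'
#' @param u,v numeric vectors of equal length >= 2, non-constant.
#' @export
correlation_distance <- function(u, v) {
  if (length(u) != length(v) || length(u) < 2L)
    stop_md("invalid-spec", "vectors must have equal length >= 2")
  if (stats::sd(u) == 0 || stats::sd(v) == 0)
    stop_md("undefined-correlation", "correlation distance of a constant vector")
  1 - stats::cor(u, v)
}

# full pairwise correlation-distance matrix of score rows
correlation_distance_matrix <- function(scores) {
  scores <- as.matrix(scores)
  if (any(apply(scores, 1, stats::sd) == 0))
    stop_md("undefined-correlation", "constant score vector in matrix")
  D <- 1 - stats::cor(t(scores))
  D[D < 0] <- 0   # numerical guard
  diag(D) <- 0
  D
}

#' Complete-linkage hierarchical clustering of shape scores
#'
#' Agglomerative merge sequence under correlation distance with
#' complete linkage (inter-cluster distance = maximum pairwise member
#' distance), which is monotone: merge heights never decrease.
#'
#' @param scores n x n_m matrix of per-shape PC scores (n >= 2).
#' @return an [stats::hclust] object with the distance matrix attached as
#'   attribute `"dmatrix"`.
#' @export
hierarchical_cluster <- function(scores) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 2L) stop_md("invalid-spec", "need >= 2 shapes")
  D <- correlation_distance_matrix(scores)
  hc <- stats::hclust(stats::as.dist(D), method = "complete")
  attr(hc, "dmatrix") <- D
  hc
}

#' Silhouette-based selection of the cluster count
#'
#' Cuts the dendrogram at each k in [k_min, k_max], computes the mean
#' silhouette width under the same correlation distance (singleton clusters
#' contribute 0), and returns the argmax; ties break toward smaller k.
#'
#' @param scores score matrix (used when `linkage` lacks its distance).
#' @param linkage result of [hierarchical_cluster()].
#' @param k_min,k_max search range; k_min >= 2, k_max < number of shapes.
#' @return list with `k`, `silhouette` and the per-k mean silhouettes.
#' @export
silhouette_select_k <- function(scores, linkage, k_min = 2L, k_max = 10L) {
  if (k_min < 2L) stop_md("invalid-spec", "k_min must be >= 2 (silhouette undefined at k = 1)")
  n <- length(linkage$order)
  k_max <- min(as.integer(k_max), n - 1L)
  if (k_max < k_min) stop_md("invalid-spec", "k_max < k_min after capping at n - 1")
  D <- attr(linkage, "dmatrix")
  if (is.null(D)) D <- correlation_distance_matrix(scores)
  ks <- k_min:k_max
  sil <- vapply(ks, function(k) {
    cl <- stats::cutree(linkage, k = k)
    mean(cluster::silhouette(cl, dmatrix = D)[, "sil_width"])
  }, numeric(1))
  best <- which.max(sil)  # first max: ties toward smaller k
  list(k = ks[best], silhouette = sil[best],
       by_k = data.frame(k = ks, mean_silhouette = sil))
}

#' Adjusted mutual information between two partitions
#'
#' MI and entropies from the contingency table (natural log), chance
#' correction by the exact permutation-model (hypergeometric) expected MI,
#' normaliser the arithmetic mean of the entropies:
#' AMI = (MI - E\[MI\]) / (mean(H(U), H(V)) - E\[MI\]).
#' If both partitions are single-class the partitions are identical and the
#' value is 1 by convention.
#'
#' @param U,V label vectors of equal length >= 2 (any atomic type).
#' @export
ami <- function(U, V) {
  if (length(U) != length(V) || length(U) < 2L)
    stop_md("invalid-spec", "label vectors must have equal length >= 2")
  tab <- table(U, V)
  n <- sum(tab)
  a <- rowSums(tab)
  b <- colSums(tab)
  Hu <- -sum(ifelse(a > 0, (a / n) * log(a / n), 0))
  Hv <- -sum(ifelse(b > 0, (b / n) * log(b / n), 0))
  if (Hu == 0 && Hv == 0) return(1.0)   # both single-class: identical partitions
  # terms are summed in sorted order so ami(U, V) == ami(V, U) bit-exactly
  mi_terms <- c()
  for (i in seq_along(a)) for (j in seq_along(b)) {
    nij <- tab[i, j]
    if (nij > 0) mi_terms <- c(mi_terms, (nij / n) * log(n * nij / (a[i] * b[j])))
  }
  mi <- sum(sort(mi_terms))
  emi <- expected_mi(a, b, n)
  denom <- (Hu + Hv) / 2 - emi
  if (abs(denom) < 1e-15) return(if (abs(mi - emi) < 1e-15) 0.0 else 1.0)
  as.numeric((mi - emi) / denom)
}

# Exact E[MI] under the permutation model: the count n_ij in cell (i, j) is
# hypergeometric with a_i draws from b_j successes out of n.
expected_mi <- function(a, b, n) {
  terms <- c()
  for (ai in a) for (bj in b) {
    lo <- max(1L, ai + bj - n)
    hi <- min(ai, bj)
    if (hi < lo) next
    nij <- lo:hi
    p <- stats::dhyper(nij, bj, n - bj, ai)
    terms <- c(terms, p * (nij / n) * log(n * nij / (ai * bj)))
  }
  sum(sort(terms))
}

#' Cluster a shape model's scores and score against reference labels
#'
#' Runs [retain_pcs()], [hierarchical_cluster()], [silhouette_select_k()],
#' cuts the dendrogram, and computes [ami()] against `labels`. Also reports
#' cluster sizes and a stability check: whether the 0.90 and 0.95 variance
#' thresholds yield the identical partition (up to renaming) as the main one.
#'
#' @param model a [fit_pca()] model.
#' @param labels reference labels, one per shape.
#' @param reference_n_m optional externally fixed retained-PC count.
#' @param threshold variance threshold for [retain_pcs()].
#' @param k_min,k_max silhouette search range.
#' @return object of class `clustering_result`: list with `n_m`, `k`,
#'   `silhouette`, `ami`, `cluster_labels`, `cluster_sizes`, `stable`,
#'   `linkage`.
#' @export
cluster_and_score <- function(model, labels, reference_n_m = NULL,
                              threshold = 0.85, k_min = 2L, k_max = 10L) {
  if (length(labels) != model$n_s)
    stop_md("invalid-spec", "labels must cover all %d shapes", model$n_s)
  run_at <- function(n_m) {
    sc <- model$scores[, seq_len(n_m), drop = FALSE]
    hc <- hierarchical_cluster(sc)
    sel <- silhouette_select_k(sc, hc, k_min, k_max)
    cl <- stats::cutree(hc, k = sel$k)
    list(hc = hc, sel = sel, cl = cl)
  }
  n_m <- retain_pcs(model, threshold, reference_n_m)
  # correlation distance needs score vectors of length >= 2
  n_m <- max(2L, min(n_m, length(model$eigenvalues)))
  main <- run_at(n_m)
  same_partition <- function(x, y) isTRUE(all.equal(ami(x, y), 1.0, tolerance = 1e-9))
  stable <- all(vapply(c(0.90, 0.95), function(th) {
    alt <- run_at(max(2L, min(retain_pcs(model, th), length(model$eigenvalues))))
    same_partition(alt$cl, main$cl)
  }, logical(1)))
  structure(list(
    n_m = n_m,
    variance_covered = compactness(model, n_m, normalized = TRUE),
    k = main$sel$k,
    silhouette = main$sel$silhouette,
    ami = ami(main$cl, labels),
    cluster_labels = as.integer(main$cl),
    cluster_sizes = as.integer(table(main$cl)),
    stable = stable,
    linkage = main$hc
  ), class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf(
    "clustering: %d PCs (%.1f%% var), k = %d (silhouette %.3f), AMI = %.4f, sizes: %s%s\n",
    x$n_m, 100 * x$variance_covered, x$k, x$silhouette, x$ami,
    paste(x$cluster_sizes, collapse = "/"),
    if (x$stable) ", stable at 90/95%" else ""))
  invisible(x)
}
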