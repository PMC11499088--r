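test_that("retain_pcs applies the variance threshold or a reference count", {
  model <- structure(list(eigenvalues = c(0.6, 0.3, 0.1)), class = "shape_model")
  expect_equal(retain_pcs(model, 0.85), 2L)
  expect_equal(retain_pcs(model, 1.0), 3L)
  expect_equal(retain_pcs(model, 0.85, reference_n_m = 10L), 10L)
})

test_that("correlation distance follows the Pearson formula", {
  u <- c(1, 2, 3)
  expect_equal(correlation_distance(u, u), 0)
  expect_equal(correlation_distance(u, -u + 4), 2)
  expect_equal(correlation_distance(u, c(1, 3, 2)), 0.5)   # r = 0.5
  expect_error(correlation_distance(u, c(1, 1, 1)),
               class = "morphodetail_undefined_correlation")
  expect_error(correlation_distance(u, c(1, 2)), class = "morphodetail_invalid_spec")
})

test_that("complete linkage is monotone and matches brute-force agglomeration", {
  # duplicate rows merge first at height zero
  set.seed(3)
  S <- matrix(stats::rnorm(40), 8, 5)
  S[2, ] <- S[1, ]
  hc <- hierarchical_cluster(S)
  expect_equal(hc$height[1], 0, tolerance = 1e-12)
  expect_setequal(abs(hc$merge[1, ]), c(1, 2))
  # monotone merge heights
  expect_true(all(diff(hc$height) >= -1e-12))

  # post-hoc: each merge height equals the true max pairwise distance of the
  # merged clusters
  D <- morphodetail:::correlation_distance_matrix(S)
  members <- lapply(1:8, identity)
  for (step in seq_len(nrow(hc$merge))) {
    pick <- function(id) if (id < 0) -id else unlist(members[[8 + id]])
    a <- pick(hc$merge[step, 1])
    b <- pick(hc$merge[step, 2])
    expect_equal(hc$height[step], max(D[a, b]), tolerance = 1e-10)
    members[[8 + step]] <- c(a, b)
  }

  # brute-force agglomeration oracle reproduces the flat partitions
  brute_complete <- function(D, k_target) {
    cl <- as.list(seq_len(nrow(D)))
    while (length(cl) > k_target) {
      best <- c(Inf, 0, 0)
      for (i in seq_along(cl)) for (j in seq_len(i - 1)) {
        h <- max(D[cl[[i]], cl[[j]]])
        if (h < best[1]) best <- c(h, j, i)
      }
      cl[[best[2]]] <- c(cl[[best[2]]], cl[[best[3]]])
      cl[[best[3]]] <- NULL
    }
    lab <- integer(nrow(D))
    for (i in seq_along(cl)) lab[cl[[i]]] <- i
    lab
  }
  set.seed(17)
  S12 <- matrix(stats::rnorm(12 * 6), 12, 6)
  hc12 <- hierarchical_cluster(S12)
  D12 <- morphodetail:::correlation_distance_matrix(S12)
  for (k in c(2, 3, 5))
    expect_equal(ami(stats::cutree(hc12, k), brute_complete(D12, k)), 1.0,
                 tolerance = 1e-12)
})

test_that("within-blob merges happen before across-blob merges", {
  set.seed(5)
  blob <- function(center, n) sweep(matrix(stats::rnorm(n * 4, sd = 0.05), n, 4),
                                    2, center, `+`)
  S <- rbind(blob(c(1, 2, 3, 4), 3), blob(c(4, 3, 2, 1), 3))
  hc <- hierarchical_cluster(S)
  # the four lowest merges are within-blob: they only involve members of one
  # blob each (blob 1 = shapes 1-3, blob 2 = shapes 4-6)
  members <- lapply(1:6, identity)
  for (step in 1:4) {
    pick <- function(id) if (id < 0) -id else members[[6 + id]]
    joined <- c(pick(hc$merge[step, 1]), pick(hc$merge[step, 2]))
    expect_true(all(joined <= 3) || all(joined >= 4))
    members[[6 + step]] <- joined
  }
  groups <- stats::cutree(hc, 2)
  expect_equal(length(unique(groups[1:3])), 1L)
  expect_equal(length(unique(groups[4:6])), 1L)
  expect_true(all(groups[1:3] != groups[4]))
})

test_that("silhouette selects the constructed number of blobs", {
  set.seed(7)
  blob <- function(center, n) sweep(matrix(stats::rnorm(n * 6, sd = 0.1), n, 6),
                                    2, center, `+`)
  c1 <- stats::rnorm(6) * 3
  c2 <- -c1
  S2 <- rbind(blob(c1, 20), blob(c2, 20))
  hc2 <- hierarchical_cluster(S2)
  sel2 <- silhouette_select_k(S2, hc2)
  expect_equal(sel2$k, 2L)
  expect_true(all(sel2$by_k$mean_silhouette >= -1 & sel2$by_k$mean_silhouette <= 1))

  c3 <- stats::rnorm(6) * 4
  S3 <- rbind(blob(c1, 13), blob(c2, 13), blob(c3, 13))
  hc3 <- hierarchical_cluster(S3)
  expect_equal(silhouette_select_k(S3, hc3)$k, 3L)

  expect_error(silhouette_select_k(S2, hc2, k_min = 1L),
               class = "morphodetail_invalid_spec")
})

test_that("AMI is exact against a brute-force hypergeometric oracle", {
  # log-factorial form of the permutation-model expectation, summed directly
  emi_oracle <- function(a, b, n) {
    total <- 0
    for (i in seq_along(a)) for (j in seq_along(b)) {
      for (nij in max(1, a[i] + b[j] - n):min(a[i], b[j])) {
        if (nij < 1) next
        logp <- lgamma(a[i] + 1) - lgamma(nij + 1) - lgamma(a[i] - nij + 1) +
          lgamma(n - a[i] + 1) - lgamma(b[j] - nij + 1) -
          lgamma(n - a[i] - b[j] + nij + 1) - (lgamma(n + 1) - lgamma(b[j] + 1) -
          lgamma(n - b[j] + 1))
        total <- total + exp(logp) * (nij / n) * log(n * nij / (a[i] * b[j]))
      }
    }
    total
  }
  ami_oracle <- function(U, V) {
    tab <- table(U, V)
    n <- sum(tab)
    a <- rowSums(tab); b <- colSums(tab)
    Hu <- -sum((a / n) * log(a / n))
    Hv <- -sum((b / n) * log(b / n))
    mi <- 0
    for (i in seq_along(a)) for (j in seq_along(b))
      if (tab[i, j] > 0)
        mi <- mi + tab[i, j] / n * log(n * tab[i, j] / (a[i] * b[j]))
    (mi - emi_oracle(a, b, n)) / ((Hu + Hv) / 2 - emi_oracle(a, b, n))
  }
  set.seed(11)
  for (rep in 1:8) {
    U <- sample(1:4, 60, replace = TRUE)
    V <- sample(1:4, 60, replace = TRUE)
    expect_lt(abs(ami(U, V) - ami_oracle(U, V)), 1e-10)
  }
})

test_that("AMI has the similarity-measure properties", {
  U <- c(1, 1, 2, 2, 3, 3, 1, 2)
  expect_equal(ami(U, U), 1.0)
  # invariance to class renaming
  expect_equal(ami(U, c("b", "b", "c", "c", "a", "a", "b", "c")), 1.0)
  # symmetry
  set.seed(2)
  V <- sample(1:3, 8, replace = TRUE)
  expect_identical(ami(U, V), ami(V, U))
  expect_lte(ami(U, V), 1)
  # single-class degenerate convention
  expect_equal(ami(rep(1, 5), rep("x", 5)), 1.0)
  # chance adjustment: independent labels score near zero
  vals <- vapply(1:20, function(s) {
    set.seed(s)
    ami(sample(0:1, 1000, replace = TRUE), sample(0:1, 1000, replace = TRUE))
  }, numeric(1))
  expect_true(all(abs(vals) < 0.05))
})

test_that("cluster_and_score recovers planted structure and reports stability", {
  set.seed(13)
  n <- 30
  lab <- rep(c("A", "B"), each = n / 2)
  dir1 <- stats::rnorm(20)
  scores <- rbind(
    matrix(stats::rnorm(n / 2 * 20, sd = 0.2), n / 2, 20) + rep(dir1 * 2, each = n / 2),
    matrix(stats::rnorm(n / 2 * 20, sd = 0.2), n / 2, 20) - rep(dir1 * 2, each = n / 2))
  model <- fit_pca(scores)
  res <- cluster_and_score(model, lab)
  expect_equal(res$k, 2L)
  expect_equal(res$ami, 1.0, tolerance = 1e-9)
  expect_true(res$stable)
  expect_equal(sort(res$cluster_sizes), c(15L, 15L))
  expect_error(cluster_and_score(model, lab[-1]), class = "morphodetail_invalid_spec")
})
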