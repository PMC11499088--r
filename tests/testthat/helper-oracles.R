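# Independent brute-force oracles used by both the module tests and the
# acceptance suite. These deliberately avoid the package's computational
# paths: direct dense eigensolvers, naive loops, and log-factorial
# hypergeometric sums.

# exact E[MI] under the permutation model via log-factorials
oracle_emi <- function(a, b, n) {
  total <- 0
  for (i in seq_along(a)) for (j in seq_along(b)) {
    for (nij in max(1, a[i] + b[j] - n):min(a[i], b[j])) {
      if (nij < 1) next
      logp <- lgamma(a[i] + 1) - lgamma(nij + 1) - lgamma(a[i] - nij + 1) +
        lgamma(n - a[i] + 1) - lgamma(b[j] - nij + 1) -
        lgamma(n - a[i] - b[j] + nij + 1) -
        (lgamma(n + 1) - lgamma(b[j] + 1) - lgamma(n - b[j] + 1))
      total <- total + exp(logp) * (nij / n) * log(n * nij / (a[i] * b[j]))
    }
  }
  total
}

oracle_ami <- function(U, V) {
  tab <- table(U, V)
  n <- sum(tab)
  a <- rowSums(tab)
  b <- colSums(tab)
  Hu <- -sum((a / n) * log(a / n))
  Hv <- -sum((b / n) * log(b / n))
  mi <- 0
  for (i in seq_along(a)) for (j in seq_along(b))
    if (tab[i, j] > 0)
      mi <- mi + tab[i, j] / n * log(n * tab[i, j] / (a[i] * b[j]))
  emi <- oracle_emi(a, b, n)
  (mi - emi) / ((Hu + Hv) / 2 - emi)
}

# mean per-particle distance between two flattened shape vectors
oracle_particle_dist <- function(x, y) {
  d <- matrix(x - y, nrow = 3)
  mean(sqrt(colSums(d^2)))
}

# naive leave-one-out generalisation via a dense eigensolver
oracle_generalisation <- function(X, n_m) {
  mean(vapply(seq_len(nrow(X)), function(j) {
    Xt <- X[-j, , drop = FALSE]
    mu <- colMeans(Xt)
    ev <- eigen(stats::cov(Xt), symmetric = TRUE)$vectors[, seq_len(n_m), drop = FALSE]
    rec <- mu + ev %*% crossprod(ev, X[j, ] - mu)
    oracle_particle_dist(X[j, ], rec)
  }, numeric(1)))
}
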