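# Fixture builders shared across test files; everything is generated in code.

unit_cube <- function() {
  v <- as.matrix(expand.grid(c(0, 1), c(0, 1), c(0, 1)))
  dimnames(v) <- NULL
  f <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
             c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
             c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  trimesh(v, f)
}

# icosphere by midpoint subdivision
icosphere <- function(r = 1, sub = 3) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(sub)) {
    env <- new.env()
    vlist <- lapply(seq_len(nrow(v)), function(j) v[j, ])
    mid <- function(a, b) {
      k <- paste(min(a, b), max(a, b))
      if (!is.null(env[[k]])) return(env[[k]])
      m <- (vlist[[a]] + vlist[[b]]) / 2
      m <- m / sqrt(sum(m^2))
      vlist[[length(vlist) + 1]] <<- m
      env[[k]] <- length(vlist)
      length(vlist)
    }
    newf <- vector("list", nrow(f) * 4)
    ct <- 0
    for (t_ in seq_len(nrow(f))) {
      a <- f[t_, 1]; b <- f[t_, 2]; c_ <- f[t_, 3]
      ab <- mid(a, b); bc <- mid(b, c_); ca <- mid(c_, a)
      newf[[ct + 1]] <- c(a, ab, ca)
      newf[[ct + 2]] <- c(b, bc, ab)
      newf[[ct + 3]] <- c(c_, ca, bc)
      newf[[ct + 4]] <- c(ab, bc, ca)
      ct <- ct + 4
    }
    f <- do.call(rbind, newf)
    v <- do.call(rbind, vlist)
  }
  trimesh(v * r, f)
}

random_rotation <- function(seed, max_angle = pi) {
  set.seed(seed)
  axis <- stats::rnorm(3)
  axis <- axis / sqrt(sum(axis^2))
  ang <- stats::runif(1, 0, max_angle)
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
}

# fast small anatomy (coarse mesh) for registration/correspondence tests
quick_anatomy <- function(seed, bend = 60, detail = 0.4, res = 1.3) {
  normalize_volume(generate_shape(anatomy_spec(
    bend_angle = bend, detail_amplitude = detail, mesh_resolution = res,
    seed = seed)))
}

# random correspondence matrix: n shapes x 3K coordinates
random_corr_matrix <- function(n, K, seed, sd = 1) {
  set.seed(seed)
  base <- matrix(stats::rnorm(3 * K), n, 3 * K, byrow = TRUE)
  base + matrix(stats::rnorm(n * 3 * K, sd = sd), n, 3 * K)
}
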