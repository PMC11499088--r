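# Classed conditions shared by all modules. Every domain failure signals a
# condition of class "morphodetail_<id>" so callers can distinguish, e.g.,
# an unreadable file (format-error) from a topologically broken mesh
# (invalid-mesh).

stop_md <- function(id, msg, ...) {
  stop(structure(
    class = c(paste0("morphodetail_", gsub("-", "_", id)), "morphodetail_error",
              "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

warn_md <- function(id, msg, ...) {
  warning(structure(
    class = c(paste0("morphodetail_", gsub("-", "_", id)), "morphodetail_warning",
              "warning", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All stochastic steps in the package
# draw through this so no global state leaks between stages.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

# Deterministic substream seeds: fold a master seed and integer tags into a
# 31-bit seed with a Weyl-style mixing step (no global RNG involved).
derive_seed <- function(master, ...) {
  tags <- c(as.numeric(master), vapply(list(...), as.numeric, numeric(1)))
  h <- 0
  for (t in tags) h <- (h * 69069 + (t %% 2147483647) + 1013904223) %% 2147483647
  as.integer(h %% 2147483629 + 1)
}
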