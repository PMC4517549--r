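# Build a volume from a plain value vector (default: Nx1x1 grid).
vol3 <- function(values, dims = c(length(values), 1, 1), ...) {
  volume(array(values, dims), ...)
}

# Independent Rayleigh sampler (inverse-CDF), for noise-estimator oracles.
r_rayleigh <- function(n, sigma) sigma * sqrt(-2 * log(1 - runif(n)))

# Literal scalar transcription of the two-segment mean-anchored mapping with
# ceiling: the independent oracle for apply_map.
oracle_two_segment <- function(g, il, rl, apply_ceiling = TRUE) {
  vapply(g, function(gi) {
    y <- if (gi <= il$mean_val)
      rl$mean_val + (gi - il$mean_val) * (rl$low - rl$mean_val) / (il$low - il$mean_val)
    else
      rl$mean_val + (gi - il$mean_val) * (rl$high - rl$mean_val) / (il$high - il$mean_val)
    if (apply_ceiling) ceiling(y) else y
  }, numeric(1))
}

# Random strictly-ordered landmark set on an arbitrary gray range.
random_landmarks <- function(lo = 0, hi = 200) {
  repeat {
    v <- sort(runif(5, lo, hi))
    if (all(diff(v) > 1e-3))
      return(landmark_set(v[2], v[3], v[4], v[1], v[5]))
  }
}

# Small, fast phantom for unit tests (acceptance-style tests use defaults).
small_spec <- function(seed = 1, shape = c(48, 48, 48), ...) {
  phantom_spec(shape = shape, seed = seed, ...)
}

strip_attrs <- function(x) {
  attributes(x) <- NULL
  x
}
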