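# Shared fixture builders.  All fixtures are generated in code; no
# binary files ship with the package.

# Small 4D volume whose voxels each carry an independent random series.
random_volume <- function(dims = c(6, 5, 4), nt = 40, tr = 2, seed = 1,
                          voxel = c(3, 3, 3.5)) {
  set.seed(seed)
  volume4d(array(rnorm(prod(dims) * nt), dim = c(dims, nt)),
           voxel_size = voxel, tr = tr)
}

random_mask <- function(dims = c(6, 5, 4), p = 0.4, seed = 2,
                        voxel = c(3, 3, 3.5)) {
  set.seed(seed)
  repeat {
    m <- array(rbinom(prod(dims), 1, p), dim = dims)
    if (any(m != 0)) break
  }
  mask_volume(m, voxel)
}

# Volume where every voxel carries `series` exactly (no noise).
constant_signal_volume <- function(series, dims = c(4, 4, 3), tr = 2) {
  nt <- length(series)
  arr <- array(rep(series, each = prod(dims)), dim = c(dims, nt))
  volume4d(arr, voxel_size = c(3, 3, 3), tr = tr)
}

# Naive shift-slice-Pearson oracle for the lagged cross-correlation.
oracle_xcorr <- function(g, c, max_lag_s, dt) {
  K <- round(max_lag_s / dt)
  n <- min(length(g), length(c))
  g <- g[seq_len(n)]; c <- c[seq_len(n)]
  sapply((-K):K, function(k) {
    gs <- numeric(0); cs <- numeric(0)
    for (t in seq_len(n)) {          # literal definition: pair g[t+k], c[t]
      if (t + k >= 1 && t + k <= n) {
        gs <- c(gs, g[t + k]); cs <- c(cs, c[t])
      }
    }
    cor(gs, cs)
  })
}

# A tiny cohort config that keeps unit tests fast.
tiny_synthetic_config <- function(...) {
  synthetic_config(n_bqd = 3, n_hc = 3, n_volumes = 64,
                   grid_dim = c(8, 8, 4), seed = 42, ...)
}
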