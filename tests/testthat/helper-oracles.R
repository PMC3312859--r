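# Independent reference implementations used as oracles. These are kept
# deliberately naive (explicit loops, dense algebra) and separate from the
# package code paths they check.

# Brute-force cluster classification: loops over every coarse site and its
# neighbourhood, no vectorisation shared with classify_clusters().
oracle_classify <- function(occ, r) {
  nl <- ceiling(dim(occ) / r)
  dense <- matrix(FALSE, nl[1], nl[2])
  counts <- matrix(0L, nl[1], nl[2])
  for (i in seq_len(nl[1])) {
    for (j in seq_len(nl[2])) {
      rows <- ((i - 1) * r + 1):min(i * r, nrow(occ))
      cols <- ((j - 1) * r + 1):min(j * r, ncol(occ))
      blk <- occ[rows, cols, drop = FALSE]
      counts[i, j] <- sum(blk != 0)
      dense[i, j] <- all(blk != 0)
    }
  }
  labels <- matrix("empty", nl[1], nl[2])
  for (i in seq_len(nl[1])) {
    for (j in seq_len(nl[2])) {
      if (counts[i, j] == 0) next
      homog <- dense[i, j]
      if (homog) {
        for (di in -1:1) {
          for (dj in -1:1) {
            if (di == 0 && dj == 0) next
            ii <- i + di; jj <- j + dj
            if (ii < 1 || ii > nl[1] || jj < 1 || jj > nl[2] ||
                  !dense[ii, jj]) {
              homog <- FALSE
            }
          }
        }
      }
      labels[i, j] <- if (homog) "homogeneous" else "heterogeneous"
    }
  }
  list(counts = counts, dense = dense, labels = labels)
}

# One classical RK4 step in plain R, built on the package's derivative
# function only (the compiled kernel hardcodes its own copy of the rhs).
oracle_rk4_step <- function(x, params, h) {
  f <- function(v) unname(pathway_derivatives(pathway_state(
    v[1], v[2], v[3], v[4], v[5], v[6], v[7], v[8], v[9], v[10], v[11]),
    params))
  k1 <- f(x)
  k2 <- f(x + h / 2 * k1)
  k3 <- f(x + h / 2 * k2)
  k4 <- f(x + h * k3)
  x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

# Dense LU solve of a tridiagonal system via base solve().
oracle_tridiag_dense <- function(sub, dg, sup, rhs) {
  n <- length(dg)
  A <- diag(dg)
  for (i in seq_len(n - 1)) {
    A[i + 1, i] <- sub[i]
    A[i, i + 1] <- sup[i]
  }
  as.numeric(solve(A, rhs))
}

# Brute-force crossing scan with an explicit loop.
oracle_crossings <- function(prolif, migr) {
  d <- prolif - migr
  out <- integer(0)
  for (t in 2:length(d)) {
    if (sign(d[t]) != sign(d[t - 1]) || d[t] == 0) out <- c(out, t)
  }
  out
}

# Small default config for fast engine tests.
small_config <- function(steps = 15, ...) {
  gbm_config(steps = steps, replicates = 1,
             lattice = list(shape_high = c(60L, 60L)),
             init = list(tumor_radius = 3), ...)
}

run_steps <- function(cfg, n = cfg$steps, seed = cfg$seed) {
  sim <- gbm_init(cfg, seed = seed)
  for (i in seq_len(n)) gbm_step(sim)
  sim
}
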