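test_that("Thomas solve matches direct substitution and a dense oracle", {
  # identity system returns the rhs
  expect_equal(thomas_solve(c(0, 0), c(1, 1, 1), c(0, 0), c(3, -2, 7)),
               c(3, -2, 7))
  # classic -1/2/-1 Laplacian system
  expect_equal(thomas_solve(c(-1, -1), c(2, 2, 2), c(-1, -1), c(1, 0, 1)),
               c(1, 1, 1))
  # random diagonally dominant systems vs dense LU
  set.seed(7)
  for (rep in 1:5) {
    n <- 50
    sub <- runif(n - 1, -1, 1)
    sup <- runif(n - 1, -1, 1)
    dg <- abs(c(0, sub)) + abs(c(sup, 0)) + runif(n, 0.5, 2)
    rhs <- rnorm(n)
    expect_equal(thomas_solve(sub, dg, sup, rhs),
                 oracle_tridiag_dense(sub, dg, sup, rhs), tolerance = 1e-10)
  }
  expect_error(thomas_solve(c(0, 0), c(0, 1, 1), c(0, 0), c(1, 1, 1)),
               "pivot")
  expect_warning(thomas_solve(c(-3, -3), c(1, 1, 1), c(-3, -3), c(1, 1, 1)),
                 "dominant")
})

test_that("a uniform field is a steady state of the zero-flux ADI step", {
  f <- chemo_field(c(32, 32), Y = 2)
  f2 <- adi_step(f, dt = 300)
  expect_lt(max(abs(f2$Y - 2)), 1e-13)
  expect_identical(f2$n_clamped, 0L)
  f$Y[5, 5] <- NaN
  expect_error(adi_step(f, 1), "non-finite")
})

test_that("total mass is conserved under zero-flux with no sources", {
  Y0 <- make_fixture(fixture_spec("gaussian-field", shape = c(64, 64),
                                  peak = 5, width = 6))
  f <- chemo_field(Y0)
  m0 <- sum(f$Y) * f$dx^2
  for (i in 1:10) f <- adi_step(f, 200)
  expect_lt(abs(sum(f$Y) * f$dx^2 - m0) / m0, 1e-10)
  expect_identical(f$n_clamped, 0L)
})

test_that("the Dirichlet sine eigenmode decays at the analytic rate", {
  n <- 63
  D <- 1e-7
  dx <- 10
  Y0 <- make_fixture(fixture_spec("sine-field", shape = c(n, n)))
  L <- (n + 1) * dx
  f <- chemo_field(Y0, D = D, dx = dx)
  tend <- 8000
  for (i in 1:40) f <- adi_step(f, tend / 40, bc = "dirichlet-zero")
  ana <- exp(-2 * (D * 1e8) * pi^2 * tend / L^2)
  expect_lt(abs(max(f$Y) / max(Y0) / ana - 1), 0.01)
})

test_that("the spatial error drops about fourfold when dx halves", {
  D <- 1e-7
  decay_err <- function(n, dx) {
    Y0 <- make_fixture(fixture_spec("sine-field", shape = c(n, n)))
    L <- (n + 1) * dx
    f <- chemo_field(Y0, D = D, dx = dx)
    tend <- 8000
    for (i in 1:160) f <- adi_step(f, tend / 160, bc = "dirichlet-zero")
    abs(max(f$Y) / max(Y0) / exp(-2 * (D * 1e8) * pi^2 * tend / L^2) - 1)
  }
  ratio <- decay_err(63, 20) / decay_err(127, 10)
  expect_gt(ratio, 3)
  expect_lt(ratio, 5.5)
})

test_that("source terms enter each half step and can trigger counted clamping", {
  f <- chemo_field(c(16, 16), Y = 1)
  f$S <- matrix(0.01, 16, 16)
  f2 <- adi_step(f, dt = 100)
  # uniform secretion on a uniform field: exact increment S*dt
  expect_equal(unique(round(as.numeric(f2$Y), 12)), 2)
  f$S[] <- 0
  f$U <- matrix(1, 16, 16)  # uptake overdraws the pool
  expect_warning(f3 <- adi_step(f, dt = 100), "clamped")
  expect_true(all(f3$Y >= 0))
  expect_gt(f3$n_clamped, 0)
})

test_that("deposit_sources splits per-cell and aggregated contributions", {
  f <- chemo_field(c(12, 12), Y = 2, dx = 10)
  # no cells: empty maps
  f0 <- deposit_sources(f, data.frame(x = integer(0), y = integer(0)))
  expect_true(all(f0$U == 0) && all(f0$S == 0))
  # one heterogeneous cell: a point source at its node
  f1 <- deposit_sources(f, data.frame(x = 5, y = 7), NULL,
                        secretion = 0.05, uptake_rate = 0.001)
  expect_equal(f1$S[5, 7], 0.05)
  expect_equal(sum(f1$S != 0), 1L)
  expect_equal(f1$U[5, 7], 0.001 * 2)
  # a homogeneous 2x2-site cluster aggregates as one big cell
  L <- dual_lattice(c(12, 12), r = 2)
  L$occ[] <- seq_len(144)  # fully occupied: interior sites homogeneous
  cm <- classify_clusters(L)
  cells <- data.frame(x = rep(1:12, 12), y = rep(1:12, each = 12))
  fh <- deposit_sources(f, cells, cm, secretion = 0.05, uptake_rate = 0.001)
  # interior homogeneous site (3,3) covers nodes 5:6 x 5:6, 4 cells
  expect_equal(fh$S[5, 5], 4 * 0.05 / 4)
  # uniform field: aggregated uptake equals the per-cell value
  expect_equal(fh$U[5, 5], 0.001 * 2)
  # totals match per-cell deposition on a uniform field
  fpc <- deposit_sources(f, cells, NULL, secretion = 0.05,
                         uptake_rate = 0.001)
  expect_equal(sum(fh$S), sum(fpc$S), tolerance = 1e-12)
  expect_equal(sum(fh$U), sum(fpc$U), tolerance = 1e-12)
  expect_error(deposit_sources(f, data.frame(x = 99, y = 1)), "off the lattice")
})
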