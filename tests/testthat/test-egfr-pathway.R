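test_that("reaction velocities match the kinetic scheme at reference states", {
  p <- egfr_kinetics()
  # default initial state: only ligand-receptor binding is active
  v <- reaction_rates(pathway_state(), p)
  expect_equal(unname(v["v1"]), 0.003 * 9010.55 * 100)
  expect_equal(unname(v[c("v2", "v3", "v4", "v5", "v6", "v7", "v8", "v9")]),
               rep(0, 8))
  # the zero state is a fixed point of mass action
  zero <- pathway_state(X0 = 0, X1 = 0, X2 = 0, X6 = 0)
  expect_equal(unname(reaction_rates(zero, p)), rep(0, 9))
  # Michaelis-Menten dephosphorylation of the receptor dimer
  s5 <- pathway_state(X0 = 0, X1 = 0, X2 = 0, X5 = 50, X6 = 0)
  expect_equal(unname(reaction_rates(s5, p)["v4"]), 450 * 50 / (50 + 50))
  expect_error(pathway_state(X1 = -1), "nonnegative")
})

test_that("derivatives follow the stoichiometry and conserve every moiety", {
  p <- egfr_kinetics()
  d <- pathway_derivatives(pathway_state(), p)
  v1 <- 0.003 * 9010.55 * 100
  expect_equal(unname(d[c("dX1", "dX2", "dX3")]), c(-v1, -v1, v1))
  expect_equal(unname(d[c("dX0", "dX4", "dX5", "dX6", "dX7", "dX8", "dX9",
                          "dX10")]), rep(0, 8))
  # moiety-weighted derivative sums vanish identically for random states
  w_egfr <- c(0, 0, 1, 1, 2, 2, 0, 2, 2, 0, 0)
  w_plcg <- c(0, 0, 0, 0, 0, 0, 1, 1, 1, 1, 1)
  w_tgfa <- c(0, 1, 0, 1, 2, 2, 0, 2, 2, 0, 0)
  set.seed(42)
  for (i in 1:25) {
    x <- runif(11, 0, 100)
    st <- do.call(pathway_state, as.list(setNames(x, names(formals(pathway_state))[1:11])))
    dv <- unname(pathway_derivatives(st, p))
    scale <- max(abs(dv), 1)
    expect_lt(abs(sum(w_egfr * dv)) / scale, 1e-12)
    expect_lt(abs(sum(w_plcg * dv)) / scale, 1e-12)
    expect_lt(abs(sum(w_tgfa * dv)) / scale, 1e-12)
  }
})

test_that("compiled RK4 kernel agrees with an R-level RK4 step", {
  p <- egfr_kinetics()
  x0 <- as.numeric(unclass(pathway_state()))
  ref <- oracle_rk4_step(x0, p, 0.01)
  got <- as.numeric(unclass(integrate_pathway(pathway_state(), p, 0.01, 0.01)))
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("integration conserves moieties and is partition-independent", {
  p <- egfr_kinetics()
  s <- integrate_pathway(pathway_state(), p, 400, 0.01)
  mt <- moiety_totals(s)
  expect_equal(unname(mt), c(100, 10, 9010.55), tolerance = 1e-9)
  # splitting the duration into calls changes nothing (fixed-step contract)
  s_split <- pathway_state()
  for (k in 1:4) s_split <- integrate_pathway(s_split, p, 100, 0.01)
  expect_identical(as.numeric(unclass(s)), as.numeric(unclass(s_split)))
  expect_equal(attr(s, "t"), 400)
  # duration zero is the identity
  expect_identical(as.numeric(unclass(integrate_pathway(pathway_state(), p, 0, 0.01))),
                   as.numeric(unclass(pathway_state())))
  # non-commensurate duration/dt is refused rather than silently truncated
  expect_error(integrate_pathway(pathway_state(), p, 1.005, 0.01), "multiple")
})

test_that("integrator agrees with an adaptive stiff solver", {
  skip_if_not_installed("deSolve")
  p <- egfr_kinetics()
  rhs <- function(t, y, parms) {
    st <- do.call(pathway_state,
                  as.list(setNames(y, names(formals(pathway_state))[1:11])))
    list(unname(pathway_derivatives(st, p)))
  }
  ref <- deSolve::lsoda(as.numeric(unclass(pathway_state())), c(0, 200), rhs,
                        NULL, rtol = 1e-10, atol = 1e-10)
  got <- as.numeric(unclass(integrate_pathway(pathway_state(), p, 200, 0.01)))
  expect_equal(got, unname(ref[2, -1]), tolerance = 1e-6)
})

test_that("no species goes negative over 100 simulated hours at dt = 0.01", {
  s <- integrate_pathway(pathway_state(), egfr_kinetics(), 100 * 3600, 0.01)
  expect_true(all(unclass(s) >= 0))
  expect_identical(attr(s, "n_clamped"), 0L)
})

test_that("too-large steps abort with a stiffness error instead of clamping", {
  expect_error(integrate_pathway(pathway_state(), egfr_kinetics(), 10, 1),
               "reduce dt")
})

test_that("batch integration is bitwise identical to the sequential loop", {
  p <- egfr_kinetics()
  states <- list(pathway_state(),
                 pathway_state(X1 = 50, X9 = 2),
                 pathway_state(X1 = 0.5, X5 = 10, X6 = 3))
  got <- batch_integrate(states, p, 50, 0.01)
  ref <- lapply(states, integrate_pathway, params = p, duration = 50,
                dt = 0.01)
  for (i in 1:3) {
    expect_identical(as.numeric(unclass(got[[i]])), as.numeric(unclass(ref[[i]])))
  }
  # identical inputs give identical outputs
  same <- batch_integrate(list(pathway_state(), pathway_state(),
                               pathway_state()), p, 10, 0.01)
  expect_identical(unclass(same[[1]]), unclass(same[[2]]))
  expect_identical(unclass(same[[2]]), unclass(same[[3]]))
  expect_error(batch_integrate(list(), p, 10, 0.01), "non-empty")
  expect_error(batch_integrate(matrix(numeric(0), 0, 11), p, 10, 0.01),
               "non-empty")
  # per-cell errors name the cell
  bad <- rbind(as.numeric(unclass(pathway_state())),
               as.numeric(unclass(pathway_state())))
  expect_error(batch_integrate(bad, p, 10, 1), "cell [12]")
})

test_that("percentage rate of change handles zeros per the division policy", {
  a <- pathway_state(X9 = 10)
  b <- pathway_state(X9 = 11)
  attr(b, "t") <- 1
  r <- percentage_rate_of_change(a, b)
  expect_equal(unname(r["X9"]), 0.10)
  # unchanged state: all rates zero, nothing undefined
  r0 <- percentage_rate_of_change(pathway_state(), pathway_state(t = 1))
  expect_equal(as.numeric(r0), rep(0, 11))
  expect_length(attr(r0, "undefined"), 0)
  # appearing from exactly zero is undefined, flagged and NA
  c1 <- pathway_state(X3 = 0)
  c2 <- pathway_state(X3 = 5, t = 1)
  rc <- percentage_rate_of_change(c1, c2)
  expect_true(is.na(rc["X3"]))
  expect_true("X3" %in% attr(rc, "undefined"))
  expect_error(percentage_rate_of_change(b, a), "precede")
})

test_that("phenotype decision implements both branches of the switch rule", {
  expect_identical(decide_phenotype(0.12, 0.10), "migratory")
  expect_identical(decide_phenotype(0.10, 0.10), "proliferative")  # tie
  expect_identical(decide_phenotype(-0.05, 0), "proliferative")
  expect_identical(decide_phenotype(c(1, -1, 0), 0),
                   c("migratory", "proliferative", "proliferative"))
  expect_error(decide_phenotype(NA_real_, 0), "finite")
})

test_that("pathway trajectories export as a tidy table", {
  tr <- simulate_pathway(pathway_state(), egfr_kinetics(), duration = 10,
                         dt = 0.01, record_every = 5)
  expect_identical(names(tr), c("t", paste0("X", 0:10)))
  expect_equal(tr$t, c(0, 5, 10))
  path <- withr::local_tempfile(fileext = ".csv")
  write_pathway_csv(tr, path)
  back <- read.csv(path)
  expect_equal(back$X9, tr$X9, tolerance = 1e-12)
})
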