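test_that("the decision threshold is the cohort mean with sane edge cases", {
  expect_equal(compute_avg_threshold(c(0.1, 0.3)), 0.2)
  expect_equal(compute_avg_threshold(numeric(0)), 0)
  expect_equal(compute_avg_threshold(c(NA, NaN)), 0)
  # a lone decision-maker equals its own average and so proliferates
  r <- 0.42
  expect_identical(decide_phenotype(r, compute_avg_threshold(r)),
                   "proliferative")
})

test_that("receptor coupling transfers ligand from field to cell", {
  f <- chemo_field(c(8, 8), Y = 0)
  s <- pathway_state()
  out <- couple_receptor_input(s, f, c(3, 3))
  expect_equal(as.numeric(unclass(out$state))[2], 0)  # X1 reset to local field
  f$Y[3, 3] <- 50
  out2 <- couple_receptor_input(s, f, c(3, 3), conversion = 1)
  expect_equal(as.numeric(unclass(out2$state))[2], 50)
  expect_equal(out2$field$Y[3, 3], 0)
  expect_equal(out2$uptake, 50)
  # balance audit: over several cells the field loses what the cells gain
  f3 <- chemo_field(matrix(runif(64, 0, 20), 8, 8))
  mass0 <- sum(f3$Y)
  gained <- 0
  for (node in list(c(1, 1), c(2, 5), c(8, 8), c(4, 4), c(5, 2))) {
    o <- couple_receptor_input(pathway_state(X1 = 0), f3, node)
    f3 <- o$field
    gained <- gained + as.numeric(unclass(o$state))[2]
  }
  expect_equal(mass0 - sum(f3$Y), gained, tolerance = 1e-12)
  expect_error(couple_receptor_input(s, f, c(9, 1)), "off the lattice")
})

test_that("a cell-free state still diffuses and records empty steps", {
  cfg <- small_config(steps = 2)
  sim <- gbm_init(cfg)
  sim$alive[seq_len(sim$n)] <- FALSE
  sim$occ[] <- 0L
  sim$cluster <- classify_clusters(glioscale:::.as_lattice(sim))
  y0 <- sim$field$Y
  gbm_step(sim)
  rec <- sim$records[[1]]
  expect_identical(rec$n_total, 0L)
  expect_identical(rec$n_decisions, 0L)
  expect_false(identical(sim$field$Y, y0))  # the field still evolved
})

test_that("population counts partition the living cells at every step", {
  sim <- run_steps(small_config(steps = 14))
  res <- gbm_collect(sim)
  expect_equal(res$population$proliferative + res$population$migratory +
                 res$population$quiescent, res$population$total)
  # no death rule: occupied area never shrinks
  expect_true(all(diff(res$population$total) >= 0))
})

test_that("movement and division are disjoint within every step", {
  sim <- run_steps(small_config(steps = 14))
  for (r in sim$records) {
    expect_length(intersect(r$moved, r$divided), 0)
  }
})

test_that("occupancy and the living cells stay in bijection", {
  sim <- run_steps(small_config(steps = 14))
  live <- which(sim$alive[seq_len(sim$n)])
  expect_setequal(sim$occ[sim$occ != 0L], sim$id[live])
  for (i in live) {
    expect_identical(sim$occ[sim$x[i], sim$y[i]], sim$id[i])
  }
})

test_that("equal seeds give bitwise-equal runs; distinct seeds diverge", {
  cfg <- small_config(steps = 14)
  a <- gbm_collect(run_steps(cfg))
  b <- gbm_collect(run_steps(cfg))
  expect_identical(a$population, b$population)
  expect_identical(a$switch_events, b$switch_events)
  expect_identical(a$cells, b$cells)
  expect_identical(a$state$occ, b$state$occ)
  expect_identical(a$state$pw, b$state$pw)
  c_run <- gbm_collect(run_steps(cfg, seed = cfg$seed + 1))
  expect_false(identical(a$cells, c_run$cells))
})

test_that("a checkpointed run resumes exactly where it left off", {
  cfg <- small_config(steps = 14)
  full <- run_steps(cfg, n = 14)
  half <- run_steps(cfg, n = 7)
  resumed <- gbm_clone(half)
  for (i in 1:7) gbm_step(resumed)
  expect_identical(gbm_collect(full)$population,
                   gbm_collect(resumed)$population)
  expect_identical(full$occ, resumed$occ)
  expect_identical(full$pw, resumed$pw)
  # the original half-run state was not disturbed by its clone
  expect_identical(half$step, 7L)
})

test_that("a lone cell grows by at most one per decision interval", {
  cfg <- gbm_config(steps = 26, replicates = 1,
                    lattice = list(shape_high = c(36L, 36L)),
                    init = list(tumor_radius = 0))
  sim <- run_steps(cfg, n = 26)
  pop <- gbm_collect(sim)$population
  growth <- diff(c(1, pop$total))
  # divisions happen only at decision steps (cycle interval 12), and each
  # cell divides at most once per interval
  expect_true(all(growth[setdiff(1:26, c(12, 24))] == 0))
  expect_lte(growth[12], 1)
  expect_lte(growth[24], pop$total[23])
  expect_lte(max(pop$total), 4)
})

test_that("the engine accepts the Schwarz solver configuration", {
  cfg <- small_config(steps = 1,
                      diffusion = list(sub_dt = 100,
                                       tiles = list(tiles = c(2, 2),
                                                    overlap = 2,
                                                    iterations = 3)))
  sim <- run_steps(cfg, n = 1)
  expect_identical(sim$step, 1L)
  expect_true(all(is.finite(sim$field$Y)))
})

test_that("decisions occur only when the cycle clock expires", {
  sim <- run_steps(small_config(steps = 14))
  res <- gbm_collect(sim)
  expect_true(all(res$population$n_decisions[1:11] == 0))
  expect_gt(res$population$n_decisions[12], 0)
  # switch events only ever happen at decision steps
  if (nrow(res$switch_events) > 0) {
    expect_true(all(res$switch_events$step %% 12 == 0))
  }
})

test_that("step errors carry the step index", {
  cfg <- small_config(steps = 1, ode = list(dt = 5))  # unstable micro-step
  sim <- gbm_init(cfg)
  expect_error(gbm_step(sim), "step 1")
})
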