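test_that("crossing detection flags every sign change, zeros included", {
  s <- tibble::tibble(migratory = c(5, 8, 10), proliferative = c(9, 7, 11))
  expect_identical(find_crossings(s), c(2L, 3L))
  # identical curves: degenerate case, every step after the first
  ident <- tibble::tibble(migratory = rep(4, 6), proliferative = rep(4, 6))
  expect_identical(find_crossings(ident), 2:6)
  # well-separated curves never cross
  apart <- tibble::tibble(migratory = 1:10, proliferative = 21:30)
  expect_length(find_crossings(apart), 0)
  # touching counts (zero is a crossing), as does leaving the tie again
  touch <- tibble::tibble(migratory = c(1, 2, 1), proliferative = c(2, 2, 2))
  expect_identical(find_crossings(touch), c(2L, 3L))
})

test_that("crossing detection agrees with a brute-force scan", {
  set.seed(99)
  for (rep in 1:5) {
    m <- cumsum(sample(-2:2, 1000, TRUE)) + 50
    p <- cumsum(sample(-2:2, 1000, TRUE)) + 50
    s <- tibble::tibble(migratory = m, proliferative = p)
    expect_identical(find_crossings(s), as.integer(oracle_crossings(p, m)))
  }
})

make_events <- function(n_pm, n_mp, seed = 5) {
  set.seed(seed)
  sp <- paste0("X", 1:10)
  ev <- tibble::tibble(step = 12L,
                       id = seq_len(n_pm + n_mp),
                       direction = rep(c("PM", "MP"), c(n_pm, n_mp)))
  for (s in sp) ev[[s]] <- rnorm(n_pm + n_mp, 0.05, 0.1)
  ev
}

test_that("switch profiles are cohort means per species and direction", {
  ev <- make_events(2, 0)
  ev$X9 <- c(0.10, 0.20)
  prof <- switch_profiles(ev)
  pm_x9 <- prof$mean_rate[prof$direction == "PM" & prof$species == "X9"]
  expect_equal(pm_x9, 0.15)
  # no MP events: empty profile with cohort size 0
  expect_true(all(prof$cohort[prof$direction == "MP"] == 0))
  expect_true(all(is.na(prof$mean_rate[prof$direction == "MP"])))
  # ten-event fixture against a hand loop
  ev10 <- make_events(6, 4)
  prof10 <- switch_profiles(ev10)
  for (dir in c("PM", "MP")) {
    for (s in paste0("X", 1:10)) {
      hand <- mean(ev10[[s]][ev10$direction == dir])
      expect_equal(
        prof10$mean_rate[prof10$direction == dir & prof10$species == s],
        hand)
    }
  }
  # event order does not matter
  shuf <- ev10[sample(nrow(ev10)), ]
  expect_equal(switch_profiles(shuf)$mean_rate, prof10$mean_rate)
  # undefined rates are excluded and counted
  ev10$X3[1] <- NA
  profNA <- switch_profiles(ev10)
  expect_equal(profNA$n_excluded[profNA$direction == "PM" &
                                   profNA$species == "X3"], 1)
  # matrix export is species x direction
  m <- profile_matrix(prof10)
  expect_identical(dim(m), c(10L, 2L))
  expect_equal(m["X9", "PM"], mean(ev10$X9[ev10$direction == "PM"]))
})

test_that("trajectories are gap-free position histories", {
  sim <- run_steps(small_config(steps = 14))
  res <- gbm_collect(sim)
  # a founder cell has one row per step
  tr <- trajectory(res, 1L)
  expect_identical(tr$step, 1:14)
  # the walled-in centre cell cannot move before the first decision round
  ctr <- as.integer(floor(c(60, 60) / 2) + 1L)
  idc <- res$cells$id[res$cells$step == 1 & res$cells$x == ctr[1] &
                        res$cells$y == ctr[2]]
  trc <- trajectory(res, idc)
  expect_identical(unique(trc$x[trc$step <= 11]), ctr[1])
  expect_identical(unique(trc$y[trc$step <= 11]), ctr[2])
  # a daughter's trajectory starts at its birth step
  born <- setdiff(unique(res$cells$id), res$cells$id[res$cells$step == 1])
  if (length(born) > 0) {
    trb <- trajectory(res, born[1])
    expect_identical(trb$step, seq(min(trb$step), 14L))
  }
  expect_error(trajectory(res, 10 * sum(res$state$alive) + 99), "unknown")
})

test_that("tidy and glance summarise a run", {
  cfg <- small_config(steps = 14)
  cfg$replicates <- 2L
  run <- gbm_run(cfg)
  td <- tidy(run)
  expect_identical(names(td), c("replicate", "step", "phenotype", "count"))
  expect_identical(nrow(td), 2L * 14L * 4L)
  gl <- glance(run)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$steps, 14L)
  expect_identical(gl$replicates, 2L)
  expect_gte(gl$final_total, 29)
})

test_that("figures render to files without touching their inputs", {
  cfg <- small_config(steps = 13)
  run <- gbm_run(cfg, replicates = 1)
  before <- serialize(run, NULL)
  dir <- withr::local_tempdir()
  paths <- render_figures(run, dir)
  expect_true(all(file.exists(paths)))
  expect_true(any(grepl("population.png", paths)))
  expect_true(any(grepl("clusters_step", paths)))
  expect_identical(serialize(run, NULL), before)
  # plot constructors return ggplot objects with the agreed colour coding
  p1 <- autoplot(run)
  expect_s3_class(p1, "ggplot")
  lab <- run$replicates[[1]]$clusters[[13]]
  p2 <- plot_cluster_map(lab)
  expect_s3_class(p2, "ggplot")
  cols <- ggplot2::ggplot_build(p2)$data[[1]]["fill"]
  expect_true(all(unlist(cols) %in% c("white", "black", "green3")))
  cells13 <- dplyr::filter(run$replicates[[1]]$cells, step == 13)
  p3 <- plot_phenotype_map(cells13)
  expect_s3_class(p3, "ggplot")
  p4 <- plot_trajectory(trajectory(run, 1L))
  expect_s3_class(p4, "ggplot")
  # an empty run still renders axes-only output
  empty <- run
  empty$replicates[[1]]$switch_events <- empty$replicates[[1]]$switch_events[0, ]
  expect_no_error(render_figures(empty, withr::local_tempdir()))
})
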