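#' Simulation configuration
#'
#' Builds the full, validated configuration for a multiscale run. Every
#' block can be overridden piecemeal; unspecified entries keep their
#' defaults. See the methods vignette for the rationale behind each
#' default.
#'
#' @param lattice `shape_high` (fine nodes, default 120 x 120 = 20 x 20
#'   coarse sites) and nesting ratio `r` (default 6).
#' @param steps simulated hours (default 100).
#' @param seed base random seed; every stream and replicate seed derives
#'   from it by fixed offsets.
#' @param replicates independent replicate runs (default 10).
#' @param kinetics overrides for [egfr_kinetics()].
#' @param pathway_init overrides for [pathway_state()] initial values.
#' @param ode `dt` micro-step in s (default 0.1 inside the engine),
#'   `hours_per_step` seconds of pathway time per simulated hour (3600),
#'   `clamp_tol` (nM), `rate_mode` `"relative"` (percentage rate of
#'   change, default) or `"absolute"`.
#' @param diffusion `D` (cm^2/s), `dx` (um), `substeps` ADI steps per
#'   simulated hour, `sub_dt` (s), `bc`, per-cell `secretion` (nM/s),
#'   `uptake_rate` (1/s), optional `tiles` list
#'   (`tiles`, `overlap`, `iterations`) to use the Schwarz solver.
#' @param attraction overrides for [attraction_params()].
#' @param cycle `interval`: steps between phenotype decisions (default 12).
#' @param coupling `conversion`: tissue-to-intracellular TGFalpha factor
#'   (default 1; both sides in nM).
#' @param init initial-condition fixture: `tumor_radius` (fine nodes),
#'   `field_peak` (nM), `field_width` (um, Gaussian s.d.), `source`
#'   (fractional position of the chemoattractant source).
#' @param cluster `neighbourhood` for [classify_clusters()].
#' @param daughter `inherit`: daughters copy the parent pathway state
#'   (default) or reset to the standard initial conditions.
#' @param record `snapshot_every`: store a field snapshot every N steps
#'   (0 = never).
#' @return An object of class `gbm_config` (nested named list).
#' @examples
#' cfg <- gbm_config(steps = 5, replicates = 1, lattice = list(shape_high = c(60, 60)))
#' @export
gbm_config <- function(lattice = list(), steps = 100, seed = 1,
                       replicates = 10, kinetics = list(),
                       pathway_init = list(), ode = list(),
                       diffusion = list(), attraction = list(),
                       cycle = list(), coupling = list(), init = list(),
                       cluster = list(), daughter = list(), record = list()) {
  cfg <- list(
    lattice = modifyList(list(shape_high = c(120L, 120L), r = 6L), lattice),
    steps = as.integer(steps),
    seed = as.integer(seed),
    replicates = as.integer(replicates),
    kinetics = modifyList(unclass(egfr_kinetics()), kinetics),
    pathway_init = modifyList(
      list(X0 = 25, X1 = 9010.55, X2 = 100, X3 = 0, X4 = 0, X5 = 0,
           X6 = 10, X7 = 0, X8 = 0, X9 = 0, X10 = 0), pathway_init),
    ode = modifyList(list(dt = 0.1, hours_per_step = 3600,
                          clamp_tol = 1e-9, rate_mode = "relative"), ode),
    diffusion = modifyList(list(D = 1e-7, dx = 10, substeps = 6L,
                                sub_dt = 600, bc = "zero-flux",
                                secretion = 0.05, uptake_rate = 0.001,
                                tiles = NULL), diffusion),
    attraction = modifyList(list(psi = 0.7, mu = 0, sigma = NULL,
                                 sigma_scale = 0.1), attraction),
    cycle = modifyList(list(interval = 12L), cycle),
    coupling = modifyList(list(conversion = 1), coupling),
    init = modifyList(list(tumor_radius = 5, field_peak = 50,
                           field_width = 300, source = c(0.75, 0.75)), init),
    cluster = modifyList(list(neighbourhood = "moore"), cluster),
    daughter = modifyList(list(inherit = TRUE), daughter),
    record = modifyList(list(snapshot_every = 0L), record)
  )
  # modifyList drops NULL-valued overrides; restore the optional slots so a
  # round-tripped config compares identical to a freshly built one
  if (!"tiles" %in% names(cfg$diffusion)) cfg$diffusion["tiles"] <- list(NULL)
  if (!"sigma" %in% names(cfg$attraction)) cfg$attraction["sigma"] <- list(NULL)
  canon <- function(x, keys) x[c(keys, setdiff(names(x), keys))]
  cfg$diffusion <- canon(cfg$diffusion, c("D", "dx", "substeps", "sub_dt",
                                          "bc", "secretion", "uptake_rate",
                                          "tiles"))
  cfg$attraction <- canon(cfg$attraction, c("psi", "mu", "sigma",
                                            "sigma_scale"))
  class(cfg) <- "gbm_config"
  validate_config(cfg)
}

#' @export
print.gbm_config <- function(x, ...) {
  cat(sprintf("<gbm_config> %d x %d fine lattice (r = %d), %d steps, %d replicate(s), seed %d\n",
              x$lattice$shape_high[1], x$lattice$shape_high[2], x$lattice$r,
              x$steps, x$replicates, x$seed))
  invisible(x)
}

# --- seeded stream management ----------------------------------------------
# One base seed derives every module-level stream by a fixed offset, so
# adding a stream never perturbs the existing ones.
.stream_offsets <- c(init = 11L, actions = 23L)

.streams_new <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  streams <- lapply(.stream_offsets, function(off) {
    set.seed(seed + off)
    get(".Random.seed", globalenv())
  })
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  streams
}

# Evaluate fun() with the named stream active, persisting its advance.
.with_stream <- function(sim, name, fun) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  assign(".Random.seed", sim$streams[[name]], envir = globalenv())
  res <- fun()
  sim$streams[[name]] <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  res
}

# --- state construction -----------------------------------------------------

.grow <- function(sim, need) {
  cap <- length(sim$id)
  if (need <= cap) return(invisible())
  newcap <- max(need, 2L * cap)
  pad <- newcap - cap
  for (f in c("id", "x", "y", "program", "pheno", "clock", "birth")) {
    sim[[f]] <- c(sim[[f]], rep(NA_integer_, pad))
  }
  sim$alive <- c(sim$alive, rep(FALSE, pad))
  sim$frozen <- c(sim$frozen, rep(FALSE, pad))
  sim$pw <- rbind(sim$pw, matrix(0, pad, 11))
  sim$pw_prev <- rbind(sim$pw_prev, matrix(0, pad, 11))
  invisible()
}

.new_cell <- function(sim, x, y, program = 1L, pathway, clock = NULL,
                      birth = NULL) {
  if (sim$occ[x, y] != 0L) stop("node already occupied")
  sim$n <- sim$n + 1L
  .grow(sim, sim$n)
  i <- sim$n
  sim$id[i] <- i
  sim$x[i] <- as.integer(x)
  sim$y[i] <- as.integer(y)
  sim$program[i] <- program
  sim$pheno[i] <- program
  sim$clock[i] <- as.integer(clock %||% sim$cfg$cycle$interval)
  sim$birth[i] <- as.integer(birth %||% sim$step)
  sim$alive[i] <- TRUE
  sim$frozen[i] <- FALSE
  sim$pw[i, ] <- pathway
  sim$pw_prev[i, ] <- pathway
  sim$occ[x, y] <- i
  i
}

#' Initialise a simulation state
#'
#' Builds the mutable simulation state for one replicate: the dual
#' lattice seeded with a disc of proliferative cells at the centre, the
#' TGFalpha field initialised to a radially symmetric Gaussian profile
#' peaked at the configured source location, per-cell pathway states at
#' the standard initial conditions, and the seeded random streams.
#'
#' @param config a [gbm_config()].
#' @param seed seed for this replicate (default `config$seed`).
#' @return An environment of class `gbm_state` (modified in place by
#'   [gbm_step()] and [act()]).
#' @export
gbm_init <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "gbm_config"))
  sim <- new.env(parent = emptyenv())
  class(sim) <- "gbm_state"
  sim$cfg <- config
  sim$seed <- as.integer(seed)
  sim$step <- 0L
  sh <- config$lattice$shape_high
  sim$occ <- matrix(0L, sh[1], sh[2])
  sim$r <- config$lattice$r
  # chemoattractant field: Gaussian bump at the source location
  f <- make_fixture(fixture_spec("gaussian-field", shape = sh,
                                 peak = config$init$field_peak,
                                 width = config$init$field_width / config$diffusion$dx,
                                 centre = round(config$init$source * sh)))
  sim$field <- chemo_field(Y = f, D = config$diffusion$D,
                           dx = config$diffusion$dx)
  # cell containers
  sim$n <- 0L
  cap <- 256L
  for (fld in c("id", "x", "y", "program", "pheno", "clock", "birth")) {
    sim[[fld]] <- rep(NA_integer_, cap)
  }
  sim$alive <- rep(FALSE, cap)
  sim$frozen <- rep(FALSE, cap)
  sim$pw <- matrix(0, cap, 11)
  sim$pw_prev <- matrix(0, cap, 11)
  sim$streams <- .streams_new(sim$seed)
  sim$records <- list()
  sim$moved_step <- integer(0)
  sim$divided_step <- integer(0)
  # seed tumour: proliferative disc at the lattice centre
  disc <- make_fixture(fixture_spec("disc-tumor", shape = sh,
                                    radius = config$init$tumor_radius))
  x0 <- unname(.state_vec(do.call(pathway_state, config$pathway_init)))
  for (k in seq_len(nrow(disc))) {
    .new_cell(sim, disc[k, 1], disc[k, 2], program = 1L, pathway = x0,
              birth = 0L)
  }
  sim$cluster <- classify_clusters(.as_lattice(sim),
                                   config$cluster$neighbourhood)
  sim
}

.as_lattice <- function(sim) {
  structure(list(occ = sim$occ, r = sim$r,
                 shape_high = dim(sim$occ),
                 shape_low = as.integer(ceiling(dim(sim$occ) / sim$r))),
            class = "dual_lattice")
}

#' @export
print.gbm_state <- function(x, ...) {
  cat(sprintf("<gbm_state> step %d, %d living cells, seed %d\n",
              x$step, sum(x$alive[seq_len(x$n)]), x$seed))
  invisible(x)
}

#' Deep-copy a simulation state (checkpointing)
#'
#' Returns an independent copy of a running simulation, including the
#' random streams, so that resuming the copy reproduces exactly what the
#' original would have produced.
#'
#' @param sim a `gbm_state`.
#' @return A new `gbm_state`.
#' @export
gbm_clone <- function(sim) {
  stopifnot(inherits(sim, "gbm_state"))
  out <- list2env(as.list.environment(sim, all.names = TRUE),
                  parent = emptyenv())
  class(out) <- "gbm_state"
  out
}

#' Population threshold of the phenotype decision
#'
#' The arithmetic mean of the PLCgamma-P rate statistics of all cells
#' whose cycle clock expired this step (the decision cohort). Undefined
#' rates (`NA`) are excluded; an empty cohort (or one with no defined
#' rate) yields 0, and no decisions occur.
#'
#' @param candidate_rates numeric vector of per-cell rate statistics.
#' @return Scalar threshold `Avg`.
#' @examples
#' compute_avg_threshold(c(0.1, 0.3))  # 0.2
#' @export
compute_avg_threshold <- function(candidate_rates) {
  r <- candidate_rates[is.finite(candidate_rates)]
  if (length(r) == 0) return(0)
  mean(r)
}

#' Reconcile a cell's TGFalpha input with the local field
#'
#' Before each hour of intracellular integration, the cell's free-ligand
#' pool `X1` is set to the chemoattractant concentration at its node
#' (scaled by the tissue-to-intracellular conversion factor) and that
#' amount is removed from the field, so that ligand is transferred, not
#' duplicated: with conversion 1 and a closed boundary, the total removed
#' from the field equals the total deposited into cells.
#'
#' @param state a [pathway_state()].
#' @param field a [chemo_field()].
#' @param node length-2 high-resolution node of the cell.
#' @param conversion tissue-to-intracellular conversion factor (default 1).
#' @return List with the updated `state`, `field` and the `uptake` amount
#'   (field units).
#' @export
couple_receptor_input <- function(state, field, node, conversion = 1) {
  if (node[1] < 1 || node[1] > nrow(field$Y) ||
        node[2] < 1 || node[2] > ncol(field$Y)) {
    stop("cell off the lattice")
  }
  supply <- max(0, field$Y[node[1], node[2]])
  x <- .state_vec(state)
  x[["X1"]] <- supply * conversion
  field$Y[node[1], node[2]] <- field$Y[node[1], node[2]] - supply
  list(state = structure(x, t = .state_time(state), class = "pathway_state"),
       field = field, uptake = supply)
}

#' Advance the simulation by one step (one simulated hour)
#'
#' Executes the fixed interface loop: (1) rebuild uptake/secretion maps
#' from the current cells and cluster labels; (2) diffusion sub-steps
#' (monolithic ADI, or Schwarz tiles when configured); (3) reclassify
#' clusters; (4) refresh each active cell's TGFalpha input from its node
#' and integrate the EGFR pathway for all heterogeneous-cluster cells;
#' (5) compute the cohort-average PLCgamma-P rate threshold; (6) phenotype
#' decisions and actions in randomised cell order; (7) append the step
#' record.
#'
#' @param sim a `gbm_state` from [gbm_init()].
#' @return The state (invisibly); modified in place.
#' @export
gbm_step <- function(sim) {
  stopifnot(inherits(sim, "gbm_state"))
  cfg <- sim$cfg
  s <- sim$step + 1L
  res <- tryCatch(.gbm_step_inner(sim, cfg, s),
                  error = function(e) {
                    stop("step ", s, ": ", conditionMessage(e), call. = FALSE)
                  })
  sim$step <- s
  sim$records[[s]] <- res
  invisible(sim)
}

.gbm_step_inner <- function(sim, cfg, s) {
  live <- which(sim$alive[seq_len(sim$n)])
  kin <- do.call(egfr_kinetics, cfg$kinetics)

  # (1) sources from the previous step's classification
  cells_df <- data.frame(x = sim$x[live], y = sim$y[live])
  sim$field <- deposit_sources(sim$field, cells_df, sim$cluster,
                               secretion = cfg$diffusion$secretion,
                               uptake_rate = cfg$diffusion$uptake_rate)
  # (2) diffusion sub-steps
  layout <- if (!is.null(cfg$diffusion$tiles)) do.call(tile_layout, cfg$diffusion$tiles)
  for (k in seq_len(cfg$diffusion$substeps)) {
    sim$field <- if (is.null(layout)) {
      adi_step(sim$field, cfg$diffusion$sub_dt, cfg$diffusion$bc,
               warn = FALSE)
    } else {
      schwarz_step(sim$field, layout, cfg$diffusion$sub_dt, cfg$diffusion$bc,
                   warn = FALSE)
    }
  }
  # (3) cluster classification
  lat <- .as_lattice(sim)
  sim$cluster <- classify_clusters(lat, cfg$cluster$neighbourhood)
  site <- cbind((sim$x[live] - 1L) %/% sim$r + 1L,
                (sim$y[live] - 1L) %/% sim$r + 1L)
  lab <- sim$cluster$labels[site]
  sim$frozen[live] <- lab == "homogeneous"
  active <- live[lab == "heterogeneous"]

  cohort <- integer(0)
  avg <- 0
  switches <- NULL
  if (length(active) > 0) {
    # (4) receptor coupling + pathway integration for active cells
    sim$pw_prev[active, ] <- sim$pw[active, ]
    nodes <- cbind(sim$x[active], sim$y[active])
    supply <- pmax(0, sim$field$Y[nodes])
    sim$pw[active, 2] <- supply * cfg$coupling$conversion
    sim$field$Y[nodes] <- sim$field$Y[nodes] - supply
    sim$pw[active, ] <- batch_integrate(sim$pw[active, , drop = FALSE],
                                        kin, cfg$ode$hours_per_step,
                                        cfg$ode$dt, cfg$ode$clamp_tol)
    # (5) decision cohort: active cells whose cycle clock expires now
    sim$clock[active] <- sim$clock[active] - 1L
    cohort <- active[sim$clock[active] <= 0L]
    if (length(cohort) > 0) {
      prev9 <- sim$pw_prev[cohort, 10]
      curr9 <- sim$pw[cohort, 10]
      rates <- if (cfg$ode$rate_mode == "relative") {
        ifelse(prev9 > 0, (curr9 - prev9) / prev9,
               ifelse(curr9 == 0, 0, NA_real_))
      } else {
        curr9 - prev9
      }
      avg <- compute_avg_threshold(rates)
      old_prog <- sim$program[cohort]
      new_prog <- ifelse(is.na(rates), 1L,
                         ifelse(rates > avg, 2L, 1L))
      sim$program[cohort] <- new_prog
      sim$clock[cohort] <- cfg$cycle$interval
      changed <- which(new_prog != old_prog)
      if (length(changed) > 0) {
        rate_mat <- t(vapply(cohort[changed], function(i) {
          p <- sim$pw_prev[i, ]
          q <- sim$pw[i, ]
          ifelse(p > 0, (q - p) / p, ifelse(q == 0, 0, NA_real_))
        }, numeric(11)))
        colnames(rate_mat) <- .species_names
        switches <- tibble::tibble(
          step = s,
          id = sim$id[cohort[changed]],
          direction = ifelse(old_prog[changed] == 1L, "PM", "MP"))
        switches <- dplyr::bind_cols(
          switches, tibble::as_tibble(rate_mat[, -1, drop = FALSE]))
      }
    }
  }
  # (6) actions in randomised order (seeded stream)
  sim$moved_step <- integer(0)
  sim$divided_step <- integer(0)
  decided_now <- sim$id[cohort]
  .with_stream(sim, "actions", function() {
    ord <- if (length(active) > 1) sample(sim$id[active]) else sim$id[active]
    for (id in ord) {
      row <- id  # ids are row indices by construction
      if (sim$program[row] == 2L) {
        act(sim, id)
      } else if (id %in% decided_now) {
        act(sim, id)
      } else {
        # mid-cycle proliferative cell: cycling if it has room, else quiescent
        free <- .free_neighbours(c(sim$x[row], sim$y[row]), sim$occ)
        sim$pheno[row] <- if (nrow(free) > 0) 1L else 3L
      }
    }
    invisible(NULL)
  })
  # frozen (homogeneous-core) cells are quiescent by definition
  live2 <- which(sim$alive[seq_len(sim$n)])
  sim$pheno[live2[sim$frozen[live2]]] <- 3L
  # inactive but not frozen cells keep a displayed phenotype consistent
  # with their surroundings (no action attempted -> quiescent if walled in)
  idle <- setdiff(live2, c(active, which(sim$frozen[seq_len(sim$n)])))
  for (row in idle) {
    free <- .free_neighbours(c(sim$x[row], sim$y[row]), sim$occ)
    sim$pheno[row] <- if (nrow(free) > 0) sim$program[row] else 3L
  }

  # (7) record
  live3 <- which(sim$alive[seq_len(sim$n)])
  ph <- sim$pheno[live3]
  rec <- list(
    step = s,
    n_proliferative = sum(ph == 1L),
    n_migratory = sum(ph == 2L),
    n_quiescent = sum(ph == 3L),
    n_total = length(live3),
    avg_threshold = avg,
    n_decisions = length(cohort),
    field_clamped = sim$field$n_clamped,  # cumulative clamp count
    moved = sort(sim$moved_step),
    divided = sort(sim$divided_step),
    switch_events = switches,
    cluster_labels = .labels_int(sim$cluster$labels),
    cells = tibble::tibble(step = s, id = sim$id[live3],
                           x = sim$x[live3], y = sim$y[live3],
                           phenotype = c("proliferative", "migratory",
                                         "quiescent")[ph],
                           cycle_clock = sim$clock[live3]),
    field_snapshot = if (cfg$record$snapshot_every > 0 &&
                           s %% cfg$record$snapshot_every == 0) {
      sim$field$Y
    }
  )
  rec
}

.labels_int <- function(labels) {
  out <- matrix(0L, nrow(labels), ncol(labels))
  out[labels == "heterogeneous"] <- 1L
  out[labels == "homogeneous"] <- 2L
  out
}

#' Run a full simulation
#'
#' Executes `config$steps` steps for `config$replicates` independent
#' replicates (seeds derived from the base seed by fixed offsets) and
#' collects tidy outputs: per-step population counts, switch events with
#' molecular profiles, per-step cell tables, cluster label matrices and
#' the across-replicate mean population curves.
#'
#' @param config a [gbm_config()].
#' @param replicates override the configured replicate count.
#' @param steps override the configured step count.
#' @return An object of class `gbm_sim`; see [tidy.gbm_sim()],
#'   [glance.gbm_sim()], [autoplot.gbm_sim()].
#' @export
gbm_run <- function(config, replicates = config$replicates,
                    steps = config$steps) {
  stopifnot(inherits(config, "gbm_config"))
  reps <- vector("list", replicates)
  for (rep_i in seq_len(replicates)) {
    seed_i <- config$seed + (rep_i - 1L) * 1009L
    sim <- gbm_init(config, seed = seed_i)
    for (s in seq_len(steps)) gbm_step(sim)
    reps[[rep_i]] <- gbm_collect(sim)
    reps[[rep_i]]$seed <- seed_i
  }
  pop <- dplyr::bind_rows(lapply(seq_along(reps), function(i) {
    dplyr::mutate(reps[[i]]$population, replicate = i, .before = 1)
  }))
  pop_mean <- pop |>
    dplyr::group_by(.data$step) |>
    dplyr::summarise(dplyr::across(c("proliferative", "migratory",
                                     "quiescent", "total"), mean),
                     .groups = "drop")
  structure(list(config = config, replicates = reps,
                 population = pop, population_mean = pop_mean),
            class = "gbm_sim")
}

#' Collect tidy outputs from a simulation state
#'
#' @param sim a `gbm_state` after one or more [gbm_step()] calls.
#' @return List with `population`, `switch_events` and `cells` tibbles,
#'   the per-step `clusters` label matrices (0 empty / 1 heterogeneous /
#'   2 homogeneous), any `field_snapshots`, and the final state.
#' @export
gbm_collect <- function(sim) {
  stopifnot(inherits(sim, "gbm_state"))
  recs <- sim$records
  population <- dplyr::bind_rows(lapply(recs, function(r) {
    tibble::tibble(step = r$step, proliferative = r$n_proliferative,
                   migratory = r$n_migratory, quiescent = r$n_quiescent,
                   total = r$n_total, avg_threshold = r$avg_threshold,
                   n_decisions = r$n_decisions)
  }))
  switch_events <- dplyr::bind_rows(purrr::compact(
    lapply(recs, function(r) r$switch_events)))
  cells <- dplyr::bind_rows(lapply(recs, function(r) r$cells))
  clusters <- lapply(recs, function(r) r$cluster_labels)
  snaps <- purrr::compact(lapply(recs, function(r) r$field_snapshot))
  list(population = population, switch_events = switch_events,
       cells = cells, clusters = clusters, field_snapshots = snaps,
       state = sim)
}

#' @export
print.gbm_sim <- function(x, ...) {
  cat(sprintf("<gbm_sim> %d replicate(s) x %d steps\n",
              length(x$replicates), max(x$population$step)))
  fin <- dplyr::filter(x$population_mean, .data$step == max(.data$step))
  cat(sprintf("  final mean population: %.1f total (%.1f proliferative, %.1f migratory, %.1f quiescent)\n",
              fin$total, fin$proliferative, fin$migratory, fin$quiescent))
  invisible(x)
}
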