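#' Specification of a synthetic fixture
#'
#' Deterministic generators for the inputs a simulation or test needs:
#' `"disc-tumor"` (node list of a filled lattice disc centred on the
#' domain), `"random-occupancy"` (seeded Bernoulli occupancy matrix),
#' `"gaussian-field"` (Gaussian concentration bump) and `"sine-field"`
#' (the Dirichlet heat-equation eigenmode
#' `sin(pi x / L) sin(pi y / L)` with `L = (n + 1) dx`). The same spec and
#' seed always produce an identical fixture.
#'
#' @param kind one of `"disc-tumor"`, `"random-occupancy"`,
#'   `"gaussian-field"`, `"sine-field"`.
#' @param shape lattice shape `c(nx, ny)`.
#' @param radius disc radius in nodes (disc-tumor).
#' @param density occupancy probability (random-occupancy).
#' @param peak,width,centre Gaussian amplitude (nM), s.d. (nodes) and
#'   centre node (gaussian-field; centre defaults to the domain centre).
#' @param seed RNG seed (random-occupancy only).
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(kind = c("disc-tumor", "random-occupancy",
                                  "gaussian-field", "sine-field"),
                         shape = c(101, 101), radius = 5, density = 0.5,
                         peak = 1, width = 10, centre = NULL, seed = 1) {
  kind <- match.arg(kind)
  structure(list(kind = kind, shape = as.integer(shape), radius = radius,
                 density = density, peak = peak, width = width,
                 centre = centre, seed = seed),
            class = "fixture_spec")
}

#' Build a fixture from its specification
#'
#' @param spec a [fixture_spec()].
#' @return `"disc-tumor"`: a 2-column matrix of occupied nodes;
#'   `"random-occupancy"`: an integer occupancy matrix with cell ids;
#'   the field kinds: a numeric matrix.
#' @examples
#' nrow(make_fixture(fixture_spec("disc-tumor", radius = 0)))  # 1
#' @export
make_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  sh <- spec$shape
  switch(spec$kind,
    "disc-tumor" = {
      ctr <- floor(sh / 2) + 1L
      r <- spec$radius
      if (r < 0 || ctr[1] + r > sh[1] || ctr[1] - r < 1 ||
            ctr[2] + r > sh[2] || ctr[2] - r < 1) {
        stop("disc geometry exceeds the lattice")
      }
      xs <- (ctr[1] - r):(ctr[1] + r)
      ys <- (ctr[2] - r):(ctr[2] + r)
      g <- as.matrix(expand.grid(x = xs, y = ys))
      keep <- (g[, 1] - ctr[1])^2 + (g[, 2] - ctr[2])^2 <= r^2
      unname(g[keep, , drop = FALSE])
    },
    "random-occupancy" = {
      old <- if (exists(".Random.seed", globalenv())) {
        get(".Random.seed", globalenv())
      }
      set.seed(spec$seed)
      occ <- matrix(rbinom(prod(sh), 1, spec$density), sh[1], sh[2])
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      ids <- matrix(0L, sh[1], sh[2])
      ids[occ == 1] <- seq_len(sum(occ))
      ids
    },
    "gaussian-field" = {
      ctr <- spec$centre %||% (floor(sh / 2) + 1L)
      dx2 <- outer((seq_len(sh[1]) - ctr[1])^2, (seq_len(sh[2]) - ctr[2])^2, `+`)
      spec$peak * exp(-dx2 / (2 * spec$width^2))
    },
    "sine-field" = {
      sx <- sin(pi * seq_len(sh[1]) / (sh[1] + 1))
      sy <- sin(pi * seq_len(sh[2]) / (sh[2] + 1))
      spec$peak * outer(sx, sy)
    })
}

# --- configuration I/O ------------------------------------------------------

.cfg_blocks <- c("lattice", "steps", "seed", "replicates", "kinetics",
                 "pathway_init", "ode", "diffusion", "attraction", "cycle",
                 "coupling", "init", "cluster", "daughter", "record")

#' Validate a simulation configuration
#'
#' Checks every parameter against its admissible range and rejects
#' unknown keys (typo protection). All problems are reported together,
#' each named by its configuration path (e.g. `attraction.psi`).
#'
#' @param config a `gbm_config` (or plain nested list with the same
#'   shape).
#' @return The validated config (class `gbm_config`), or an error
#'   listing every problem.
#' @export
validate_config <- function(config) {
  probs <- character(0)
  note <- function(...) probs <<- c(probs, sprintf(...))
  bad <- setdiff(names(config), .cfg_blocks)
  if (length(bad) > 0) note("unknown configuration block(s): %s",
                            paste(bad, collapse = ", "))
  chk_keys <- function(block, allowed) {
    extra <- setdiff(names(config[[block]]), allowed)
    if (length(extra) > 0) {
      note("unknown key(s) in %s: %s", block,
           paste(paste0(block, ".", extra), collapse = ", "))
    }
  }
  pos <- function(path, v, strict = TRUE) {
    if (is.null(v) || any(!is.finite(v)) || any(if (strict) v <= 0 else v < 0)) {
      note("%s must be %s", path, if (strict) "> 0" else ">= 0")
    }
  }
  chk_keys("lattice", c("shape_high", "r"))
  chk_keys("kinetics", .kin_order)
  chk_keys("pathway_init", .species_names)
  chk_keys("ode", c("dt", "hours_per_step", "clamp_tol", "rate_mode"))
  chk_keys("diffusion", c("D", "dx", "substeps", "sub_dt", "bc",
                          "secretion", "uptake_rate", "tiles"))
  chk_keys("attraction", c("psi", "mu", "sigma", "sigma_scale"))
  chk_keys("cycle", "interval")
  chk_keys("coupling", "conversion")
  chk_keys("init", c("tumor_radius", "field_peak", "field_width", "source"))
  chk_keys("cluster", "neighbourhood")
  chk_keys("daughter", "inherit")
  chk_keys("record", "snapshot_every")

  if (length(config$lattice$shape_high) != 2 ||
        any(config$lattice$shape_high < 1)) {
    note("lattice.shape_high must be two positive integers")
  }
  pos("lattice.r", config$lattice$r)
  if (is.null(config$steps) || config$steps < 1) note("steps must be >= 1")
  if (is.null(config$replicates) || config$replicates < 1) {
    note("replicates must be >= 1")
  }
  for (k in intersect(names(config$kinetics), .kin_order)) {
    pos(paste0("kinetics.", k), config$kinetics[[k]])
  }
  for (k in intersect(names(config$pathway_init), .species_names)) {
    pos(paste0("pathway_init.", k), config$pathway_init[[k]], strict = FALSE)
  }
  pos("ode.dt", config$ode$dt)
  pos("ode.hours_per_step", config$ode$hours_per_step)
  pos("ode.clamp_tol", config$ode$clamp_tol)
  if (!config$ode$rate_mode %in% c("relative", "absolute")) {
    note("ode.rate_mode must be 'relative' or 'absolute'")
  }
  pos("diffusion.D", config$diffusion$D)
  pos("diffusion.dx", config$diffusion$dx)
  pos("diffusion.substeps", config$diffusion$substeps)
  pos("diffusion.sub_dt", config$diffusion$sub_dt)
  pos("diffusion.secretion", config$diffusion$secretion, strict = FALSE)
  pos("diffusion.uptake_rate", config$diffusion$uptake_rate, strict = FALSE)
  if (!config$diffusion$bc %in% c("zero-flux", "dirichlet-zero")) {
    note("diffusion.bc must be 'zero-flux' or 'dirichlet-zero'")
  }
  psi <- config$attraction$psi
  if (is.null(psi) || !is.finite(psi) || psi <= 0 || psi >= 1) {
    note("attraction.psi must lie strictly in (0, 1)")
  }
  pos("cycle.interval", config$cycle$interval)
  pos("coupling.conversion", config$coupling$conversion)
  pos("init.tumor_radius", config$init$tumor_radius, strict = FALSE)
  pos("init.field_peak", config$init$field_peak, strict = FALSE)
  pos("init.field_width", config$init$field_width)
  if (any(config$init$source < 0) || any(config$init$source > 1)) {
    note("init.source must be fractional coordinates in [0, 1]")
  }
  if (!config$cluster$neighbourhood %in% c("moore", "von-neumann")) {
    note("cluster.neighbourhood must be 'moore' or 'von-neumann'")
  }
  if (length(probs) > 0) {
    stop("invalid configuration:\n  - ", paste(probs, collapse = "\n  - "))
  }
  class(config) <- "gbm_config"
  config
}

#' Read a simulation configuration from YAML
#'
#' Missing entries are filled with the package defaults (the standard
#' kinetic constants and initial concentrations among them), so an empty
#' file yields the full default configuration. Unknown keys are rejected.
#'
#' @param path YAML file.
#' @return A validated [gbm_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  bad <- setdiff(names(raw), .cfg_blocks)
  if (length(bad) > 0) {
    stop("unknown configuration block(s): ", paste(bad, collapse = ", "))
  }
  scalars <- intersect(names(raw), c("steps", "seed", "replicates"))
  blocks <- setdiff(names(raw), scalars)
  args <- c(raw[scalars], raw[blocks])
  do.call(gbm_config, args)
}

#' Write a configuration to YAML
#'
#' `load_config(write_config(cfg, path))` reproduces `cfg` exactly.
#'
#' @param config a `gbm_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "gbm_config"))
  yaml::write_yaml(unclass(config), path,
                   handlers = list(numeric = function(x) {
                     # full double precision round trip
                     if (length(x) == 1) as.numeric(format(x, digits = 17)) else x
                   }))
  invisible(path)
}

# --- run output writers -----------------------------------------------------

#' Write the standard output files of a run
#'
#' Writes `population.csv`, `switch_events.csv`, per-step
#' `clusters_stepNNN.csv` and `cells_stepNNN.csv` label/cell tables, any
#' field snapshots as CSV matrices, and a JSON run manifest echoing the
#' full configuration and seed.
#'
#' @param result a [gbm_collect()] list (or `gbm_sim`, first replicate).
#' @param out_dir output directory.
#' @param config the run's `gbm_config` (taken from a `gbm_sim`
#'   automatically).
#' @param every write per-step tables every `every` steps (default 10).
#' @return Invisibly, the written paths.
#' @export
write_run <- function(result, out_dir, config = NULL, every = 10L) {
  if (inherits(result, "gbm_sim")) {
    config <- result$config
    result <- result$replicates[[1]]
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wp <- function(df, name) {
    p <- file.path(out_dir, name)
    write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wp(result$population, "population.csv")
  if (nrow(result$switch_events %||% tibble::tibble()) > 0) {
    wp(result$switch_events, "switch_events.csv")
  }
  steps <- seq_along(result$clusters)
  for (s in steps[steps %% every == 0 | steps == max(steps)]) {
    p <- file.path(out_dir, sprintf("clusters_step%03d.csv", s))
    write.table(result$clusters[[s]], p, sep = ",", row.names = FALSE,
                col.names = FALSE)
    paths <- c(paths, p)
    wp(dplyr::filter(result$cells, .data$step == s),
       sprintf("cells_step%03d.csv", s))
  }
  if (length(result$field_snapshots) > 0) {
    for (i in seq_along(result$field_snapshots)) {
      p <- file.path(out_dir, sprintf("field_snapshot%03d.csv", i))
      write.table(result$field_snapshots[[i]], p, sep = ",",
                  row.names = FALSE, col.names = FALSE)
      paths <- c(paths, p)
    }
  }
  manifest <- list(
    package = "glioscale",
    version = as.character(utils::packageVersion("glioscale")),
    seed = result$seed %||% (if (!is.null(config)) config$seed),
    config = if (!is.null(config)) unclass(config))
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(paths, mp))
}

#' Export a pathway trajectory as CSV
#'
#' @param traj a [simulate_pathway()] tibble (`t`, `X0..X10`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pathway_csv <- function(traj, path) {
  write.csv(traj, path, row.names = FALSE)
  invisible(path)
}
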