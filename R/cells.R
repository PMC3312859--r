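#' Parameters of the stochastic attraction rule
#'
#' A cell evaluates candidate locations by
#' `T = psi * E + (1 - psi) * eps`, where `E` is the local TGFalpha
#' concentration, `psi` in (0,1) is the search precision and
#' `eps ~ N(mu, sigma^2)` is sensing noise. When `sigma` is `NULL` the
#' noise s.d. is scale-aware: `sigma_scale` times the mean concentration
#' over the evaluated neighbourhood, so the noise level tracks the local
#' signal instead of being an absolute constant.
#'
#' @param psi search precision, strictly between 0 and 1 (default 0.7).
#' @param mu noise mean (nM).
#' @param sigma noise s.d. (nM), or `NULL` for scale-aware noise.
#' @param sigma_scale multiplier for scale-aware noise (default 0.1).
#' @return An object of class `attraction_params`.
#' @export
attraction_params <- function(psi = 0.7, mu = 0, sigma = NULL,
                              sigma_scale = 0.1) {
  if (!is.finite(psi) || psi <= 0 || psi >= 1) {
    stop("attraction.psi must lie strictly between 0 and 1")
  }
  if (!is.null(sigma) && (!is.finite(sigma) || sigma < 0)) {
    stop("attraction.sigma must be nonnegative")
  }
  structure(list(psi = psi, mu = mu, sigma = sigma,
                 sigma_scale = sigma_scale),
            class = "attraction_params")
}

#' Attraction value of candidate locations
#'
#' Draws one noise term per location from the current R random number
#' generator (seed it, or run inside the engine's seeded streams, for
#' reproducibility) and returns `psi * E + (1 - psi) * eps`.
#'
#' @param E nonnegative TGFalpha concentration(s) at the candidate
#'   location(s) (nM).
#' @param params an [attraction_params()].
#' @param eps optional pre-drawn noise value(s), bypassing the generator.
#' @return Numeric attraction values, same length as `E`.
#' @examples
#' attraction(10, attraction_params(psi = 0.7, sigma = 0), eps = 2)  # 7.6
#' @export
attraction <- function(E, params = attraction_params(), eps = NULL) {
  if (any(E < 0)) stop("concentration must be nonnegative")
  if (is.null(eps)) {
    sd_eff <- params$sigma %||% (params$sigma_scale * mean(E))
    eps <- rnorm(length(E), params$mu, sd_eff)
  }
  params$psi * E + (1 - params$psi) * eps
}

# Moore neighbourhood offsets in fixed (row, col) ascending order; this
# ordering is the tie-break contract and the noise-draw order.
.moore_offsets <- matrix(c(-1, -1, -1, 0, -1, 1,
                           0, -1, 0, 1,
                           1, -1, 1, 0, 1, 1),
                         ncol = 2, byrow = TRUE)

.free_neighbours <- function(pos, occ) {
  nb <- sweep(.moore_offsets, 2, pos, `+`)
  ok <- nb[, 1] >= 1 & nb[, 1] <= nrow(occ) &
    nb[, 2] >= 1 & nb[, 2] <= ncol(occ)
  nb <- nb[ok, , drop = FALSE]
  nb[occ[nb] == 0L, , drop = FALSE]
}

#' Select the most attractive free neighbouring node
#'
#' Evaluates the attraction rule at every unoccupied node of the cell's
#' 8-connected Moore neighbourhood and returns the argmax. Ties are broken
#' deterministically by the lowest `(row, column)` ordering; noise terms
#' are drawn in that same fixed order, so equal seeds give equal choices.
#'
#' @param pos length-2 vector: the cell's high-resolution node.
#' @param field a [chemo_field()] supplying the concentrations.
#' @param occ integer occupancy matrix (0 = free).
#' @param params an [attraction_params()].
#' @return Length-2 integer vector (target node), or `NULL` when no
#'   neighbour is free.
#' @export
select_target <- function(pos, field, occ, params = attraction_params()) {
  free <- .free_neighbours(pos, occ)
  if (nrow(free) == 0) return(NULL)
  E <- field$Y[free]
  # scale-aware noise uses the mean concentration over the whole evaluated
  # neighbourhood (free nodes), so sigma does not depend on occupancy order
  sd_eff <- params$sigma %||% (params$sigma_scale * mean(E))
  eps <- rnorm(nrow(free), params$mu, sd_eff)
  Tval <- params$psi * E + (1 - params$psi) * eps
  best <- which.max(Tval)  # first maximum = lowest (row, col) by construction
  as.integer(free[best, ])
}

#' Apply a cell's phenotype action to the simulation state
#'
#' Commits one action for one cell in a running simulation: a migratory
#' cell moves to the target (old node freed, new node filled, trajectory
#' extended); a proliferative cell spawns a daughter at the target, the
#' daughter inheriting a copy of the parent's pathway state (or the
#' standard initial state, per the configuration) with both cycle clocks
#' reset. A cell never both moves and divides in the same step. With no
#' free target the cell is marked quiescent for this step. If the chosen
#' target is occupied at commit time the cell retargets once, then
#' quiesces.
#'
#' @param sim a simulation state from [gbm_init()].
#' @param id cell id.
#' @param target length-2 node, or `NULL` to let the cell choose via
#'   [select_target()].
#' @return The action outcome, one of `"moved"`, `"divided"`,
#'   `"quiescent"` (invisibly). The state is modified in place.
#' @export
act <- function(sim, id, target = NULL) {
  stopifnot(inherits(sim, "gbm_state"))
  row <- match(id, sim$id[seq_len(sim$n)])
  if (is.na(row) || !sim$alive[row]) stop("unknown or dead cell id: ", id)
  pos <- c(sim$x[row], sim$y[row])
  pars <- do.call(attraction_params, sim$cfg$attraction)
  fld <- list(Y = sim$field$Y)
  if (is.null(target)) target <- select_target(pos, fld, sim$occ, pars)
  if (!is.null(target) && sim$occ[target[1], target[2]] != 0L) {
    target <- select_target(pos, fld, sim$occ, pars)  # retarget once
  }
  if (is.null(target)) {
    sim$pheno[row] <- 3L  # quiescent this step
    return(invisible("quiescent"))
  }
  if (sim$program[row] == 2L) {  # migratory
    sim$occ[pos[1], pos[2]] <- 0L
    sim$occ[target[1], target[2]] <- as.integer(id)
    sim$x[row] <- target[1]
    sim$y[row] <- target[2]
    sim$pheno[row] <- 2L
    sim$moved_step <- c(sim$moved_step, id)
    invisible("moved")
  } else {  # proliferative: spawn offspring at the target
    did <- .new_cell(sim, target[1], target[2],
                     program = 1L,
                     pathway = if (isTRUE(sim$cfg$daughter$inherit)) {
                       sim$pw[row, ]
                     } else {
                       unname(.state_vec(do.call(pathway_state, sim$cfg$pathway_init)))
                     })
    sim$clock[row] <- sim$cfg$cycle$interval
    sim$pheno[row] <- 1L
    sim$divided_step <- c(sim$divided_step, id)
    invisible("divided")
  }
}
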