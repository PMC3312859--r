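#' Kinetic constants of the EGFR/PLCgamma interaction network
#'
#' Constructs the full set of rate constants for the intracellular EGFR
#' signalling network: nine reversible reaction pairs (`k1`/`km1` ...
#' `k9`/`km9`, mass-action) and two enzymatic dephosphorylation steps in
#' Michaelis--Menten form (`V4`/`K4` acting on the phosphorylated receptor
#' dimer, `V8`/`K8` acting on phosphorylated PLCgamma). Defaults are the
#' literature values used throughout the package.
#'
#' Units: second-order forward rates in 1/(nM s), first-order rates in 1/s,
#' Michaelis constants in nM, maximal enzyme rates in nM/s.
#'
#' @param k1,km1 TGFalpha + EGFR binding / unbinding.
#' @param k2,km2 receptor-complex dimerisation / undimerisation.
#' @param k3,km3 dimer phosphorylation / dephosphorylation (mass action).
#' @param K4,V4 Michaelis constant and maximal rate of the phosphatase
#'   acting on the phosphorylated dimer.
#' @param k5,km5 phosphorylated receptor + PLCgamma binding / unbinding.
#' @param k6,km6 receptor-bound PLCgamma phosphorylation / reverse.
#' @param k7,km7 release of phosphorylated PLCgamma / rebinding.
#' @param K8,V8 Michaelis constant and maximal rate of the PLCgamma-P
#'   phosphatase.
#' @param k9,km9 PLCgamma-P translocation/inactivation and its reverse.
#'
#' @return An object of class `egfr_kinetics`: a named list of the 18
#'   constants, all strictly positive.
#' @examples
#' p <- egfr_kinetics()
#' p$k1
#' @export
egfr_kinetics <- function(k1 = 0.003, km1 = 0.06,
                          k2 = 0.01, km2 = 0.1,
                          k3 = 1, km3 = 0.01,
                          K4 = 50, V4 = 450,
                          k5 = 0.06, km5 = 0.2,
                          k6 = 1, km6 = 0.05,
                          k7 = 0.3, km7 = 0.006,
                          K8 = 100, V8 = 1,
                          k9 = 1, km9 = 0.03) {
  p <- list(k1 = k1, km1 = km1, k2 = k2, km2 = km2, k3 = k3, km3 = km3,
            K4 = K4, V4 = V4, k5 = k5, km5 = km5, k6 = k6, km6 = km6,
            k7 = k7, km7 = km7, K8 = K8, V8 = V8, k9 = k9, km9 = km9)
  vals <- unlist(p)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all kinetic constants must be strictly positive and finite")
  }
  structure(p, class = "egfr_kinetics")
}

# Fixed parameter ordering shared with the compiled integrator.
.kin_order <- c("k1", "km1", "k2", "km2", "k3", "km3", "K4", "V4",
                "k5", "km5", "k6", "km6", "k7", "km7", "K8", "V8",
                "k9", "km9")

.kin_vec <- function(params) {
  if (!inherits(params, "egfr_kinetics")) params <- do.call(egfr_kinetics, as.list(params))
  unlist(params[.kin_order])
}

#' Molecular state of one cell's EGFR network
#'
#' The 11 state variables tracked per cell: `X0` glucose (mM, inert),
#' `X1` TGFalpha, `X2` EGFR, `X3` TGFalpha-EGFR, `X4` (TGFalpha-EGFR)^2,
#' `X5` TGFalpha-EGFR-P, `X6` PLCgamma, `X7` TGFalpha-EGFR-PLCgamma,
#' `X8` TGFalpha-EGFR-PLCgamma-P, `X9` PLCgamma-P, `X10` PLCgamma-P-I,
#' all in nM except glucose. Defaults are the standard initial conditions
#' (free ligand, receptor and PLCgamma only; all complexes zero).
#'
#' @param X0,X1,X2,X3,X4,X5,X6,X7,X8,X9,X10 species values.
#' @param t elapsed time in seconds.
#' @return An object of class `pathway_state`: named numeric vector of the
#'   11 species with a `t` attribute.
#' @examples
#' s <- pathway_state()
#' moiety_totals(s)
#' @export
pathway_state <- function(X0 = 25, X1 = 9010.55, X2 = 100, X3 = 0, X4 = 0,
                          X5 = 0, X6 = 10, X7 = 0, X8 = 0, X9 = 0, X10 = 0,
                          t = 0) {
  x <- c(X0 = X0, X1 = X1, X2 = X2, X3 = X3, X4 = X4, X5 = X5,
         X6 = X6, X7 = X7, X8 = X8, X9 = X9, X10 = X10)
  if (any(!is.finite(x))) stop("pathway state must be finite")
  if (any(x < 0)) stop("pathway state concentrations must be nonnegative")
  structure(x, t = t, class = "pathway_state")
}

.species_names <- c("X0", "X1", "X2", "X3", "X4", "X5",
                    "X6", "X7", "X8", "X9", "X10")

.state_vec <- function(state) {
  x <- unclass(state)
  attributes(x) <- NULL
  if (length(x) != 11) stop("pathway state must have 11 species")
  if (any(!is.finite(x))) stop("pathway state must be finite")
  if (any(x < 0)) stop("pathway state concentrations must be nonnegative")
  names(x) <- .species_names
  x
}

.state_time <- function(state) {
  t <- attr(state, "t")
  if (is.null(t)) 0 else t
}

#' Instantaneous reaction velocities of the EGFR network
#'
#' Evaluates the nine reaction velocities `v1..v9` (nM/s) at a given state:
#' mass-action for the reversible steps, Michaelis--Menten quotients for
#' the two phosphatase reactions (`v4 = V4*X5/(K4+X5)`,
#' `v8 = V8*X9/(K8+X9)`).
#'
#' @param state a [pathway_state()] (or bare numeric vector of 11 species).
#' @param params an [egfr_kinetics()] object.
#' @return Named numeric vector `v1..v9`.
#' @examples
#' reaction_rates(pathway_state(), egfr_kinetics())
#' @export
reaction_rates <- function(state, params = egfr_kinetics()) {
  x <- .state_vec(state)
  p <- .kin_vec(params)
  c(v1 = p[["k1"]] * x[["X1"]] * x[["X2"]] - p[["km1"]] * x[["X3"]],
    v2 = p[["k2"]] * x[["X3"]]^2 - p[["km2"]] * x[["X4"]],
    v3 = p[["k3"]] * x[["X4"]] - p[["km3"]] * x[["X5"]],
    v4 = p[["V4"]] * x[["X5"]] / (p[["K4"]] + x[["X5"]]),
    v5 = p[["k5"]] * x[["X5"]] * x[["X6"]] - p[["km5"]] * x[["X7"]],
    v6 = p[["k6"]] * x[["X7"]] - p[["km6"]] * x[["X8"]],
    v7 = p[["k7"]] * x[["X8"]] - p[["km7"]] * x[["X5"]] * x[["X9"]],
    v8 = p[["V8"]] * x[["X9"]] / (p[["K8"]] + x[["X9"]]),
    v9 = p[["k9"]] * x[["X9"]] - p[["km9"]] * x[["X10"]])
}

#' Time derivatives of the EGFR network state
#'
#' Assembles `dXi/dt` from the reaction velocities by the network
#' stoichiometry. Glucose (`X0`) appears in no reaction and is carried as
#' an inert variable (`dX0/dt = 0`).
#'
#' @inheritParams reaction_rates
#' @return Named numeric vector `dX0..dX10` in nM/s.
#' @examples
#' pathway_derivatives(pathway_state())
#' @export
pathway_derivatives <- function(state, params = egfr_kinetics()) {
  v <- reaction_rates(state, params)
  setNames(c(0,
             -v[["v1"]],
             -v[["v1"]],
             v[["v1"]] - 2 * v[["v2"]],
             v[["v2"]] + v[["v4"]] - v[["v3"]],
             v[["v3"]] + v[["v7"]] - v[["v4"]] - v[["v5"]],
             v[["v8"]] - v[["v5"]],
             v[["v5"]] - v[["v6"]],
             v[["v6"]] - v[["v7"]],
             v[["v7"]] - v[["v8"]] - v[["v9"]],
             v[["v9"]]),
           paste0("d", .species_names))
}

#' Conserved moiety totals of the EGFR network
#'
#' The reaction scheme conserves three linear combinations: total receptor
#' (`X2 + X3 + 2*(X4+X5+X7+X8)`; dimer-containing complexes carry two
#' receptors), total PLCgamma (`X6 + X7 + X8 + X9 + X10`) and total ligand
#' (`X1 + X3 + 2*(X4+X5+X7+X8)`). Along any exact trajectory these are
#' constant; they are the main correctness audit of the integrator.
#'
#' @inheritParams reaction_rates
#' @return Named numeric vector `egfr_total`, `plcg_total`, `tgfa_total` (nM).
#' @export
moiety_totals <- function(state) {
  x <- .state_vec(state)
  dim2 <- 2 * (x[["X4"]] + x[["X5"]] + x[["X7"]] + x[["X8"]])
  c(egfr_total = x[["X2"]] + x[["X3"]] + dim2,
    plcg_total = x[["X6"]] + x[["X7"]] + x[["X8"]] + x[["X9"]] + x[["X10"]],
    tgfa_total = x[["X1"]] + x[["X3"]] + dim2)
}

.check_steps <- function(duration, dt) {
  if (!is.finite(duration) || duration < 0) stop("duration must be >= 0")
  if (duration == 0) return(0L)
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  if (dt > duration) stop("dt must not exceed duration")
  n <- round(duration / dt)
  if (abs(n * dt - duration) > 1e-9 * max(1, duration)) {
    stop("duration must be an integer multiple of dt")
  }
  n
}

#' Integrate the EGFR network by fixed-step RK4
#'
#' Advances a pathway state by classical 4th-order Runge--Kutta with a
#' fixed micro-step. Tiny negative overshoot (within `clamp_tol`) is
#' clamped to zero and counted; a larger undershoot, or a non-finite
#' value, aborts with an error advising a smaller `dt` (the explicit
#' scheme has a finite stability region). Because the step size is fixed
#' and `duration` must be a multiple of `dt`, the result is independent of
#' how a duration is partitioned into successive calls.
#'
#' @inheritParams reaction_rates
#' @param duration integration time (s); must be a multiple of `dt`.
#' @param dt micro-step (s); default 0.01.
#' @param clamp_tol negative-overshoot tolerance in nM (default 1e-9).
#' @return A [pathway_state()] with time advanced by `duration`; the number
#'   of clamping events is in attribute `n_clamped`.
#' @examples
#' s <- integrate_pathway(pathway_state(), egfr_kinetics(), 10, 0.01)
#' moiety_totals(s)
#' @export
integrate_pathway <- function(state, params = egfr_kinetics(), duration,
                              dt = 0.01, clamp_tol = 1e-9) {
  x <- .state_vec(state)
  n <- .check_steps(duration, dt)
  if (n == 0L) {
    out <- state
    attr(out, "n_clamped") <- 0L
    return(out)
  }
  res <- rk4_pathway_cpp(unname(x), .kin_vec(params), n, dt, clamp_tol)
  out <- setNames(res$state, .species_names)
  structure(out, t = .state_time(state) + duration,
            n_clamped = res$n_clamped, class = "pathway_state")
}

#' Integrate a batch of pathway states
#'
#' Element-wise identical to calling [integrate_pathway()] on each state in
#' turn (the batch form exists so a data-parallel backend could process the
#' whole heterogeneous-cluster cohort at once; results are contractually
#' identical to the sequential loop). Errors carry the offending cell's
#' index.
#'
#' @param states a non-empty list of [pathway_state()] objects, or a numeric
#'   matrix with 11 columns (one row per cell).
#' @inheritParams integrate_pathway
#' @return Same container type as the input, integrated; clamp counts in
#'   attribute `n_clamped` (integer per cell).
#' @export
batch_integrate <- function(states, params = egfr_kinetics(), duration,
                            dt = 0.01, clamp_tol = 1e-9) {
  as_list <- !is.matrix(states)
  if (as_list) {
    if (length(states) == 0) stop("batch_integrate requires a non-empty batch")
    m <- do.call(rbind, lapply(states, function(s) unname(.state_vec(s))))
    t0 <- vapply(states, .state_time, numeric(1))
  } else {
    if (nrow(states) == 0) stop("batch_integrate requires a non-empty batch")
    if (ncol(states) != 11) stop("state matrix must have 11 columns (X0..X10)")
    if (any(!is.finite(states))) stop("pathway state must be finite")
    if (any(states < 0)) stop("pathway state concentrations must be nonnegative")
    m <- unname(states)
    t0 <- NULL
  }
  n <- .check_steps(duration, dt)
  if (n == 0L) {
    return(structure(states, n_clamped = integer(nrow(m))))
  }
  res <- rk4_pathway_batch_cpp(m, .kin_vec(params), n, dt, clamp_tol)
  if (as_list) {
    out <- lapply(seq_len(nrow(m)), function(i) {
      structure(setNames(res$states[i, ], .species_names),
                t = t0[i] + duration, class = "pathway_state")
    })
  } else {
    out <- res$states
    colnames(out) <- .species_names
  }
  structure(out, n_clamped = res$n_clamped)
}

#' Record a pathway trajectory as a tibble
#'
#' Convenience wrapper around [integrate_pathway()] that saves the state
#' every `record_every` seconds, returning a tidy table ready for CSV
#' export or plotting.
#'
#' @inheritParams integrate_pathway
#' @param record_every sampling interval (s); must be a multiple of `dt`.
#' @return A tibble with columns `t` and `X0..X10`.
#' @export
simulate_pathway <- function(state, params = egfr_kinetics(), duration,
                             dt = 0.01, record_every = 60,
                             clamp_tol = 1e-9) {
  n_chunks <- .check_steps(duration, record_every)
  rows <- vector("list", n_chunks + 1)
  rows[[1]] <- c(t = .state_time(state), .state_vec(state))
  s <- state
  for (i in seq_len(n_chunks)) {
    s <- integrate_pathway(s, params, record_every, dt, clamp_tol)
    rows[[i + 1]] <- c(t = .state_time(s), .state_vec(s))
  }
  tibble::as_tibble(as.data.frame(do.call(rbind, rows)))
}

#' Per-species percentage rate of change between two states
#'
#' For each species, the relative change `(curr - prev) / prev` per
#' simulation step (normalised by `dt_step` when the two states are more
#' than one step apart). A species at zero that stays at zero has rate 0;
#' a species that appears from exactly zero has an undefined relative rate
#' and is returned as `NA` (callers exclude these from averages).
#'
#' @param prev,curr [pathway_state()] objects with `prev` earlier.
#' @param dt_step elapsed steps between the two states (default 1).
#' @return Named numeric vector over `X0..X10`; `NA` marks undefined rates.
#'   Attribute `undefined` lists the affected species.
#' @examples
#' a <- pathway_state(X9 = 10); b <- pathway_state(X9 = 11)
#' percentage_rate_of_change(a, b)[["X9"]]
#' @export
percentage_rate_of_change <- function(prev, curr, dt_step = 1) {
  if (!is.finite(dt_step) || dt_step <= 0) stop("dt_step must be > 0")
  tp <- attr(prev, "t")
  tc <- attr(curr, "t")
  if (!is.null(tp) && !is.null(tc) && tp >= tc) {
    stop("prev must precede curr in time")
  }
  p <- .state_vec(prev)
  q <- .state_vec(curr)
  r <- ifelse(p > 0, (q - p) / p / dt_step, ifelse(q == 0, 0, NA_real_))
  structure(setNames(r, .species_names),
            undefined = .species_names[is.na(r)])
}

#' Phenotype decision from the PLCgamma-P rate statistic
#'
#' A cell whose PLCgamma-P rate-of-change statistic strictly exceeds the
#' cohort average becomes migratory; otherwise (including ties) it adopts
#' the proliferative phenotype. Vectorised over `cell_rate`.
#'
#' @param cell_rate the cell's rate statistic (finite).
#' @param avg the population threshold (finite scalar).
#' @return Character vector: `"migratory"` or `"proliferative"`.
#' @examples
#' decide_phenotype(c(0.12, 0.10, -0.05), avg = 0.10)
#' @export
decide_phenotype <- function(cell_rate, avg) {
  if (any(!is.finite(cell_rate)) || !is.finite(avg)) {
    stop("cell_rate and avg must be finite")
  }
  ifelse(cell_rate > avg, "migratory", "proliferative")
}

#' @export
print.pathway_state <- function(x, ...) {
  cat("<pathway_state> t =", .state_time(x), "s\n")
  print(setNames(as.numeric(x), .species_names))
  invisible(x)
}

#' @export
print.egfr_kinetics <- function(x, ...) {
  cat("<egfr_kinetics>\n")
  print(unlist(x))
  invisible(x)
}
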