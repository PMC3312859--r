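#' Chemoattractant field on the high-resolution lattice
#'
#' Container for the tissue-scale TGFalpha concentration `Y` (nM) together
#' with per-node uptake `U` and secretion `S` rate maps (nM/s) entering the
#' reaction-diffusion balance `dY/dt = D lap(Y) - U + S`.
#'
#' @param shape integer vector `c(nx, ny)` of high-resolution nodes (used
#'   when `Y` is a scalar).
#' @param Y initial concentration: scalar (filled) or matrix (nM).
#' @param D diffusivity in cm^2/s (default 1e-7, typical for a small
#'   protein in tissue); converted internally to um^2/s.
#' @param dx grid spacing in um (default 10, one cell diameter).
#' @param U,S optional uptake/secretion maps (nM/s); default zero.
#' @return An object of class `chemo_field`.
#' @examples
#' f <- chemo_field(c(64, 64), Y = 1)
#' @export
chemo_field <- function(shape = c(128, 128), Y = 0, D = 1e-7, dx = 10,
                        U = NULL, S = NULL) {
  if (is.matrix(shape)) {  # chemo_field(Y, ...) convenience form
    Y <- shape
  }
  if (is.matrix(Y)) shape <- dim(Y) else Y <- matrix(Y, shape[1], shape[2])
  if (is.null(U)) U <- matrix(0, shape[1], shape[2])
  if (is.null(S)) S <- matrix(0, shape[1], shape[2])
  stopifnot(all(dim(U) == dim(Y)), all(dim(S) == dim(Y)),
            is.finite(D), D > 0, is.finite(dx), dx > 0)
  structure(list(Y = Y, U = U, S = S, D = D, dx = dx, t = 0,
                 n_clamped = 0L),
            class = "chemo_field")
}

#' @export
print.chemo_field <- function(x, ...) {
  cat(sprintf("<chemo_field> %d x %d nodes, dx = %g um, D = %g cm^2/s, t = %g s\n",
              nrow(x$Y), ncol(x$Y), x$dx, x$D, x$t))
  cat(sprintf("  Y range [%g, %g] nM; clamped nodes so far: %d\n",
              min(x$Y), max(x$Y), x$n_clamped))
  invisible(x)
}

#' Solve a tridiagonal linear system (Thomas algorithm)
#'
#' O(n) forward elimination / back substitution for a tridiagonal system.
#' Diagonal dominance (`|diag| >= |sub| + |sup|` row-wise) is checked and a
#' warning issued when violated; a zero pivot aborts.
#'
#' @param sub lower diagonal, length `n - 1` (entries for rows `2..n`).
#' @param diag main diagonal, length `n`.
#' @param sup upper diagonal, length `n - 1` (entries for rows `1..n-1`).
#' @param rhs right-hand side, length `n`.
#' @return Solution vector of length `n`.
#' @examples
#' thomas_solve(c(-1, -1), c(2, 2, 2), c(-1, -1), c(1, 0, 1))
#' @export
thomas_solve <- function(sub, diag, sup, rhs) {
  n <- length(diag)
  stopifnot(length(rhs) == n, length(sub) == n - 1, length(sup) == n - 1)
  dom <- abs(diag) >= abs(c(0, sub)) + abs(c(sup, 0))
  if (!all(dom)) {
    warning("tridiagonal system is not diagonally dominant in rows: ",
            paste(head(which(!dom), 5), collapse = ", "))
  }
  cp <- numeric(n)
  dp <- numeric(n)
  if (diag[1] == 0) stop("zero pivot in Thomas solve (row 1)")
  cp[1] <- if (n > 1) sup[1] / diag[1] else 0
  dp[1] <- rhs[1] / diag[1]
  if (n > 1) {
    for (i in 2:n) {
      piv <- diag[i] - sub[i - 1] * cp[i - 1]
      if (piv == 0) stop("zero pivot in Thomas solve (row ", i, ")")
      if (i < n) cp[i] <- sup[i] / piv
      dp[i] <- (rhs[i] - sub[i - 1] * dp[i - 1]) / piv
    }
  }
  x <- numeric(n)
  x[n] <- dp[n]
  if (n > 1) for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

# --- internal ADI machinery -------------------------------------------------
# Ghost specification per side: "reflect" (zero-flux), "zero"
# (Dirichlet-zero), or a numeric vector of boundary values (Dirichlet with
# supplied data, used by the Schwarz tiling).

# (I + a*L) applied along rows (first index). ghost_lo/ghost_hi give the
# virtual row above row 1 / below row n.
.explicit_rows <- function(Y, a, ghost_lo, ghost_hi) {
  n <- nrow(Y)
  up <- if (identical(ghost_lo, "reflect")) {
    Y[c(1, seq_len(n - 1)), , drop = FALSE]
  } else if (identical(ghost_lo, "zero")) {
    rbind(0, Y[seq_len(n - 1), , drop = FALSE])
  } else {
    rbind(ghost_lo, Y[seq_len(n - 1), , drop = FALSE])
  }
  down <- if (identical(ghost_hi, "reflect")) {
    Y[c(seq.int(2, length.out = n - 1), n), , drop = FALSE]
  } else if (identical(ghost_hi, "zero")) {
    rbind(Y[seq.int(2, length.out = n - 1), , drop = FALSE], 0)
  } else {
    rbind(Y[seq.int(2, length.out = n - 1), , drop = FALSE], ghost_hi)
  }
  Y + a * (up + down - 2 * Y)
}

# Solves (I - a*L) X = RHS along rows for every column at once. The
# tridiagonal matrix is identical across columns, so the Thomas sweeps are
# vectorised over columns.
.implicit_rows <- function(RHS, a, ghost_lo, ghost_hi) {
  n <- nrow(RHS)
  if (n == 1) {
    # single row: L degenerates; reflect -> 0, Dirichlet couples both ghosts
    if (identical(ghost_lo, "reflect")) return(RHS)
    extra <- matrix(0, 1, ncol(RHS))
    if (!identical(ghost_lo, "zero")) extra <- extra + a * rbind(ghost_lo)
    if (!identical(ghost_hi, "zero") && !identical(ghost_hi, "reflect")) {
      extra <- extra + a * rbind(ghost_hi)
    }
    return((RHS + extra) / (1 + 2 * a))
  }
  d <- rep(1 + 2 * a, n)
  if (identical(ghost_lo, "reflect")) d[1] <- 1 + a
  if (identical(ghost_hi, "reflect")) d[n] <- 1 + a
  if (is.numeric(ghost_lo)) RHS[1, ] <- RHS[1, ] + a * ghost_lo
  if (is.numeric(ghost_hi)) RHS[n, ] <- RHS[n, ] + a * ghost_hi
  off <- -a
  # forward elimination (scalar pivots shared by all columns)
  cp <- numeric(n)
  piv <- d[1]
  cp[1] <- off / piv
  RHS[1, ] <- RHS[1, ] / piv
  for (i in 2:n) {
    piv <- d[i] - off * cp[i - 1]
    if (i < n) cp[i] <- off / piv
    RHS[i, ] <- (RHS[i, ] - off * RHS[i - 1, ]) / piv
  }
  for (i in (n - 1):1) RHS[i, ] <- RHS[i, ] - cp[i] * RHS[i + 1, ]
  RHS
}

.bc_ghosts <- function(bc) {
  g <- if (bc == "zero-flux") "reflect" else "zero"
  list(x_lo = g, x_hi = g, y_lo = g, y_hi = g)
}

# Core Peaceman-Rachford step on a (sub)domain. ghosts is a list with
# x_lo/x_hi (virtual rows, at both the old and intermediate time levels)
# and y_lo/y_hi (virtual columns). For tiled solves the caller passes
# time-level-specific ghost data via ghosts_old / ghosts_star / ghosts_new;
# for a monolithic solve all three are the physical bc.
.adi_core <- function(Y, a, src2, ghosts_old, ghosts_star, ghosts_new) {
  # half step 1: implicit in x (rows), explicit in y (columns)
  rhs1 <- t(.explicit_rows(t(Y), a, ghosts_old$y_lo, ghosts_old$y_hi)) + src2
  Ystar <- .implicit_rows(rhs1, a, ghosts_star$x_lo, ghosts_star$x_hi)
  # half step 2: implicit in y, explicit in x
  rhs2 <- .explicit_rows(Ystar, a, ghosts_star$x_lo2 %||% ghosts_star$x_lo,
                         ghosts_star$x_hi2 %||% ghosts_star$x_hi) + src2
  Ynew <- t(.implicit_rows(t(rhs2), a, ghosts_new$y_lo, ghosts_new$y_hi))
  list(star = Ystar, new = Ynew)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One ADI step of the chemoattractant reaction-diffusion equation
#'
#' Advances the field by one Peaceman--Rachford alternating-direction
#' implicit step of size `dt`: a half step implicit in x / explicit in y,
#' then the directions swapped, each half step adding the reaction source
#' `(S - U) * dt/2`. The linear part is unconditionally stable; the
#' implicit sweeps are Thomas solves batched across grid lines. Negative
#' values produced by the source term are clamped at zero and counted in
#' `n_clamped` (with a one-off warning).
#'
#' @param field a [chemo_field()].
#' @param dt time step (s).
#' @param bc `"zero-flux"` (closed tissue slice, default) or
#'   `"dirichlet-zero"` (absorbing edges).
#' @param warn emit a warning when nodes are clamped (default `TRUE`);
#'   the count is accumulated in `n_clamped` either way.
#' @return The advanced `chemo_field`.
#' @examples
#' f <- chemo_field(c(32, 32), Y = 1)
#' f2 <- adi_step(f, dt = 50)
#' sum(f2$Y) / sum(f$Y)  # mass conserved under zero-flux
#' @export
adi_step <- function(field, dt, bc = c("zero-flux", "dirichlet-zero"),
                     warn = TRUE) {
  bc <- match.arg(bc)
  stopifnot(inherits(field, "chemo_field"), is.finite(dt), dt > 0)
  if (any(!is.finite(field$Y))) stop("non-finite field values")
  a <- (field$D * 1e8) * dt / (2 * field$dx^2)  # D converted cm^2/s -> um^2/s
  src2 <- (field$S - field$U) * dt / 2
  g <- .bc_ghosts(bc)
  res <- .adi_core(field$Y, a, src2, g, g, g)
  Y <- res$new
  neg <- Y < 0
  ncl <- sum(neg)
  if (ncl > 0) {
    Y[neg] <- 0
    if (warn) {
      warning(sprintf("adi_step: clamped %d negative node(s) to zero", ncl))
    }
  }
  field$Y <- Y
  field$t <- field$t + dt
  field$n_clamped <- field$n_clamped + as.integer(ncl)
  field
}

#' Overlapping-tile layout for the Schwarz diffusion solver
#'
#' Describes how the domain is decomposed into an array of tiles extended
#' by `overlap` nodes on interior sides, and how many alternating-Schwarz
#' sweeps are performed per time step.
#'
#' @param tiles integer vector `c(tx, ty)`: tile grid.
#' @param overlap overlap width in nodes (>= 1).
#' @param iterations Schwarz sweeps per ADI step (>= 1).
#' @return An object of class `tile_layout`.
#' @export
tile_layout <- function(tiles = c(2, 2), overlap = 2, iterations = 3) {
  tiles <- as.integer(tiles)
  stopifnot(length(tiles) == 2, all(tiles >= 1))
  if (!is.finite(overlap) || overlap < 1) {
    stop("tile overlap must be at least 1 node")
  }
  stopifnot(is.finite(iterations), iterations >= 1)
  structure(list(tiles = tiles, overlap = as.integer(overlap),
                 iterations = as.integer(iterations)),
            class = "tile_layout")
}

# Contiguous owned ranges splitting n nodes into k chunks.
.tile_ranges <- function(n, k) {
  br <- floor(seq(0, n, length.out = k + 1))
  lapply(seq_len(k), function(i) c(br[i] + 1, br[i + 1]))
}

#' One ADI step by alternating-Schwarz domain decomposition
#'
#' Performs the same Peaceman--Rachford step as [adi_step()], but tile by
#' tile: each overlapping tile is solved with Dirichlet data on its
#' interior boundaries taken from the current global iterate (old-time
#' values for the explicit parts, latest intermediate/new-time estimates
#' for the implicit sweeps), sweeping the tiles in row-major order for the
#' configured number of iterations. As the iteration count or overlap
#' grows, the result converges to the monolithic [adi_step()]; a 1x1
#' layout reproduces it exactly. The contract permits (but this
#' implementation does not use) concurrent tile execution.
#'
#' @inheritParams adi_step
#' @param layout a [tile_layout()] compatible with the field shape.
#' @return The advanced `chemo_field`.
#' @export
schwarz_step <- function(field, layout, dt,
                         bc = c("zero-flux", "dirichlet-zero"),
                         warn = TRUE) {
  bc <- match.arg(bc)
  stopifnot(inherits(field, "chemo_field"), inherits(layout, "tile_layout"))
  n <- nrow(field$Y)
  m <- ncol(field$Y)
  if (layout$tiles[1] > n || layout$tiles[2] > m) {
    stop("tile layout has more tiles than grid lines")
  }
  a <- (field$D * 1e8) * dt / (2 * field$dx^2)
  src2 <- (field$S - field$U) * dt / 2
  Yold <- field$Y
  Ystar <- Yold
  Ynew <- Yold
  ov <- layout$overlap
  rx <- .tile_ranges(n, layout$tiles[1])
  ry <- .tile_ranges(m, layout$tiles[2])
  phys <- if (bc == "zero-flux") "reflect" else "zero"

  side_ghost <- function(M, idx, lo_edge, at_phys, along_rows) {
    # Dirichlet data just outside the tile from iterate M, or physical bc
    if (at_phys) return(phys)
    if (along_rows) {
      if (lo_edge) M[idx[1] - 1, idx[3]:idx[4]] else M[idx[2] + 1, idx[3]:idx[4]]
    } else {
      if (lo_edge) M[idx[1]:idx[2], idx[3] - 1] else M[idx[1]:idx[2], idx[4] + 1]
    }
  }

  for (it in seq_len(layout$iterations)) {
    for (ti in seq_along(rx)) {
      for (tj in seq_along(ry)) {
        r1 <- max(1, rx[[ti]][1] - ov); r2 <- min(n, rx[[ti]][2] + ov)
        c1 <- max(1, ry[[tj]][1] - ov); c2 <- min(m, ry[[tj]][2] + ov)
        idx <- c(r1, r2, c1, c2)
        ri <- r1:r2; ci <- c1:c2
        g_old <- list(
          x_lo = side_ghost(Yold, idx, TRUE, r1 == 1, TRUE),
          x_hi = side_ghost(Yold, idx, FALSE, r2 == n, TRUE),
          y_lo = side_ghost(Yold, idx, TRUE, c1 == 1, FALSE),
          y_hi = side_ghost(Yold, idx, FALSE, c2 == m, FALSE))
        g_star <- list(
          x_lo = side_ghost(Ystar, idx, TRUE, r1 == 1, TRUE),
          x_hi = side_ghost(Ystar, idx, FALSE, r2 == n, TRUE))
        g_new <- list(
          y_lo = side_ghost(Ynew, idx, TRUE, c1 == 1, FALSE),
          y_hi = side_ghost(Ynew, idx, FALSE, c2 == m, FALSE))
        res <- .adi_core(Yold[ri, ci, drop = FALSE], a,
                         src2[ri, ci, drop = FALSE], g_old, g_star, g_new)
        Ystar[ri, ci] <- res$star
        Ynew[ri, ci] <- res$new
      }
    }
  }
  neg <- Ynew < 0
  ncl <- sum(neg)
  if (ncl > 0) {
    Ynew[neg] <- 0
    if (warn) {
      warning(sprintf("schwarz_step: clamped %d negative node(s) to zero",
                      ncl))
    }
  }
  field$Y <- Ynew
  field$t <- field$t + dt
  field$n_clamped <- field$n_clamped + as.integer(ncl)
  field
}

#' Rebuild the uptake and secretion maps from the current cell population
#'
#' Heterogeneous-cluster cells contribute individually at their lattice
#' nodes: secretion at the constant per-cell rate, uptake proportional to
#' the local field value (`uptake_rate * Y`). Each homogeneous cluster is
#' treated as a single big "cell": the summed rates of its members are
#' spread uniformly over the cluster's high-resolution footprint.
#'
#' @param field a [chemo_field()].
#' @param cells data frame with high-resolution node columns `x`, `y`
#'   (1-based); may be empty.
#' @param cluster_map a [classify_clusters()] result (or `NULL` to treat
#'   every cell individually).
#' @param secretion per-cell secretion rate (nM/s).
#' @param uptake_rate per-cell uptake rate constant (1/s), applied to the
#'   local concentration.
#' @return The field with `U` and `S` replaced.
#' @export
deposit_sources <- function(field, cells, cluster_map = NULL,
                            secretion = 0.05, uptake_rate = 0.001) {
  shape <- dim(field$Y)
  U <- matrix(0, shape[1], shape[2])
  S <- matrix(0, shape[1], shape[2])
  if (is.null(cells) || nrow(cells) == 0) {
    field$U <- U
    field$S <- S
    return(field)
  }
  if (any(cells$x < 1 | cells$x > shape[1] | cells$y < 1 | cells$y > shape[2])) {
    stop("deposit_sources: cell off the lattice")
  }
  node <- cbind(cells$x, cells$y)
  upt <- uptake_rate * field$Y[node]
  if (is.null(cluster_map)) {
    homog <- rep(FALSE, nrow(cells))
  } else {
    r <- cluster_map$r
    site <- cbind((cells$x - 1) %/% r + 1, (cells$y - 1) %/% r + 1)
    homog <- cluster_map$labels[site] == "homogeneous"
  }
  # per-cell deposition for heterogeneous-cluster cells
  if (any(!homog)) {
    idx <- node[!homog, , drop = FALSE]
    S[idx] <- S[idx] + secretion
    U[idx] <- U[idx] + upt[!homog]
  }
  # aggregated deposition, one homogeneous cluster at a time
  if (any(homog)) {
    r <- cluster_map$r
    key <- paste(site[, 1], site[, 2])[homog]
    hidx <- which(homog)
    for (k in unique(key)) {
      members <- hidx[key == k]
      si <- site[members[1], ]
      rows <- ((si[1] - 1) * r + 1):min(si[1] * r, shape[1])
      cols <- ((si[2] - 1) * r + 1):min(si[2] * r, shape[2])
      foot <- length(rows) * length(cols)
      S[rows, cols] <- S[rows, cols] + length(members) * secretion / foot
      U[rows, cols] <- U[rows, cols] + sum(upt[members]) / foot
    }
  }
  field$U <- U
  field$S <- S
  field
}
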