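#' Coupled dual-resolution lattice
#'
#' The tumour lives on a fine lattice (one node per cell diameter, 10 um
#' spacing by default) nested inside a coarse lattice whose sites each
#' cover an `r x r` block of fine nodes. The coarse lattice carries the
#' cluster classification that decides where full intracellular
#' computation is spent. All indices are 1-based.
#'
#' @param shape_high integer `c(nx, ny)` of high-resolution nodes.
#' @param r nesting ratio: fine nodes per coarse-cell edge (default 6,
#'   i.e. a 60 um coarse cell at 10 um fine spacing).
#' @return An object of class `dual_lattice` with an integer occupancy
#'   matrix (`0` = empty, otherwise the occupying cell id).
#' @examples
#' L <- dual_lattice(c(60, 60), r = 6)
#' L$shape_low
#' @export
dual_lattice <- function(shape_high = c(120, 120), r = 6) {
  shape_high <- as.integer(shape_high)
  r <- as.integer(r)
  stopifnot(length(shape_high) == 2, all(shape_high >= 1), r >= 1)
  structure(list(occ = matrix(0L, shape_high[1], shape_high[2]),
                 r = r,
                 shape_high = shape_high,
                 shape_low = as.integer(ceiling(shape_high / r))),
            class = "dual_lattice")
}

#' @export
print.dual_lattice <- function(x, ...) {
  cat(sprintf("<dual_lattice> high %d x %d, low %d x %d (r = %d), %d cells\n",
              x$shape_high[1], x$shape_high[2], x$shape_low[1], x$shape_low[2],
              x$r, sum(x$occ != 0L)))
  invisible(x)
}

#' Place cells on a dual lattice
#'
#' @param lattice a [dual_lattice()].
#' @param x,y 1-based high-resolution node coordinates.
#' @param ids cell ids (default `1..n`).
#' @return The lattice with the occupancy map filled.
#' @export
place_cells <- function(lattice, x, y, ids = seq_along(x)) {
  stopifnot(inherits(lattice, "dual_lattice"), length(x) == length(y))
  if (any(x < 1 | x > lattice$shape_high[1] | y < 1 | y > lattice$shape_high[2])) {
    stop("cell coordinates off the lattice")
  }
  idx <- cbind(x, y)
  if (any(lattice$occ[idx] != 0L) || anyDuplicated(idx)) {
    stop("at most one cell per high-resolution node")
  }
  lattice$occ[idx] <- as.integer(ids)
  lattice
}

#' Map a high-resolution node to its low-resolution site
#'
#' Nodes `(1..r, 1..r)` belong to site `(1, 1)`, and so on (floor
#' division on 0-based coordinates).
#'
#' @param coord length-2 vector or 2-column matrix of 1-based fine-node
#'   coordinates.
#' @param lattice a [dual_lattice()] (bounds are checked), or a bare
#'   integer nesting ratio.
#' @return Same shape as `coord`: 1-based coarse-site coordinates.
#' @examples
#' high_to_low(c(14, 8), 6)  # -> site (3, 2)
#' @export
high_to_low <- function(coord, lattice) {
  r <- if (inherits(lattice, "dual_lattice")) lattice$r else as.integer(lattice)
  m <- if (is.matrix(coord)) coord else matrix(coord, ncol = 2)
  if (inherits(lattice, "dual_lattice")) {
    if (any(m[, 1] < 1 | m[, 1] > lattice$shape_high[1] |
              m[, 2] < 1 | m[, 2] > lattice$shape_high[2])) {
      stop("coordinate off the lattice")
    }
  } else if (any(m < 1)) {
    stop("coordinate off the lattice")
  }
  out <- (m - 1L) %/% r + 1L
  if (is.matrix(coord)) out else as.integer(out)
}

.occ_checksum <- function(occ) {
  w <- which(occ != 0L)
  c(length(w), sum(as.double(w)), sum(as.double(occ[w])))
}

#' Classify low-resolution sites as empty, heterogeneous or homogeneous
#'
#' A coarse site is *dense* when every affiliated fine node is occupied.
#' A dense site all of whose topographic neighbours (8-connected Moore
#' neighbourhood by default) are themselves dense is *homogeneous* --
#' these form the frozen tumour core treated as a single big "cell". Any
#' other occupied site is *heterogeneous* (the active rim). Sites on the
#' coarse-lattice edge are never homogeneous: missing neighbours count as
#' non-dense.
#'
#' @param lattice a [dual_lattice()].
#' @param neighbourhood `"moore"` (8-connected, default) or
#'   `"von-neumann"` (4-connected).
#' @return An object of class `cluster_map`: per-site occupant `counts`,
#'   logical `dense` flags and a character `labels` matrix in
#'   `{"empty", "heterogeneous", "homogeneous"}`.
#' @export
classify_clusters <- function(lattice, neighbourhood = c("moore", "von-neumann")) {
  neighbourhood <- match.arg(neighbourhood)
  stopifnot(inherits(lattice, "dual_lattice"))
  r <- lattice$r
  nl <- lattice$shape_low
  occ <- lattice$occ != 0L
  # occupant counts per coarse site via block aggregation
  site_row <- (seq_len(nrow(occ)) - 1L) %/% r + 1L
  site_col <- (seq_len(ncol(occ)) - 1L) %/% r + 1L
  counts <- matrix(0L, nl[1], nl[2])
  # aggregate fine rows into coarse rows, then fine columns into coarse columns
  by_row <- rowsum(occ + 0L, site_row, reorder = TRUE)
  counts[] <- t(rowsum(t(by_row), site_col, reorder = TRUE))
  blocksize <- tabulate(site_row, nl[1]) %o% tabulate(site_col, nl[2])
  dense <- counts > 0L & counts == blocksize
  shift <- function(M, di, dj) {
    out <- matrix(FALSE, nl[1], nl[2])
    ri <- seq_len(nl[1]) + di
    ci <- seq_len(nl[2]) + dj
    ok_r <- ri >= 1 & ri <= nl[1]
    ok_c <- ci >= 1 & ci <= nl[2]
    out[ok_r, ok_c] <- M[ri[ok_r], ci[ok_c]]
    out
  }
  offs <- if (neighbourhood == "moore") {
    list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
         c(1, -1), c(1, 0), c(1, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  }
  all_nb_dense <- matrix(TRUE, nl[1], nl[2])
  for (o in offs) all_nb_dense <- all_nb_dense & shift(dense, o[1], o[2])
  homogeneous <- dense & all_nb_dense
  labels <- matrix("empty", nl[1], nl[2])
  labels[counts > 0L] <- "heterogeneous"
  labels[homogeneous] <- "homogeneous"
  structure(list(counts = counts, dense = dense, labels = labels,
                 r = r, shape_high = lattice$shape_high, shape_low = nl,
                 neighbourhood = neighbourhood,
                 checksum = .occ_checksum(lattice$occ)),
            class = "cluster_map")
}

#' @export
print.cluster_map <- function(x, ...) {
  tab <- table(factor(x$labels, c("empty", "heterogeneous", "homogeneous")))
  cat(sprintf("<cluster_map> %d x %d sites: %d empty, %d heterogeneous, %d homogeneous\n",
              x$shape_low[1], x$shape_low[2], tab[1], tab[2], tab[3]))
  invisible(x)
}

#' Cells receiving full intracellular computation
#'
#' Returns the ids of all cells sitting in heterogeneous-labelled coarse
#' sites -- exactly the cells whose EGFR pathway is integrated and whose
#' phenotype can switch. Cells in homogeneous clusters are frozen until
#' reclassification. Errors if the occupancy map changed since the
#' cluster map was computed.
#'
#' @param lattice a [dual_lattice()].
#' @param cluster_map the matching [classify_clusters()] result.
#' @return Sorted integer vector of cell ids (possibly empty).
#' @export
active_cells <- function(lattice, cluster_map) {
  stopifnot(inherits(lattice, "dual_lattice"), inherits(cluster_map, "cluster_map"))
  if (!isTRUE(all.equal(.occ_checksum(lattice$occ), cluster_map$checksum))) {
    stop("stale cluster map: occupancy changed since classification")
  }
  w <- which(lattice$occ != 0L, arr.ind = TRUE)
  if (nrow(w) == 0) return(integer(0))
  site <- (w - 1L) %/% cluster_map$r + 1L
  het <- cluster_map$labels[site] == "heterogeneous"
  sort(lattice$occ[w[het, , drop = FALSE]])
}
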