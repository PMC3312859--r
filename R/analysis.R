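#' Population series of a run
#'
#' @param x a `gbm_sim` (mean across replicates), a [gbm_collect()] list
#'   or a `gbm_state`.
#' @return Tibble with `step`, `proliferative`, `migratory`, `quiescent`,
#'   `total`.
#' @export
population_series <- function(x) {
  if (inherits(x, "gbm_sim")) return(x$population_mean)
  if (inherits(x, "gbm_state")) x <- gbm_collect(x)
  x$population
}

#' Steps where the proliferation and migration curves cross
#'
#' Scans the sign of `proliferative - migratory` along the series and
#' reports every step whose sign differs from the previous step's, the
#' later step of each pair. A difference of exactly zero is treated as a
#' crossing, so two identical curves flag every step after the first
#' (documented degenerate behaviour).
#'
#' @param series a tibble with `proliferative` and `migratory` columns
#'   (e.g. from [population_series()]).
#' @return Integer vector of 1-based step indices (possibly empty).
#' @examples
#' find_crossings(tibble::tibble(migratory = c(5, 8, 10),
#'                               proliferative = c(9, 7, 11)))  # 2 3
#' @export
find_crossings <- function(series) {
  stopifnot(nrow(series) >= 1)
  d <- series$proliferative - series$migratory
  if (length(d) == 1) return(integer(0))
  s <- sign(d)
  idx <- which(s[-1] != s[-length(s)] | d[-1] == 0) + 1L
  as.integer(idx)
}

#' Cohort-mean molecular profiles of phenotype switches
#'
#' Averages the per-species percentage rates of change across all cells
#' that switched phenotype, separately for each direction (PM:
#' proliferation to migration; MP: the reverse). Undefined rates are
#' excluded per species, with the exclusion count reported.
#'
#' @param events a switch-event tibble (from [gbm_collect()] or a run),
#'   with a `direction` column and rate columns `X1..X10`.
#' @return A tibble of class `switch_profile`: one row per direction x
#'   species with `mean_rate`, `cohort` size and `n_excluded`.
#' @export
switch_profiles <- function(events) {
  species <- .species_names[-1]
  if (is.null(events) || nrow(events) == 0 || !"direction" %in% names(events)) {
    events <- tibble::as_tibble(c(list(direction = character(0)),
                                  setNames(rep(list(numeric(0)), 10), species)))
  }
  out <- lapply(c("PM", "MP"), function(dir) {
    ev <- events[events$direction == dir, , drop = FALSE]
    tibble::tibble(
      direction = dir,
      species = factor(species, levels = species),
      mean_rate = vapply(species, function(sp) {
        v <- ev[[sp]]
        v <- v[is.finite(v)]
        if (length(v) == 0) NA_real_ else mean(v)
      }, numeric(1)),
      cohort = nrow(ev),
      n_excluded = vapply(species, function(sp) {
        sum(!is.finite(ev[[sp]]))
      }, numeric(1)))
  })
  structure(dplyr::bind_rows(out), class = c("switch_profile",
                                             class(dplyr::bind_rows(out))))
}

#' Heatmap-ready matrix of switch profiles
#'
#' @param profiles a [switch_profiles()] result.
#' @return Numeric matrix species x direction of mean rates.
#' @export
profile_matrix <- function(profiles) {
  m <- matrix(profiles$mean_rate, ncol = 2,
              dimnames = list(as.character(unique(profiles$species)),
                              c("PM", "MP")))
  m
}

#' Position history of a single cell
#'
#' @param x a `gbm_sim` (first replicate), [gbm_collect()] list or
#'   `gbm_state`.
#' @param cell_id the cell to trace.
#' @return Tibble `step`, `x`, `y`, gap-free from the cell's birth step.
#' @export
trajectory <- function(x, cell_id) {
  if (inherits(x, "gbm_sim")) x <- x$replicates[[1]]
  if (inherits(x, "gbm_state")) x <- gbm_collect(x)
  tr <- dplyr::filter(x$cells, .data$id == cell_id) |>
    dplyr::arrange(.data$step) |>
    dplyr::select("step", "x", "y")
  if (nrow(tr) == 0) stop("unknown cell id: ", cell_id)
  if (!all(diff(tr$step) == 1)) stop("gap in trajectory of cell ", cell_id)
  tr
}

# --- broom-style methods ----------------------------------------------------

#' Tidy the population curves of a run
#'
#' @param x a `gbm_sim`.
#' @param ... unused.
#' @return Long tibble: `replicate`, `step`, `phenotype`, `count`.
#' @export
tidy.gbm_sim <- function(x, ...) {
  tidyr::pivot_longer(x$population,
                      c("proliferative", "migratory", "quiescent", "total"),
                      names_to = "phenotype", values_to = "count") |>
    dplyr::select("replicate", "step", "phenotype", "count")
}

#' One-row summary of a run
#'
#' @param x a `gbm_sim`.
#' @param ... unused.
#' @return Tibble with steps, replicates, final mean counts, the number
#'   of proliferation/migration crossings of the mean curves and the
#'   total number of switch events.
#' @export
glance.gbm_sim <- function(x, ...) {
  fin <- dplyr::filter(x$population_mean, .data$step == max(.data$step))
  tibble::tibble(
    steps = max(x$population$step),
    replicates = length(x$replicates),
    final_total = fin$total,
    final_proliferative = fin$proliferative,
    final_migratory = fin$migratory,
    n_crossings = length(find_crossings(x$population_mean)),
    n_switch_events = sum(vapply(x$replicates,
                                 function(r) nrow(r$switch_events),
                                 numeric(1))))
}

# --- figures ----------------------------------------------------------------

#' Population curves (migratory red, proliferative blue, total black)
#'
#' @param object a `gbm_sim`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot gbm_sim
#' @export
autoplot.gbm_sim <- function(object, ...) {
  df <- tidyr::pivot_longer(object$population_mean,
                            c("migratory", "proliferative", "total"),
                            names_to = "phenotype", values_to = "count")
  ggplot2::ggplot(df, ggplot2::aes(.data$step, .data$count,
                                   colour = .data$phenotype)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_colour_manual(values = c(migratory = "red",
                                            proliferative = "blue",
                                            total = "black")) +
    ggplot2::labs(x = "time step (h)", y = "number of tumour cells",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of switch-event molecular profiles
#'
#' Colour is min-max scaled per figure; the unscaled numbers are available
#' via [profile_matrix()] and are always written alongside rendered
#' figures, so numeric output, not colour, is the reference.
#'
#' @param profiles a [switch_profiles()] result.
#' @return A ggplot.
#' @export
plot_switch_profiles <- function(profiles) {
  df <- dplyr::filter(profiles, is.finite(.data$mean_rate))
  ggplot2::ggplot(df, ggplot2::aes(.data$direction, .data$species,
                                   fill = .data$mean_rate)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "mean % rate\n(per step)") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Low-resolution cluster map (black heterogeneous, green homogeneous)
#'
#' @param labels integer label matrix (0 empty / 1 heterogeneous /
#'   2 homogeneous) or a `cluster_map`.
#' @return A ggplot.
#' @export
plot_cluster_map <- function(labels) {
  if (inherits(labels, "cluster_map")) labels <- .labels_int(labels$labels)
  df <- expand.grid(x = seq_len(nrow(labels)), y = seq_len(ncol(labels)))
  df$label <- factor(labels[cbind(df$x, df$y)], levels = 0:2,
                     labels = c("empty", "heterogeneous", "homogeneous"))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$label)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(empty = "white",
                                          heterogeneous = "black",
                                          homogeneous = "green3"),
                               drop = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "low-res x", y = "low-res y", fill = NULL) +
    ggplot2::theme_minimal()
}

#' High-resolution phenotype map (red migratory, blue proliferative,
#' green quiescent)
#'
#' @param cells a per-step cell tibble (`x`, `y`, `phenotype`).
#' @param shape optional `c(nx, ny)` lattice extent for fixed axes.
#' @return A ggplot.
#' @export
plot_phenotype_map <- function(cells, shape = NULL) {
  p <- ggplot2::ggplot(cells, ggplot2::aes(.data$x, .data$y,
                                           colour = .data$phenotype)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(values = c(migratory = "red",
                                            proliferative = "blue",
                                            quiescent = "green3")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "high-res x", y = "high-res y", colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(shape)) {
    p <- p + ggplot2::xlim(1, shape[1]) + ggplot2::ylim(1, shape[2])
  }
  p
}

#' Single-cell trajectory over time
#'
#' The position history is drawn in the (x, y) plane with the time step
#' encoded as colour (a planar rendering of the step-x-y curve).
#'
#' @param traj a [trajectory()] tibble.
#' @return A ggplot.
#' @export
plot_trajectory <- function(traj) {
  ggplot2::ggplot(traj, ggplot2::aes(.data$x, .data$y,
                                     colour = .data$step)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_colour_viridis_c(name = "step (h)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "high-res x", y = "high-res y") +
    ggplot2::theme_minimal()
}

#' Render all standard figures and their numeric tables
#'
#' Writes the population curves, the switch-profile heatmap, the final
#' cluster and phenotype maps and one cell trajectory to `out_dir`, each
#' figure paired with the CSV holding its exact numbers. Inputs are not
#' modified.
#'
#' @param sim a `gbm_sim`.
#' @param out_dir output directory (created if needed).
#' @param cell_id cell to trace (default: cell 1).
#' @return Invisibly, the written file paths.
#' @export
render_figures <- function(sim, out_dir, cell_id = 1L) {
  stopifnot(inherits(sim, "gbm_sim"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  save_pair <- function(plot, df, stem) {
    fp <- file.path(out_dir, paste0(stem, ".png"))
    fc <- file.path(out_dir, paste0(stem, ".csv"))
    ggplot2::ggsave(fp, plot, width = 6, height = 4.5, dpi = 150)
    write.csv(df, fc, row.names = FALSE)
    c(fp, fc)
  }
  paths <- c(paths, save_pair(autoplot.gbm_sim(sim), sim$population_mean,
                              "population"))
  rep1 <- sim$replicates[[1]]
  prof <- switch_profiles(rep1$switch_events)
  paths <- c(paths, save_pair(plot_switch_profiles(prof),
                              as.data.frame(prof), "switch_profiles"))
  last <- length(rep1$clusters)
  if (last > 0) {
    lab <- rep1$clusters[[last]]
    paths <- c(paths,
               save_pair(plot_cluster_map(lab), as.data.frame(lab),
                         sprintf("clusters_step%03d", last)))
    cells_last <- dplyr::filter(rep1$cells, .data$step == last)
    paths <- c(paths,
               save_pair(plot_phenotype_map(cells_last,
                                            sim$config$lattice$shape_high),
                         cells_last, sprintf("phenotypes_step%03d", last)))
    if (nrow(rep1$cells) > 0 && cell_id %in% rep1$cells$id) {
      tr <- trajectory(rep1, cell_id)
      paths <- c(paths, save_pair(plot_trajectory(tr), tr,
                                  sprintf("trajectory_cell%03d", cell_id)))
    }
  }
  invisible(paths)
}
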