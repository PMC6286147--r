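#' @export
print.polarsim_run <- function(x, ...) {
  cat(sprintf("<polarsim_run: %s> %d cells at time %g\n",
              x$name, n_cells(x$state), state_time(x$state)))
  cat(sprintf("  seed %s; %d sampled metric rows; %d frames\n",
              format(x$manifest$seed), nrow(x$metrics), length(x$frames)))
  invisible(x)
}

#' Tidy methods for simulation results
#'
#' `tidy()` returns the per-sample metrics time series (one row per sampled
#' step: time, mean/sd energy per cell, mean/sd neighbor count, and cell
#' count where it varies); `glance()` a one-row summary of the final state.
#'
#' @param x A `polarsim_run`, `polarsim_sim`, or `polarsim_growth`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.polarsim_run <- function(x, ...) x$metrics

#' @rdname tidy.polarsim_run
#' @export
tidy.polarsim_sim <- function(x, ...) x$metrics

#' @rdname tidy.polarsim_run
#' @export
tidy.polarsim_growth <- function(x, ...) x$metrics

glance_state <- function(state, graph, extra = list()) {
  e <- energy_per_cell(state, graph)
  deg <- degrees(graph)
  out <- tibble::tibble(
    n_cells = n_cells(state), time = state_time(state),
    energy_mean = mean(e), neighbors_mean = mean(deg),
    n_local_minima = count_local_minima(state, graph),
    n_shells = count_shells(state, graph))
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  out
}

#' @rdname tidy.polarsim_run
#' @export
glance.polarsim_run <- function(x, ...) {
  extra <- list(scenario = x$name)
  if (!is.null(x$axes)) {
    extra$semi_major <- x$axes[["semi_major"]]
    extra$semi_minor <- x$axes[["semi_minor"]]
  }
  glance_state(x$state, x$graph, extra)
}

#' @rdname tidy.polarsim_run
#' @export
glance.polarsim_sim <- function(x, ...) glance_state(x$state, x$graph)

#' @rdname tidy.polarsim_run
#' @export
glance.polarsim_growth <- function(x, ...)
  glance_state(x$state, x$graph, list(n_divisions = nrow(x$divisions)))

#' Plot simulation metrics or states
#'
#' `autoplot()` on a run draws the energy-per-cell and neighbors-per-cell
#' time series; on a `cell_state` it draws a 2D projection of the cells
#' colored by the chosen AB-polarity component.
#'
#' @param object A `polarsim_run`/`polarsim_sim` or a `cell_state`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.polarsim_run <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$metrics[c("time", "energy_mean", "neighbors_mean")],
    -"time", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "time", y = NULL)
}

#' @rdname autoplot.polarsim_run
#' @export
autoplot.polarsim_sim <- autoplot.polarsim_run

#' @rdname autoplot.polarsim_run
#' @param axes Which position columns to project onto (default x, z).
#' @export
autoplot.cell_state <- function(object, axes = c("x", "z"), ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data[[axes[1]]], y = .data[[axes[2]]],
                               color = .data$pz)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::scale_color_gradient2(low = "#b2182b", mid = "#f7f7f7",
                                   high = "#2166ac") +
    ggplot2::labs(color = "AB z")
}

#' @rdname autoplot.polarsim_run
#' @param state A `cell_state`.
#' @export
plot_state <- function(state, axes = c("x", "z"), ...) {
  autoplot.cell_state(state, axes = axes, ...)
}
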