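#' Divide a cell
#'
#' Adds a daughter cell half a cell radius away from the mother in a uniformly
#' random direction. The daughter inherits the mother's polarity directions,
#' lambda weights, and flags bitwise.
#'
#' @param state A `cell_state`.
#' @param mother Index of the dividing cell.
#' @return The `cell_state` with one more row (the daughter appended last).
#' @examples
#' st <- make_hollow_sphere(20)
#' n_cells(divide_cell(st, 5))
#' @export
divide_cell <- function(state, mother) {
  n <- n_cells(state)
  if (!is.numeric(mother) || length(mother) != 1 || mother < 1 || mother > n)
    abort("`mother` must be a valid cell index")
  u <- rnorm(3)
  u <- u / sqrt(sum(u^2))
  daughter <- state[mother, ]
  daughter$x <- daughter$x + 0.5 * u[1]
  daughter$y <- daughter$y + 0.5 * u[2]
  daughter$z <- daughter$z + 0.5 * u[3]
  out <- dplyr::bind_rows(state, daughter)
  tibble::new_tibble(out, time = state_time(state), class = "cell_state")
}

#' Exponential growth schedule
#'
#' The population target is `N(t) = n0 * exp(log(2) * t / generation_time)`,
#' i.e. the population doubles every generation time.
#'
#' @param n0 Initial cell count (200 in the organoid simulations).
#' @param generation_time Doubling time `t_G` (time units).
#' @param n_max Stop size.
#' @return A `growth_schedule` object.
#' @export
growth_schedule <- function(n0 = 200, generation_time, n_max) {
  if (n_max < n0) abort("`n_max` must be >= `n0`")
  if (generation_time <= 0) abort("`generation_time` must be positive")
  structure(list(n0 = as.integer(n0), generation_time = generation_time,
                 n_max = as.integer(n_max)),
            class = "growth_schedule")
}

#' @rdname growth_schedule
#' @param schedule A `growth_schedule`.
#' @param t Time (vectorized).
#' @return `target_count()` returns `floor(N(t))`, capped at `n_max`.
#' @export
target_count <- function(schedule, t) {
  pmin(schedule$n_max,
       floor(schedule$n0 * exp(log(2) * t / schedule$generation_time)))
}

#' Grow a proliferating aggregate
#'
#' Drives the dynamics while cells divide on the exponential schedule:
#' whenever the realized count falls below the scheduled `floor(N(t))`,
#' uniformly random mothers divide (between integration steps; several
#' divisions per step are allowed) until the counts match; the run stops when
#' `n_max` is reached and `extra_time` more time has elapsed. The AB angle
#' gate is conventionally enabled for these simulations via `config`.
#'
#' @param state A `cell_state` with `schedule$n0` cells.
#' @param schedule A [growth_schedule()].
#' @param config A [model_config()]; pass `angle_gate = TRUE` to reproduce
#'   the organoid setting.
#' @param fields An [external_fields()] or `NULL`.
#' @param extra_time Additional time integrated after `n_max` is reached.
#' @param sample_every Metric/frame sampling stride (in steps).
#' @param save_frames Keep sampled frames.
#' @return A list of class `polarsim_growth`: `state`, `metrics`, `frames`,
#'   `graph` as in [simulate_cells()], plus `divisions`, a tibble logging
#'   every division (time, mother, daughter, position).
#' @export
grow_organoid <- function(state, schedule, config = model_config(),
                          fields = NULL, extra_time = 0,
                          sample_every = 50, save_frames = FALSE) {
  if (n_cells(state) != schedule$n0)
    abort("`state` must start with `schedule$n0` cells")
  fields <- fields %||% external_fields()
  if (!is.null(fields$force_mask))
    abort("per-cell force masks are not supported while cells divide")
  dt <- config$dt
  divisions <- list()
  metrics <- list()
  frames <- list()
  repeat {
    t <- state_time(state)
    n <- n_cells(state)
    while (n < target_count(schedule, t)) {
      mother <- sample.int(n, 1)
      state <- divide_cell(state, mother)
      n <- n + 1
      divisions[[length(divisions) + 1]] <- tibble::tibble(
        time = t, mother = mother, daughter = n,
        x = state$x[n], y = state$y[n], z = state$z[n])
    }
    if (n >= schedule$n_max) break
    # integrate up to the next scheduled division (at least one step)
    t_next <- schedule$generation_time * log2((n + 1) / schedule$n0)
    chunk <- max(1, ceiling((t_next - t) / dt - 1e-9))
    sim <- simulate_cells(state, chunk, config, fields,
                          sample_every = sample_every,
                          save_frames = save_frames)
    state <- sim$state
    metrics[[length(metrics) + 1]] <-
      dplyr::mutate(sim$metrics, n_cells = n)
    frames <- c(frames, sim$frames)
  }
  if (extra_time > 0) {
    sim <- simulate_cells(state, ceiling(extra_time / dt), config, fields,
                          sample_every = sample_every,
                          save_frames = save_frames)
    state <- sim$state
    metrics[[length(metrics) + 1]] <-
      dplyr::mutate(sim$metrics, n_cells = n_cells(state))
    frames <- c(frames, sim$frames)
  }
  final <- simulate_cells(state, 0, config, fields, sample_every = 1)
  metrics[[length(metrics) + 1]] <-
    dplyr::mutate(final$metrics, n_cells = n_cells(state))
  structure(list(
    state = state,
    metrics = dplyr::distinct(dplyr::bind_rows(metrics), .data$time,
                              .keep_all = TRUE),
    frames = frames, graph = final$graph,
    divisions = dplyr::bind_rows(divisions)),
    class = "polarsim_growth")
}
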