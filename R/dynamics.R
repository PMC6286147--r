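#' Advance a cell state in time
#'
#' Integrates the overdamped dynamics with the Euler method: each cell's
#' position and polarity rates are the negative gradients of its summed pair
#' potential plus uncorrelated Gaussian noise `eta * xi`, polarities are
#' renormalized after every step, and the neighbor graph is recomputed every
#' `config$neighbor_stride` steps. Cells flagged `fixed` keep their
#' polarities bitwise; cells flagged in-plane (see `pcp_in_plane`) drop the
#' S2 term from their AB update and have PCP re-projected orthogonal to the
#' updated AB polarity each step. External fields (medium pressure on
#' positions, the gastrulation force on AB polarity) are added when supplied.
#'
#' @param state A `cell_state`.
#' @param n_steps Number of Euler steps.
#' @param config A [model_config()].
#' @param fields An [external_fields()] or `NULL`.
#' @param pcp_in_plane Logical vector (recycled) marking cells whose PCP is
#'   confined to the apical plane; defaults to none.
#' @param sample_every Record metrics (and frames) every this many steps.
#' @param save_frames Keep sampled state frames (positions + polarities).
#' @param s_const If non-negative, override the polarity coupling with a
#'   constant attraction `S` (non-polar cells); used for relaxation.
#' @return A list of class `polarsim_sim`: `state` (final `cell_state`),
#'   `metrics` (tibble with per-sample time, mean/sd energy per cell, mean/sd
#'   neighbor count), `frames` (list of sampled frames if requested), and
#'   `graph` (final `neighbor_graph`).
#' @examples
#' st <- make_hollow_sphere(100)
#' st <- apply_polarity_field(st, "radial_point")
#' out <- simulate_cells(st, 10, model_config(eta = 0))
#' @export
simulate_cells <- function(state, n_steps, config = model_config(),
                           fields = NULL, pcp_in_plane = NULL,
                           sample_every = max(1, n_steps %/% 50),
                           save_frames = FALSE, s_const = -1) {
  stopifnot(inherits(config, "model_config"))
  if (n_steps < 0) abort("`n_steps` must be >= 0")
  n <- n_cells(state)
  fields <- fields %||% external_fields()
  inplane <- rep_len(pcp_in_plane %||% FALSE, n)
  fmask <- fields$force_mask %||% rep(TRUE, n)
  if (length(fmask) != n) abort("`force_mask` must have one entry per cell")
  mode <- match(config$neighbor_mode, c("line_of_sight", "voronoi_cutoff")) - 1L
  res <- simulate_cpp(
    positions(state), ab_polarity(state), pcp_polarity(state), lambdas(state),
    state$fixed, inplane, as.integer(n_steps), config$dt, config$beta,
    config$potential_exponent, config$eta_pos, config$eta_ab, config$eta_pcp,
    config$angle_gate, s_const, mode, config$cutoff,
    as.integer(min(config$prefilter_k, n - 1)), config$neighbor_stride,
    fields$pressure, fields$force_k, fields$force_sigma, fmask,
    state_time(state), as.integer(sample_every), save_frames)
  out_state <- cell_state(res$positions, ab = res$ab, pcp = res$pcp,
                          lambda = lambdas(state), fixed = state$fixed,
                          pcp_active = state$pcp_active, time = res$time)
  g <- tibble::new_tibble(
    tibble::tibble(i = as.integer(res$edges[, 1]),
                   j = as.integer(res$edges[, 2])),
    n = n, class = "neighbor_graph")
  structure(list(state = out_state,
                 metrics = tibble::as_tibble(res$metrics),
                 frames = res$frames, graph = g),
            class = "polarsim_sim")
}

#' @rdname simulate_cells
#' @details `step_cells()` performs a single Euler step and returns the new
#'   `cell_state`.
#' @export
step_cells <- function(state, config = model_config(), fields = NULL,
                       pcp_in_plane = NULL) {
  simulate_cells(state, 1, config, fields, pcp_in_plane,
                 sample_every = 1, save_frames = FALSE)$state
}

#' Medium-resistance (pressure) force
#'
#' Force exerted by a stiff growth medium: every cell is pushed toward the
#' center of mass with magnitude `P * r / r_max`, where `r` is the cell's
#' distance from the center of mass and `r_max` the largest such distance.
#' The force at the periphery is therefore constant (magnitude `P`) as the
#' aggregate grows, while cells deep inside folds feel less resistance.
#'
#' @param positions N x 3 matrix (or data frame with `x, y, z`).
#' @param P Medium stiffness (>= 0).
#' @param center Center of mass; computed from `positions` by default.
#' @return N x 3 matrix of forces. All-zero when `P = 0` or all cells
#'   coincide (`r_max = 0`).
#' @export
pressure_force <- function(positions, P, center = NULL) {
  if (is.data.frame(positions)) positions <- positions(positions)
  positions <- as_matrix3(positions, "positions")
  if (P < 0) abort("`P` must be >= 0")
  center <- center %||% colMeans(positions)
  rel <- sweep(positions, 2, center)
  rmax <- sqrt(max(rowSums(rel^2)))
  if (P == 0 || rmax == 0) return(matrix(0, nrow(positions), 3))
  -P / rmax * rel
}

#' Gastrulation force on AB polarity
#'
#' The external field used to trigger invagination: for each selected cell,
#' `F = -k * rhat_perp * exp(-(x^2 + y^2) / sigma^2)` is added to the AB
#' polarity rate before renormalization, where `rhat_perp` is the unit vector
#' from the z-axis (the anterior-posterior axis) to the cell in the xy-plane.
#' The force is strongest for cells near the axis and reorients their AB
#' polarity so the epithelial sheet bends; cells exactly on the axis have no
#' defined direction and receive zero force.
#'
#' @param positions N x 3 matrix (or data frame with `x, y, z`).
#' @param k Force strength.
#' @param sigma Gaussian width (> 0).
#' @param mask Logical vector selecting affected cells (default all).
#' @return N x 3 matrix of AB-polarity rate contributions.
#' @export
gastrulation_ab_force <- function(positions, k, sigma, mask = NULL) {
  if (is.data.frame(positions)) positions <- positions(positions)
  positions <- as_matrix3(positions, "positions")
  if (sigma <= 0) abort("`sigma` must be > 0")
  n <- nrow(positions)
  mask <- rep_len(mask %||% TRUE, n)
  out <- matrix(0, n, 3)
  rho2 <- positions[, 1]^2 + positions[, 2]^2
  rho <- sqrt(rho2)
  sel <- mask & rho >= 1e-12
  g <- -k * exp(-rho2[sel] / sigma^2) / rho[sel]
  out[sel, 1] <- g * positions[sel, 1]
  out[sel, 2] <- g * positions[sel, 2]
  out
}
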