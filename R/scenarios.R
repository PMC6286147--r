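new_run <- function(name, sim, manifest, extra = list()) {
  structure(c(list(name = name, state = sim$state, metrics = sim$metrics,
                   frames = sim$frames, graph = sim$graph,
                   manifest = manifest), extra),
            class = "polarsim_run")
}

run_manifest <- function(name, seed, config, params) {
  list(scenario = name, seed = seed,
       config = unclass(config)[setdiff(names(config), "seed")],
       params = params,
       package_version = as.character(utils::packageVersion("polarsim")),
       created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Scenario: bulk aggregate with random AB polarity
#'
#' A compact aggregate of AB-polarized cells with uniformly random polarity
#' directions expands rapidly and then locks into a stable, interconnected
#' channel morphology; the energy per cell drops fast and plateaus above the
#' hollow-sphere reference energy for the same cell count.
#'
#' @param n Number of cells (>= 100 for a meaningful morphology).
#' @param eta Noise amplitude.
#' @param t_end Simulated time.
#' @param dt Time step.
#' @param seed RNG seed (controls initial state and noise).
#' @param neighbor_stride Steps between neighbor-graph rebuilds.
#' @param sample_every Sampling stride (steps).
#' @param save_frames Keep sampled frames.
#' @return A `polarsim_run` with the trajectory metrics; `$reference_energy`
#'   holds the mean energy per cell of a relaxed radially-polarized hollow
#'   sphere with the same `n`.
#' @export
scenario_bulk_random <- function(n = 1000, eta = 1e-4, t_end = 1000,
                                 dt = 0.2, seed = 1, neighbor_stride = 2,
                                 sample_every = 100, save_frames = FALSE) {
  if (n < 100) abort("`n` must be >= 100")
  set.seed(seed)
  config <- model_config(dt = dt, eta = eta,
                         neighbor_stride = neighbor_stride)
  st <- make_bulk_aggregate(n)
  sim <- simulate_cells(st, ceiling(t_end / dt), config,
                        sample_every = sample_every,
                        save_frames = save_frames)
  ref <- reference_sphere_energy(n, config)
  new_run("bulk_random", sim,
          run_manifest("bulk_random", seed, config,
                       list(n = n, eta = eta, t_end = t_end, dt = dt)),
          list(reference_energy = ref))
}

#' Reference hollow-sphere energy
#'
#' Mean energy per cell of a hollow sphere with radially-fixed AB polarity
#' after noiseless relaxation — the configuration reached from radially
#' polarized initial conditions with polarization preserved at all times.
#'
#' @param n Number of cells.
#' @param config A [model_config()].
#' @param relax_time Relaxation time.
#' @return Mean energy per cell (scalar).
#' @export
reference_sphere_energy <- function(n, config = model_config(),
                                    relax_time = 100) {
  st <- make_hollow_sphere(n)
  st <- apply_polarity_field(st, "radial_point", fix = TRUE)
  cfg <- config
  cfg$eta_pos <- cfg$eta_ab <- cfg$eta_pcp <- 0
  sim <- simulate_cells(st, ceiling(relax_time / cfg$dt), cfg,
                        sample_every = ceiling(relax_time / cfg$dt))
  mean(energy_per_cell(sim$state, sim$graph, cfg))
}

#' Scenario: boundary-condition morphologies
#'
#' From a compact aggregate, fixed AB-polarity boundary fields select the
#' morphology: radially-out from the center gives a single hollow sphere,
#' radially-out from a central axis a hollow tube, away from a central plane
#' two parallel sheets. With the same symmetric (radial) initial polarities
#' left free to rotate and high noise (`eta = 1`), the aggregate instead
#' resolves into nested hollow spheres that never merge because of opposing
#' polarities.
#'
#' @param field `"radial_point"`, `"radial_axis"`, `"planar"`, or
#'   `"dynamic_high_noise"`.
#' @param n Number of cells.
#' @param t_end Simulated time.
#' @param eta Noise amplitude; defaults to 0.1 for the fixed fields and 1.0
#'   for `dynamic_high_noise`.
#' @param dt,seed,neighbor_stride,sample_every,save_frames As in
#'   [scenario_bulk_random()].
#' @return A `polarsim_run`.
#' @export
scenario_boundary <- function(field = c("radial_point", "radial_axis",
                                        "planar", "dynamic_high_noise"),
                              n = 1000, t_end = 300, eta = NULL, dt = 0.2,
                              seed = 1, neighbor_stride = 2,
                              sample_every = 100, save_frames = FALSE) {
  field <- match.arg(field)
  dynamic <- field == "dynamic_high_noise"
  eta <- eta %||% (if (dynamic) 1.0 else 0.1)
  set.seed(seed)
  config <- model_config(dt = dt, eta = eta,
                         neighbor_stride = neighbor_stride)
  st <- make_bulk_aggregate(n)
  st <- apply_polarity_field(st, if (dynamic) "radial_point" else field,
                             fix = !dynamic)
  sim <- simulate_cells(st, ceiling(t_end / dt), config,
                        sample_every = sample_every,
                        save_frames = save_frames)
  new_run("boundary", sim,
          run_manifest("boundary", seed, config,
                       list(field = field, n = n, eta = eta, t_end = t_end,
                            dt = dt)))
}

#' Scenario: growing organoid (growth- vs pressure-driven folding)
#'
#' An organoid seeded as a small hollow sphere grows exponentially from
#' `n0` cells. Slow growth (large `t_G`) keeps the system near equilibrium
#' and it expands as a sphere; fast growth pushes it out of equilibrium and
#' folds (local minima) appear. Alternatively, external medium pressure `P`
#' folds even slowly-growing organoids, producing fewer but deeper folds.
#' The AB angle gate is enabled, as in all growing-organoid simulations.
#'
#' @param mode `"growth"` (vary `t_G`, `P = 0`) or `"pressure"` (fix `t_G`,
#'   vary `P`).
#' @param t_G Generation (doubling) time.
#' @param P Medium stiffness (pressure mode).
#' @param n_max Final cell count.
#' @param n0 Initial cell count (default 200).
#' @param extra_time Relaxation time integrated after reaching `n_max`.
#' @param dt,seed,neighbor_stride,sample_every,save_frames As in
#'   [scenario_bulk_random()].
#' @return A `polarsim_run`; `$divisions` logs every division and
#'   `$fold_metrics` the per-frame local-minima counts (when frames are
#'   saved).
#' @export
scenario_organoid <- function(mode = c("growth", "pressure"), t_G = 200,
                              P = 0, n_max = 1000, n0 = 200, extra_time = 0,
                              dt = 0.2, seed = 1, neighbor_stride = 2,
                              sample_every = 100, save_frames = FALSE) {
  mode <- match.arg(mode)
  if (mode == "growth") P <- 0
  if (mode == "pressure" && P < 0) abort("`P` must be >= 0")
  set.seed(seed)
  config <- model_config(dt = dt, angle_gate = TRUE,
                         neighbor_stride = neighbor_stride)
  st <- make_hollow_sphere(n0)
  st <- apply_polarity_field(st, "radial_point", fix = FALSE)
  sched <- growth_schedule(n0 = n0, generation_time = t_G, n_max = n_max)
  fields <- external_fields(pressure = P)
  res <- grow_organoid(st, sched, config, fields, extra_time = extra_time,
                       sample_every = sample_every,
                       save_frames = save_frames)
  sim <- list(state = res$state, metrics = res$metrics, frames = res$frames,
              graph = res$graph)
  run <- new_run("organoid", sim,
                 run_manifest("organoid", seed, config,
                              list(mode = mode, t_G = t_G, P = P,
                                   n_max = n_max, n0 = n0, dt = dt,
                                   extra_time = extra_time)),
                 list(divisions = res$divisions))
  run$n_local_minima <- count_local_minima(run$state, run$graph)
  run
}

#' Scenario: PCP-driven tube formation
#'
#' A hollow sphere of cells with whirling PCP elongates by convergent
#' extension into a tube whose length and width are set by the PCP strength
#' `lambda3` relative to the AB strength `lambda1 = 1 - lambda2 - lambda3`.
#' With `pcp_in_plane = TRUE`, PCP is confined to the apical plane (no
#' back-action on AB polarity); tubes still form.
#'
#' @param lambda3 PCP strength.
#' @param n Number of cells (1000 in the reference sweep).
#' @param lambda2 AB-PCP orthogonality strength (0.5 in the reference
#'   sweep).
#' @param t_end Simulated time.
#' @param pcp_in_plane Confine PCP to the apical plane.
#' @param eta Noise amplitude.
#' @param dt,seed,neighbor_stride,sample_every,save_frames As in
#'   [scenario_bulk_random()].
#' @return A `polarsim_run`; `$axes` holds the final [tube_axes()].
#' @export
scenario_tube <- function(lambda3, n = 1000, lambda2 = 0.5, t_end = 1000,
                          pcp_in_plane = FALSE, eta = 1e-4, dt = 0.2,
                          seed = 1, neighbor_stride = 2, sample_every = 250,
                          save_frames = FALSE) {
  lambda1 <- 1 - lambda2 - lambda3
  if (lambda1 < 0 || lambda3 < 0)
    abort("need lambda1 = 1 - lambda2 - lambda3 >= 0 and lambda3 >= 0")
  set.seed(seed)
  config <- model_config(dt = dt, eta = eta,
                         neighbor_stride = neighbor_stride)
  st <- make_hollow_sphere(n, pcp_whirl = TRUE,
                           lambda = c(lambda1, lambda2, lambda3))
  sim <- simulate_cells(st, ceiling(t_end / dt), config,
                        pcp_in_plane = pcp_in_plane,
                        sample_every = sample_every,
                        save_frames = save_frames)
  new_run("tube", sim,
          run_manifest("tube", seed, config,
                       list(lambda3 = lambda3, lambda2 = lambda2, n = n,
                            t_end = t_end, pcp_in_plane = pcp_in_plane,
                            dt = dt)),
          list(axes = tube_axes(sim$state)))
}

#' Scenario: gastrulation-like invagination
#'
#' A blastula (hollow sphere, AB polarity radially out) whose lower third of
#' cells acquires whirling PCP confined to the apical plane
#' (`lambda = (0.5, 0.4, 0.1)`) while the remaining cells stay purely AB
#' polarized (`lambda = (1, 0, 0)`). An external force on the AB polarity of
#' the lower cells (strength `k`, Gaussian width `sigma` about the
#' anterior-posterior axis) flattens the bottom and drives invagination;
#' PCP-driven convergent extension then elongates the invaginated tube
#' toward the opposite pole. Setting `force_off = TRUE` keeps PCP only
#' (exvagination: the tube extends outward); `pcp_off = TRUE` keeps the
#' force only (invagination without tube formation).
#'
#' @param n Number of cells (>= 500).
#' @param k Gastrulation force strength (reference value 0.02).
#' @param sigma Gaussian width of the force (reference value 10).
#' @param t_end Simulated time.
#' @param force_off Disable the external AB force (PCP-only control).
#' @param pcp_off Disable PCP in the lower cells (force-only control;
#'   their weights become `lambda = (1, 0, 0)`).
#' @param eta Noise amplitude.
#' @param dt,seed,neighbor_stride,sample_every,save_frames As in
#'   [scenario_bulk_random()].
#' @return A `polarsim_run`; `$stages` holds the per-frame stage metrics
#'   from [gastrulation_stages()] (frames are always saved for this
#'   scenario).
#' @export
scenario_gastrulation <- function(n = 600, k = 0.02, sigma = 10,
                                  t_end = 1500, force_off = FALSE,
                                  pcp_off = FALSE, eta = 1e-4, dt = 0.2,
                                  seed = 1, neighbor_stride = 2,
                                  sample_every = 250, save_frames = TRUE) {
  if (n < 500) abort("`n` must be >= 500")
  set.seed(seed)
  config <- model_config(dt = dt, eta = eta,
                         neighbor_stride = neighbor_stride)
  st <- make_hollow_sphere(n)
  lower <- st$z < quantile(st$z, 1 / 3)
  if (!pcp_off) {
    lam <- lambdas(st)
    lam[lower, ] <- matrix(rep(c(0.5, 0.4, 0.1), each = sum(lower)), ncol = 3)
    st$l1 <- lam[, 1]; st$l2 <- lam[, 2]; st$l3 <- lam[, 3]
    q <- pcp_whirl_field(positions(st))
    st$qx[lower] <- q[lower, 1]
    st$qy[lower] <- q[lower, 2]
    st$qz[lower] <- q[lower, 3]
    st$pcp_active <- lower
  }
  fields <- external_fields(
    force_k = if (force_off) 0 else k, force_sigma = sigma,
    force_mask = lower)
  sim <- simulate_cells(st, ceiling(t_end / dt), config, fields,
                        pcp_in_plane = lower & !pcp_off,
                        sample_every = sample_every,
                        save_frames = save_frames)
  run <- new_run("gastrulation", sim,
                 run_manifest("gastrulation", seed, config,
                              list(n = n, k = k, sigma = sigma,
                                   t_end = t_end, force_off = force_off,
                                   pcp_off = pcp_off, dt = dt)),
                 list(lower = which(lower)))
  if (length(run$frames)) run$stages <- gastrulation_stages(run)
  run
}

#' Stage metrics for a gastrulation run
#'
#' Per-frame geometric descriptors of the invagination sequence, measured on
#' the initially-lower (PCP/force-bearing) cell group: `z_low` the group's
#' mean height relative to the shell center, `r_low` its mean distance from
#' the center of mass, `shell_radius` the mean radial distance of the upper
#' cells, `cap_flatness` the height range of the near-axis lower cells
#' (shrinks as the bottom flattens), `tube_length` the vertical extent of
#' the lower cells, and `tip_gap` the distance from the highest lower cell
#' to the top pole of the upper shell. Invagination shows as `z_low` rising
#' with `r_low` dropping below `shell_radius`; exvagination as `z_low`
#' dropping below its initial value with `r_low` exceeding `shell_radius`.
#'
#' @param run A `polarsim_run` from [scenario_gastrulation()] with frames.
#' @return A tibble with one row per frame.
#' @export
gastrulation_stages <- function(run) {
  lower <- run$lower
  purrr::map_dfr(run$frames, function(fr) {
    pos <- fr$positions
    com <- colMeans(pos)
    rel <- sweep(pos, 2, com)
    rad <- sqrt(rowSums(rel^2))
    up <- setdiff(seq_len(nrow(pos)), lower)
    rho <- sqrt(rel[, 1]^2 + rel[, 2]^2)
    near_axis <- intersect(lower, which(rho < 0.4 * mean(rad[up])))
    top <- pos[up[which.max(rel[up, 3])], ]
    tibble::tibble(
      time = fr$time,
      z_low = mean(rel[lower, 3]),
      r_low = mean(rad[lower]),
      shell_radius = mean(rad[up]),
      cap_flatness = if (length(near_axis) > 1)
        diff(range(rel[near_axis, 3])) else NA_real_,
      tube_length = diff(range(rel[lower, 3])),
      tip_gap = sqrt(min(colSums((t(pos[lower, , drop = FALSE]) - top)^2))))
  })
}
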