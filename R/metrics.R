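#' Potential energy per cell
#'
#' Each cell's energy is the sum of its pairwise neighbor potentials,
#' `V_i = sum_j V_ij` over the edges of the neighbor graph.
#'
#' @param state A `cell_state`.
#' @param graph A `neighbor_graph` (from [find_neighbors()]); recomputed if
#'   `NULL`.
#' @param config A [model_config()].
#' @return Numeric vector of length N (0 for isolated cells).
#' @examples
#' st <- make_hollow_sphere(50)
#' mean(energy_per_cell(st))
#' @export
energy_per_cell <- function(state, graph = NULL, config = model_config()) {
  graph <- graph %||% find_neighbors(positions(state),
                                     mode = config$neighbor_mode,
                                     cutoff = config$cutoff,
                                     prefilter_k = config$prefilter_k)
  n <- n_cells(state)
  if (nrow(graph) == 0) return(numeric(n))
  pos <- positions(state); p <- ab_polarity(state); q <- pcp_polarity(state)
  lam <- lambdas(state)
  i <- graph$i; j <- graph$j
  d <- pos[j, , drop = FALSE] - pos[i, , drop = FALSE]
  r <- sqrt(rowSums(d^2))
  rhat <- d / r
  pipj <- rowSums(p[i, , drop = FALSE] * p[j, , drop = FALSE])
  rpi <- rowSums(rhat * p[i, , drop = FALSE])
  rpj <- rowSums(rhat * p[j, , drop = FALSE])
  qiqj <- rowSums(q[i, , drop = FALSE] * q[j, , drop = FALSE])
  rqi <- rowSums(rhat * q[i, , drop = FALSE])
  rqj <- rowSums(rhat * q[j, , drop = FALSE])
  piqj <- rowSums(p[i, , drop = FALSE] * q[j, , drop = FALSE])
  qipj <- rowSums(q[i, , drop = FALSE] * p[j, , drop = FALSE])
  S1 <- pipj - rpi * rpj
  S2 <- pipj * qiqj - piqj * qipj
  S3 <- qiqj - rqi * rqj
  l <- (lam[i, , drop = FALSE] + lam[j, , drop = FALSE]) / 2
  l1 <- l[, 1]
  if (config$angle_gate) l1 <- ifelse(pipj < 0, 0, l1)
  S <- l1 * S1 + l[, 2] * S2 + l[, 3] * S3
  V <- pair_potential(r, S, config$beta, config$potential_exponent)
  as.numeric(tapply(c(V, V), factor(c(i, j), levels = seq_len(n)), sum,
                    default = 0))
}

#' Count local minima (folds)
#'
#' A cell is a local minimum when (a) none of its neighbors is strictly
#' closer to the center of mass than itself, and (b) the average angle
#' between its AB polarity and the displacement vectors to its neighbors is
#' less than pi/2 — i.e. an outermost cell whose apical side points back
#' toward the tissue. Cells with no neighbors are excluded from the count.
#' The count is invariant under rigid rotation and translation of the state.
#'
#' @param state A `cell_state`.
#' @param graph A `neighbor_graph`; recomputed if `NULL`.
#' @return Integer count of local-minimum cells.
#' @export
count_local_minima <- function(state, graph = NULL) {
  graph <- graph %||% find_neighbors(positions(state))
  n <- n_cells(state)
  if (nrow(graph) == 0) return(0L)
  pos <- positions(state)
  com <- colMeans(pos)
  rad <- sqrt(rowSums(sweep(pos, 2, com)^2))
  p <- ab_polarity(state)
  i <- c(graph$i, graph$j)
  j <- c(graph$j, graph$i)
  d <- pos[j, , drop = FALSE] - pos[i, , drop = FALSE]
  ang <- acos(pmin(1, pmax(-1, rowSums(p[i, , drop = FALSE] * d) /
                             sqrt(rowSums(d^2)))))
  f <- factor(i, levels = seq_len(n))
  has_inner <- as.logical(tapply(rad[j] < rad[i], f, any, default = NA))
  mean_ang <- as.numeric(tapply(ang, f, mean, default = NA))
  ok <- !is.na(has_inner) & !has_inner & mean_ang < pi / 2
  sum(ok)
}

#' Tube semi-axes
#'
#' Approximates the semi-major and semi-minor axes of a tubular lumen as half
#' the maximum and minimum distance between two cells whose AB polarities
#' point in opposite directions (dot product below `opposite_threshold`);
#' cells on opposite walls of the tube face each other, so these distances
#' span the tube's length and width.
#'
#' @param state A `cell_state`.
#' @param opposite_threshold Dot-product threshold defining "opposite"
#'   polarity (default -0.9).
#' @return Named numeric vector `c(semi_major, semi_minor)`.
#' @examples
#' shell <- make_hollow_sphere(200, radius = 8)
#' tube_axes(shell) # both close to 8
#' @export
tube_axes <- function(state, opposite_threshold = -0.9) {
  pos <- positions(state)
  p <- ab_polarity(state)
  dots <- tcrossprod(p)
  opp <- which(dots < opposite_threshold & upper.tri(dots), arr.ind = TRUE)
  if (nrow(opp) == 0)
    abort(paste0("no cell pair with opposite AB polarity (p_i . p_j < ",
                 opposite_threshold, "); relax `opposite_threshold`"))
  d2 <- rowSums((pos[opp[, 1], , drop = FALSE] -
                 pos[opp[, 2], , drop = FALSE])^2)
  c(semi_major = sqrt(max(d2)) / 2, semi_minor = sqrt(min(d2)) / 2)
}

#' Count disjoint shells
#'
#' Number of connected components of the neighbor graph restricted to edges
#' shorter than 3 cell radii — nested hollow spheres separated by more than
#' that gap count separately.
#'
#' @param state A `cell_state`.
#' @param graph A `neighbor_graph`; recomputed if `NULL`.
#' @param max_edge Edge-length cutoff (default 3).
#' @return Integer component count.
#' @export
count_shells <- function(state, graph = NULL, max_edge = 3) {
  graph <- graph %||% find_neighbors(positions(state))
  n <- n_cells(state)
  pos <- positions(state)
  if (nrow(graph)) {
    len <- sqrt(rowSums((pos[graph$i, , drop = FALSE] -
                         pos[graph$j, , drop = FALSE])^2))
    keep <- len < max_edge
    el <- cbind(graph$i[keep], graph$j[keep])
  } else el <- matrix(integer(0), 0, 2)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::components(g)$no
}

#' Fold depth and extent
#'
#' Quantifies fold geometry from the local-minimum cells: for each
#' local-minimum cell, `depth` is the difference between the largest radial
#' distance (from the center of mass) found within `hops` graph-geodesic
#' steps of the cell and the cell's own radial distance; `extent` is the
#' edge-length-weighted geodesic diameter of the connected patch of
#' below-median-radius cells containing it. Returns the means over all
#' local minima. This measurement procedure is this package's own
#' definition of fold size.
#'
#' @param state A `cell_state`.
#' @param graph A `neighbor_graph`; recomputed if `NULL`.
#' @param hops Geodesic neighborhood radius (graph steps) for the depth
#'   measure.
#' @return Named numeric vector `c(mean_depth, mean_extent)`.
#' @export
fold_geometry <- function(state, graph = NULL, hops = 5) {
  graph <- graph %||% find_neighbors(positions(state))
  n <- n_cells(state)
  pos <- positions(state)
  com <- colMeans(pos)
  rad <- sqrt(rowSums(sweep(pos, 2, com)^2))
  minima <- local_minima_cells(state, graph)
  if (length(minima) == 0)
    abort("no folds: the state has no local-minimum cells")
  el <- cbind(graph$i, graph$j)
  len <- sqrt(rowSums((pos[graph$i, , drop = FALSE] -
                       pos[graph$j, , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::E(g)$weight <- len
  hop_d <- igraph::distances(g, v = minima, weights = NA)
  depth <- vapply(seq_along(minima), function(k) {
    nb <- which(hop_d[k, ] <= hops)
    max(rad[nb]) - rad[minima[k]]
  }, numeric(1))
  low <- which(rad < median(rad))
  sub <- igraph::induced_subgraph(g, low)
  comp <- igraph::components(sub)
  extent <- vapply(seq_along(minima), function(k) {
    at <- match(minima[k], low)
    if (is.na(at)) return(0)
    members <- which(comp$membership == comp$membership[at])
    if (length(members) < 2) return(0)
    dd <- igraph::distances(sub, v = members, to = members)
    max(dd[is.finite(dd)])
  }, numeric(1))
  c(mean_depth = mean(depth), mean_extent = mean(extent))
}

local_minima_cells <- function(state, graph) {
  n <- n_cells(state)
  if (nrow(graph) == 0) return(integer(0))
  pos <- positions(state)
  com <- colMeans(pos)
  rad <- sqrt(rowSums(sweep(pos, 2, com)^2))
  p <- ab_polarity(state)
  i <- c(graph$i, graph$j)
  j <- c(graph$j, graph$i)
  d <- pos[j, , drop = FALSE] - pos[i, , drop = FALSE]
  ang <- acos(pmin(1, pmax(-1, rowSums(p[i, , drop = FALSE] * d) /
                             sqrt(rowSums(d^2)))))
  f <- factor(i, levels = seq_len(n))
  has_inner <- as.logical(tapply(rad[j] < rad[i], f, any, default = NA))
  mean_ang <- as.numeric(tapply(ang, f, mean, default = NA))
  which(!is.na(has_inner) & !has_inner & mean_ang < pi / 2)
}

#' Per-frame metrics of a trajectory
#'
#' Computes the standard quantification record for each sampled frame of a
#' simulation: mean/sd energy per cell, mean/sd neighbor count, local-minima
#' count, and (optionally) tube semi-axes and shell count.
#'
#' @param frames List of frames as returned by [simulate_cells()] with
#'   `save_frames = TRUE` (each a list with `time`, `positions`, `ab`,
#'   `pcp`).
#' @param lambda Lambda weights of the cells (length-3 vector or N x 3
#'   matrix) used for the energy.
#' @param config A [model_config()].
#' @param tube Also compute [tube_axes()] per frame.
#' @param shells Also compute [count_shells()] per frame.
#' @return A tibble with one row per frame.
#' @export
frame_metrics <- function(frames, lambda = c(1, 0, 0),
                          config = model_config(), tube = FALSE,
                          shells = FALSE) {
  purrr::map_dfr(frames, function(fr) {
    st <- cell_state(fr$positions, ab = fr$ab, pcp = fr$pcp, lambda = lambda,
                     time = fr$time)
    g <- find_neighbors(positions(st), mode = config$neighbor_mode,
                        cutoff = config$cutoff,
                        prefilter_k = config$prefilter_k)
    e <- energy_per_cell(st, g, config)
    deg <- degrees(g)
    row <- tibble::tibble(
      time = fr$time, n_cells = n_cells(st),
      energy_mean = mean(e), energy_sd = sd(e),
      neighbors_mean = mean(deg), neighbors_sd = sd(deg),
      n_local_minima = count_local_minima(st, g))
    if (tube) {
      ax <- tube_axes(st)
      row$semi_major <- ax[["semi_major"]]
      row$semi_minor <- ax[["semi_minor"]]
    }
    if (shells) row$n_shells <- count_shells(st, g)
    row
  })
}
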