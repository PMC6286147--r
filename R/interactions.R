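#' Find interacting neighbors
#'
#' Builds the symmetric neighbor graph over cells. In `line_of_sight` mode
#' (the default rule), cells i and j interact iff no other cell lies within
#' `r_ij / 2` of the midpoint between them, i.e. the midpoint lies in the
#' Voronoi regions of i and j only; ties block conservatively. In
#' `voronoi_cutoff` mode, cells interact iff they share a Voronoi facet and
#' are within `cutoff` of each other. Both modes examine only the
#' `prefilter_k` nearest candidates per cell (exact whenever
#' `prefilter_k >= N - 1`).
#'
#' @param state A `cell_state`, data frame with `x, y, z`, or N x 3 matrix.
#' @param mode `"line_of_sight"` or `"voronoi_cutoff"`.
#' @param cutoff Distance cutoff for `voronoi_cutoff` mode.
#' @param prefilter_k Candidate-neighbor count (default 100).
#' @return A `neighbor_graph`: a tibble of edges with columns `i`, `j`
#'   (`i < j`, 1-based) and attribute `n` (number of cells).
#' @examples
#' st <- make_hollow_sphere(50)
#' g <- find_neighbors(st)
#' mean(degrees(g))
#' @export
find_neighbors <- function(state, mode = c("line_of_sight", "voronoi_cutoff"),
                           cutoff = 4, prefilter_k = 100) {
  mode <- match.arg(mode)
  pos <- if (is.data.frame(state)) positions(state) else
    as_matrix3(state, "state")
  n <- nrow(pos)
  k <- as.integer(min(prefilter_k, n - 1))
  if (n < 2) {
    edges <- matrix(integer(0), 0, 2)
  } else if (mode == "line_of_sight") {
    edges <- find_neighbors_cpp(pos, k)
  } else {
    edges <- voronoi_cutoff_cpp(pos, cutoff, k)
  }
  g <- tibble::tibble(i = as.integer(edges[, 1]), j = as.integer(edges[, 2]))
  tibble::new_tibble(g, n = n, class = "neighbor_graph")
}

#' @rdname find_neighbors
#' @param graph A `neighbor_graph`.
#' @return `degrees()` returns the per-cell neighbor count.
#' @export
degrees <- function(graph) {
  n <- attr(graph, "n")
  tabulate(c(graph$i, graph$j), nbins = n)
}

check_unit <- function(v, what, tol = 1e-6) {
  v <- as.numeric(v)
  if (length(v) != 3) abort(paste0("`", what, "` must be a 3-vector"))
  nv <- sqrt(sum(v^2))
  if (abs(nv - 1) > tol)
    abort(paste0("`", what, "` must be unit norm (|", what, "| = ",
                 format(nv), ")"))
  v
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Polarity coupling factors
#'
#' The three orientational factors modulating pair attraction:
#' `S1 = (p_i x rhat) . (p_j x rhat)` couples the AB polarities to the
#' separation direction (1 when both AB polarities are parallel and
#' perpendicular to the separation — apical sides adjacent; -1 when they are
#' anti-parallel). `S2 = (p_i x q_i) . (p_j x q_j)` favors parallel PCP
#' perpendicular to AB polarity within each cell, and
#' `S3 = (q_i x rhat) . (q_j x rhat)` is the PCP analogue of S1, giving
#' cells with parallel PCP and like poles adjacent maximal attraction.
#' All three lie in [-1, 1] for unit inputs.
#'
#' @param p_i,p_j AB polarity unit vectors.
#' @param q_i,q_j PCP unit vectors.
#' @param r_hat Unit separation vector from cell i to cell j.
#' @return A scalar in [-1, 1].
#' @examples
#' polarity_factor_s1(c(0, 0, 1), c(0, 0, 1), c(1, 0, 0)) # 1
#' @export
polarity_factor_s1 <- function(p_i, p_j, r_hat) {
  p_i <- check_unit(p_i, "p_i"); p_j <- check_unit(p_j, "p_j")
  r_hat <- check_unit(r_hat, "r_hat")
  sum(cross3(p_i, r_hat) * cross3(p_j, r_hat))
}

#' @rdname polarity_factor_s1
#' @export
polarity_factor_s2 <- function(p_i, q_i, p_j, q_j) {
  p_i <- check_unit(p_i, "p_i"); p_j <- check_unit(p_j, "p_j")
  q_i <- check_unit(q_i, "q_i"); q_j <- check_unit(q_j, "q_j")
  sum(cross3(p_i, q_i) * cross3(p_j, q_j))
}

#' @rdname polarity_factor_s1
#' @export
polarity_factor_s3 <- function(q_i, q_j, r_hat) {
  q_i <- check_unit(q_i, "q_i"); q_j <- check_unit(q_j, "q_j")
  r_hat <- check_unit(r_hat, "r_hat")
  sum(cross3(q_i, r_hat) * cross3(q_j, r_hat))
}

#' Combined attraction strength of a cell pair
#'
#' Combines the three polarity factors with the pair-effective weights
#' `lambda_k = (lambda_k,i + lambda_k,j) / 2` (the mixed-cell mean rule,
#' which keeps pair forces equal and opposite and the weights summing to 1):
#' `S = l1 S1 + l2 S2 + l3 S3`. With `angle_gate = TRUE` the S1 contribution
#' is zeroed when the AB polarities differ by more than pi/2
#' (`p_i . p_j < 0`).
#'
#' @param S1,S2,S3 Polarity factors.
#' @param lambda_i,lambda_j Length-3 weight triples, each summing to 1.
#' @param angle_gate Zero the AB term for opposed polarities.
#' @param p_dot Value of `p_i . p_j`, required when `angle_gate = TRUE`.
#' @return The scalar attraction strength `S`.
#' @export
coupling <- function(S1, S2, S3, lambda_i, lambda_j = lambda_i,
                     angle_gate = FALSE, p_dot = NULL) {
  lambda_i <- as.numeric(lambda_i); lambda_j <- as.numeric(lambda_j)
  if (length(lambda_i) != 3 || abs(sum(lambda_i) - 1) > 1e-9)
    abort("`lambda_i` must be a triple summing to 1")
  if (length(lambda_j) != 3 || abs(sum(lambda_j) - 1) > 1e-9)
    abort("`lambda_j` must be a triple summing to 1")
  l <- (lambda_i + lambda_j) / 2
  if (angle_gate) {
    if (is.null(p_dot)) abort("`p_dot` is required when `angle_gate = TRUE`")
    if (p_dot < 0) l[1] <- 0
  }
  l[1] * S1 + l[2] * S2 + l[3] * S3
}

#' Pair potential between two cells
#'
#' `V(r) = exp(-r) - S exp(-r / beta)` for `exponent = 1` (repulsion minus
#' polarity-weighted attraction), or the quartic variant
#' `exp(-r^4) - S exp(-(r / beta)^4)` for `exponent = 4`.
#'
#' @param r Center-center distance (> 0); vectorized.
#' @param S Attraction strength.
#' @param beta Attraction-range ratio.
#' @param exponent 1 or 4.
#' @return Potential value(s).
#' @examples
#' pair_potential(2, S = 1) # near the S = 1 minimum
#' @export
pair_potential <- function(r, S, beta = 5, exponent = 1) {
  if (any(r <= 0)) abort("`r` must be positive")
  if (exponent == 1) exp(-r) - S * exp(-r / beta)
  else if (exponent == 4) exp(-r^4) - S * exp(-(r / beta)^4)
  else abort("`exponent` must be 1 or 4")
}

#' Equilibrium pair distance
#'
#' The stationary point of the pair potential. For the exponential form it is
#' closed form, `r* = beta / (beta - 1) * log(beta / S)`; for the quartic
#' variant the minimum is located numerically. Perfectly aligned cells
#' (S = 1, beta = 5) sit at r* = 2.0118, i.e. about 2 cell radii.
#'
#' @param S Attraction strength, `0 < S <= beta` for a finite minimum.
#' @param beta Attraction-range ratio.
#' @param exponent 1 or 4.
#' @return The equilibrium separation.
#' @examples
#' equilibrium_distance(1, 5)
#' @export
equilibrium_distance <- function(S, beta = 5, exponent = 1) {
  if (any(S <= 0)) abort("`S` must be positive (no finite minimum otherwise)")
  if (exponent == 1) return(beta / (beta - 1) * log(beta / S))
  vapply(S, function(s) {
    optimize(function(r) pair_potential(r, s, beta, 4),
             interval = c(1e-3, 4 * beta), tol = 1e-10)$minimum
  }, numeric(1))
}

#' Pair interaction with analytic gradients
#'
#' Evaluates the potential, the coupling factors, and the analytic gradients
#' of V with respect to the position and both polarities of each cell, using
#' the same compiled kernel as the simulation driver. Polarity gradients are
#' taken through the unit normalization (Cartesian differentiation followed
#' by projection), matching how the integrator updates polarities.
#'
#' @param x_i,x_j Cell positions.
#' @param p_i,p_j AB polarity unit vectors.
#' @param q_i,q_j PCP unit vectors.
#' @param lambda_i,lambda_j Weight triples.
#' @param config A [model_config()].
#' @param inplane_i,inplane_j Whether each cell's PCP is confined to the
#'   apical plane (drops the S2 term from that cell's AB-polarity gradient).
#' @return A list with `V`, `S`, `S1`, `S2`, `S3`, `r`, and the six gradient
#'   vectors `dV_dri`, `dV_drj`, `dV_dpi`, `dV_dpj`, `dV_dqi`, `dV_dqj`.
#' @export
pair_gradients <- function(x_i, x_j, p_i, p_j, q_i, q_j,
                           lambda_i = c(1, 0, 0), lambda_j = lambda_i,
                           config = model_config(),
                           inplane_i = FALSE, inplane_j = FALSE) {
  p_i <- check_unit(p_i, "p_i"); p_j <- check_unit(p_j, "p_j")
  q_i <- check_unit(q_i, "q_i"); q_j <- check_unit(q_j, "q_j")
  if (sum((x_j - x_i)^2) == 0) abort("r_ij = 0: coincident cells")
  pair_interaction_cpp(as.numeric(x_i), as.numeric(x_j), p_i, p_j, q_i, q_j,
                       as.numeric(lambda_i), as.numeric(lambda_j),
                       config$beta, config$potential_exponent,
                       config$angle_gate, inplane_i, inplane_j, -1.0)
}

#' Log neighbor exchanges between two graphs
#'
#' Compares two neighbor graphs over the same cells and reports the edges
#' gained and lost — the elementary events of cell intercalation (T1
#' transitions appear as a lost edge between one cell pair together with a
#' gained edge between the two other cells of the quartet).
#'
#' @param old,new `neighbor_graph` objects over the same cell set.
#' @return A tibble with columns `i`, `j`, `event` (`"gained"` or
#'   `"lost"`), one row per changed edge.
#' @export
neighbor_exchanges <- function(old, new) {
  o <- tibble::as_tibble(old)
  n <- tibble::as_tibble(new)
  gained <- dplyr::anti_join(n, o, by = c("i", "j"))
  lost <- dplyr::anti_join(o, n, by = c("i", "j"))
  dplyr::bind_rows(
    dplyr::mutate(gained, event = "gained"),
    dplyr::mutate(lost, event = "lost"))
}

#' Write a neighbor graph as an edge-list text file
#'
#' @param graph A `neighbor_graph`.
#' @param path Output path (TSV with columns `i`, `j`).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  readr::write_tsv(tibble::as_tibble(graph), path)
  invisible(path)
}
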