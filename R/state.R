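#' Cell state tibbles
#'
#' A cell state is a tibble with one row per cell and columns
#' `x, y, z` (position, cell-radius units), `px, py, pz` (apical-basal
#' polarity unit vector), `qx, qy, qz` (planar cell polarity unit vector),
#' `l1, l2, l3` (polarity-strength weights, summing to 1 per cell),
#' `fixed` (polarity frozen by a boundary condition), and `pcp_active`
#' (whether the PCP vector is biologically meaningful for this cell; cells
#' without PCP carry a placeholder unit vector with `l2 = l3 = 0`). The
#' simulation time lives in the `time` attribute.
#'
#' @param positions N x 3 matrix of positions.
#' @param ab N x 3 matrix of AB polarity unit vectors.
#' @param pcp N x 3 matrix of PCP unit vectors, or `NULL` for placeholder
#'   vectors orthogonal to `ab`.
#' @param lambda Either a length-3 vector recycled to all cells or an N x 3
#'   matrix of per-cell weights; rows must sum to 1.
#' @param fixed,pcp_active Logical vectors (recycled).
#' @param time Simulation time scalar.
#'
#' @return A `cell_state` tibble.
#' @examples
#' st <- cell_state(matrix(c(0, 0, 0, 2, 0, 0), 2, 3, byrow = TRUE),
#'                  ab = matrix(c(0, 0, 1, 0, 0, 1), 2, 3, byrow = TRUE))
#' n_cells(st)
#' @export
cell_state <- function(positions, ab, pcp = NULL, lambda = c(1, 0, 0),
                       fixed = FALSE, pcp_active = FALSE, time = 0) {
  positions <- as_matrix3(positions, "positions")
  n <- nrow(positions)
  if (n < 1) abort("a cell state needs at least one cell")
  ab <- as_matrix3(ab, "ab")
  if (nrow(ab) != n) abort("`ab` must have one row per cell")
  if (is.null(pcp)) pcp <- orthogonal_unit(ab)
  pcp <- as_matrix3(pcp, "pcp")
  if (nrow(pcp) != n) abort("`pcp` must have one row per cell")
  if (is.null(dim(lambda))) lambda <- matrix(lambda, n, 3, byrow = TRUE)
  lambda <- as_matrix3(lambda, "lambda")
  if (nrow(lambda) != n) abort("`lambda` must have one row per cell")
  st <- tibble::tibble(
    x = positions[, 1], y = positions[, 2], z = positions[, 3],
    px = ab[, 1], py = ab[, 2], pz = ab[, 3],
    qx = pcp[, 1], qy = pcp[, 2], qz = pcp[, 3],
    l1 = lambda[, 1], l2 = lambda[, 2], l3 = lambda[, 3],
    fixed = rep_len(as.logical(fixed), n),
    pcp_active = rep_len(as.logical(pcp_active), n)
  )
  st <- tibble::new_tibble(st, time = as.numeric(time), class = "cell_state")
  validate_cell_state(st)
  st
}

state_cols <- c("x", "y", "z", "px", "py", "pz", "qx", "qy", "qz",
                "l1", "l2", "l3", "fixed", "pcp_active")

#' Coerce a data frame to a cell state
#'
#' @param df A data frame with the cell-state columns (see [cell_state()]).
#' @param time Simulation time; defaults to the existing `time` attribute or 0.
#' @return A `cell_state` tibble.
#' @export
as_cell_state <- function(df, time = NULL) {
  missing <- setdiff(state_cols, names(df))
  if (length(missing))
    abort(paste0("missing cell-state columns: ", paste(missing, collapse = ", ")))
  time <- time %||% attr(df, "time") %||% 0
  st <- tibble::new_tibble(tibble::as_tibble(df)[state_cols],
                           time = as.numeric(time), class = "cell_state")
  validate_cell_state(st)
  st
}

validate_cell_state <- function(st) {
  pos <- positions(st)
  if (any(!is.finite(pos))) abort("cell positions must be finite")
  pn <- sqrt(rowSums(ab_polarity(st)^2))
  qn <- sqrt(rowSums(pcp_polarity(st)^2))
  if (any(abs(pn - 1) > 1e-9)) abort("AB polarity vectors must be unit norm")
  if (any(abs(qn - 1) > 1e-9)) abort("PCP vectors must be unit norm")
  lam <- lambdas(st)
  if (any(lam < -1e-12)) abort("lambda weights must be non-negative")
  if (any(abs(rowSums(lam) - 1) > 1e-12))
    abort("lambda weights must sum to 1 for every cell")
  invisible(st)
}

#' @export
print.cell_state <- function(x, ...) {
  cat(sprintf("<cell_state> %d cells at time %g\n", nrow(x), state_time(x)))
  NextMethod()
}

#' Accessors for cell-state components
#'
#' @param state A `cell_state` tibble (or data frame with its columns).
#' @return `positions()`, `ab_polarity()`, `pcp_polarity()` and `lambdas()`
#'   return N x 3 numeric matrices; `n_cells()` the number of cells;
#'   `state_time()` the simulation time.
#' @export
positions <- function(state) cbind(x = state$x, y = state$y, z = state$z)

#' @rdname positions
#' @export
ab_polarity <- function(state) cbind(state$px, state$py, state$pz)

#' @rdname positions
#' @export
pcp_polarity <- function(state) cbind(state$qx, state$qy, state$qz)

#' @rdname positions
#' @export
lambdas <- function(state) cbind(state$l1, state$l2, state$l3)

#' @rdname positions
#' @export
n_cells <- function(state) nrow(state)

#' @rdname positions
#' @export
state_time <- function(state) attr(state, "time") %||% 0

as_matrix3 <- function(m, what) {
  m <- as.matrix(m)
  if (is.vector(m)) m <- matrix(m, 1)
  if (ncol(m) != 3) abort(paste0("`", what, "` must have three columns"))
  storage.mode(m) <- "double"
  m
}

normalize_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  if (any(n < 1e-12)) abort("cannot normalize zero vectors")
  m / n
}

# A unit vector orthogonal to each row of m (placeholder PCP).
orthogonal_unit <- function(m) {
  ref <- matrix(rep(c(1, 0, 0), each = nrow(m)), ncol = 3)
  swap <- abs(m[, 1]) > 0.9
  ref[swap, ] <- matrix(rep(c(0, 1, 0), each = sum(swap)), ncol = 3)
  v <- cbind(m[, 2] * ref[, 3] - m[, 3] * ref[, 2],
             m[, 3] * ref[, 1] - m[, 1] * ref[, 3],
             m[, 1] * ref[, 2] - m[, 2] * ref[, 1])
  normalize_rows(v)
}

random_unit_vectors <- function(n) {
  normalize_rows(matrix(rnorm(3 * n), n, 3))
}

#' Generate a compact bulk aggregate
#'
#' Places `n` cells by random sequential packing in a ball (rejecting pairs
#' closer than 1.6 cell radii), then relaxes for 50 noiseless steps with the
#' non-polar potential (`S = 1`) so the spacing settles near the equilibrium
#' distance of about 2 cell radii. AB polarities are drawn uniformly on the
#' unit sphere; PCP is inactive and the weights are `lambda = (1, 0, 0)`.
#'
#' @param n Number of cells (>= 1).
#' @param radius_scale Multiplier on the packing-ball radius; 1 gives the
#'   default compact density.
#' @param relax_steps Noiseless relaxation steps after packing.
#' @return A `cell_state` tibble.
#' @examples
#' st <- make_bulk_aggregate(50)
#' @export
make_bulk_aggregate <- function(n, radius_scale = 1, relax_steps = 50) {
  if (!is.numeric(n) || length(n) != 1 || n < 1)
    abort("`n` must be a single integer >= 1")
  n <- as.integer(n)
  if (n == 1) {
    return(cell_state(matrix(0, 1, 3), ab = random_unit_vectors(1)))
  }
  R <- radius_scale * 1.2 * n^(1 / 3)
  pos <- pack_ball_cpp(n, R, 1.6, 2000L * n)
  if (relax_steps > 0) {
    res <- simulate_cpp(pos, random_unit_vectors(n), random_unit_vectors(n),
                        matrix(c(1, 0, 0), n, 3, byrow = TRUE),
                        rep(TRUE, n), rep(FALSE, n),
                        as.integer(relax_steps), 0.1, 5, 1L, 0, 0, 0,
                        FALSE, 1.0, 0L, 4, min(100L, n - 1L), 1L,
                        0, 0, 10, logical(0), 0, as.integer(relax_steps) + 1L,
                        FALSE)
    pos <- res$positions
  }
  pos <- sweep(pos, 2, colMeans(pos))
  cell_state(pos, ab = random_unit_vectors(n))
}

#' Generate a hollow sphere of cells
#'
#' Cells sit on a deterministic Fibonacci-spiral lattice on a sphere, AB
#' polarity points radially outward, and (optionally) PCP whirls azimuthally
#' around an internal axis: `q_i = axis x rhat_i`, normalized, which is
#' orthogonal to the radial AB polarity by construction.
#'
#' @param n Number of cells (>= 4).
#' @param radius Sphere radius (cell radii); the default spaces cells about
#'   2 radii apart on the surface.
#' @param pcp_whirl If `TRUE`, activate whirling PCP around `axis`.
#' @param axis Whirl axis (default z).
#' @param lambda Length-3 weight vector applied to all cells.
#' @return A `cell_state` tibble.
#' @examples
#' shell <- make_hollow_sphere(200, pcp_whirl = TRUE)
#' @export
make_hollow_sphere <- function(n, radius = NULL, pcp_whirl = FALSE,
                               axis = c(0, 0, 1), lambda = c(1, 0, 0)) {
  if (!is.numeric(n) || length(n) != 1 || n < 4)
    abort("`n` must be a single integer >= 4")
  n <- as.integer(n)
  radius <- radius %||% (0.525 * sqrt(n))
  i <- seq_len(n) - 0.5
  zf <- 1 - 2 * i / n
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  rho <- sqrt(pmax(0, 1 - zf^2))
  rhat <- cbind(rho * cos(phi), rho * sin(phi), zf)
  pos <- radius * rhat
  if (pcp_whirl) {
    q <- pcp_whirl_field(pos, axis = axis)
    st <- cell_state(pos, ab = rhat, pcp = q, lambda = lambda,
                     pcp_active = TRUE)
  } else {
    st <- cell_state(pos, ab = rhat, lambda = lambda)
  }
  st
}

#' Azimuthal (whirling) PCP field around an axis
#'
#' Evaluates `axis x rhat` at each position (unit-normalized), the PCP
#' arrangement whirling around an internal axis. Positions on the axis have
#' no defined azimuth and are assigned the +x direction with a warning.
#'
#' @param positions N x 3 matrix (or a cell state / data frame with x, y, z).
#' @param axis Whirl axis.
#' @return N x 3 matrix of unit vectors.
#' @export
pcp_whirl_field <- function(positions, axis = c(0, 0, 1)) {
  if (is.data.frame(positions)) positions <- positions(positions)
  positions <- as_matrix3(positions, "positions")
  axis <- axis / sqrt(sum(axis^2))
  rhat <- normalize_rows(positions)
  v <- cbind(axis[2] * rhat[, 3] - axis[3] * rhat[, 2],
             axis[3] * rhat[, 1] - axis[1] * rhat[, 3],
             axis[1] * rhat[, 2] - axis[2] * rhat[, 1])
  nv <- sqrt(rowSums(v^2))
  deg <- nv < 1e-12
  if (any(deg)) {
    warn("positions on the whirl axis: assigning PCP = +x there")
    v[deg, ] <- matrix(rep(c(1, 0, 0), each = sum(deg)), ncol = 3)
    nv[deg] <- 1
  }
  v / nv
}

#' Impose a symmetric AB-polarity boundary field
#'
#' Overwrites the AB polarity of every cell with one of the three symmetric
#' fields used in the boundary-condition experiments: radially out from the
#' center of mass (`radial_point`), radially out from a central axis
#' (`radial_axis`), or pointing away from a central plane (`planar`). With
#' `fix = TRUE` the polarities are frozen so the dynamics never rotates them.
#'
#' Cells exactly on the symmetry locus have no defined field direction; they
#' are assigned +x (`radial_point`, `radial_axis`) or +z (`planar`) and a
#' warning is emitted.
#'
#' @param state A `cell_state`.
#' @param field One of `"radial_point"`, `"radial_axis"`, `"planar"`.
#' @param fix Freeze the polarities (default `TRUE`).
#' @param center Center for `radial_point`; defaults to the center of mass.
#' @param axis Axis direction for `radial_axis` (through the center of mass).
#' @param normal Plane normal for `planar` (plane through the center of mass).
#' @return The modified `cell_state`.
#' @export
apply_polarity_field <- function(state,
                                 field = c("radial_point", "radial_axis",
                                           "planar"),
                                 fix = TRUE, center = NULL,
                                 axis = c(0, 0, 1), normal = c(0, 0, 1)) {
  field <- match.arg(field)
  pos <- positions(state)
  center <- center %||% colMeans(pos)
  rel <- sweep(pos, 2, center)
  if (field == "radial_point") {
    v <- rel
    fallback <- c(1, 0, 0)
  } else if (field == "radial_axis") {
    axis <- axis / sqrt(sum(axis^2))
    v <- rel - outer(drop(rel %*% axis), axis)
    fallback <- c(1, 0, 0)
  } else {
    normal <- normal / sqrt(sum(normal^2))
    sgn <- sign(drop(rel %*% normal))
    v <- outer(sgn, normal)
    fallback <- c(0, 0, 1)
  }
  nv <- sqrt(rowSums(v^2))
  deg <- nv < 1e-12
  if (any(deg)) {
    warn(sprintf("%d cell(s) on the %s symmetry locus: assigning (%s) there",
                 sum(deg), field, paste(fallback, collapse = ",")))
    v[deg, ] <- matrix(rep(fallback, each = sum(deg)), ncol = 3)
    nv[deg] <- 1
  }
  v <- v / nv
  state$px <- v[, 1]; state$py <- v[, 2]; state$pz <- v[, 3]
  state$fixed <- rep_len(isTRUE(fix), nrow(state))
  state
}
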