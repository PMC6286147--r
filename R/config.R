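#' Model configuration
#'
#' Collects the interaction and integration parameters of the model. Defaults
#' are the values used throughout the reference simulations: attraction-range
#' ratio `beta = 5`, Euler time step `dt = 0.1`, and Gaussian noise amplitude
#' `eta = 1e-4`.
#'
#' @param beta Ratio of attraction range to repulsion range; must exceed 1.
#' @param dt Euler time step (time units); `0.1` or `0.2` are the standard
#'   choices, larger values destabilize the morphologies.
#' @param eta Noise amplitude added to every deterministic rate (positions and
#'   both polarities). `eta_pos`, `eta_ab`, `eta_pcp` override it per channel.
#' @param eta_pos,eta_ab,eta_pcp Optional per-channel noise overrides.
#' @param potential_exponent Exponent of the pair potential: `1` for the
#'   exponential form `exp(-r) - S exp(-r/beta)`, `4` for the quartic variant
#'   `exp(-r^4) - S exp(-(r/beta)^4)`.
#' @param neighbor_mode `"line_of_sight"` (midpoint rule over a Voronoi
#'   candidate subset) or `"voronoi_cutoff"` (full Voronoi facet adjacency with
#'   a distance cutoff on attraction).
#' @param cutoff Distance cutoff (cell radii) for `voronoi_cutoff` mode;
#'   default 4, twice the non-polar equilibrium spacing.
#' @param prefilter_k Number of nearest-neighbor candidates examined by the
#'   neighborhood rule (the `inc` speed-up); 100 by default. Set to `Inf` for
#'   the exact quadratic-cost mode.
#' @param neighbor_stride Recompute the neighbor graph every this many steps;
#'   1 (every step) by default.
#' @param angle_gate If `TRUE`, the AB-polarity attraction term is zeroed for
#'   pairs whose AB polarities differ by more than pi/2 (used in the growing-
#'   organoid simulations).
#' @param seed Optional integer seed recorded in run manifests.
#'
#' @return An object of class `model_config` (a named list).
#' @examples
#' cfg <- model_config()
#' cfg$beta
#' @export
model_config <- function(beta = 5, dt = 0.1, eta = 1e-4,
                         eta_pos = NULL, eta_ab = NULL, eta_pcp = NULL,
                         potential_exponent = 1,
                         neighbor_mode = c("line_of_sight", "voronoi_cutoff"),
                         cutoff = 4, prefilter_k = 100, neighbor_stride = 1,
                         angle_gate = FALSE, seed = NULL) {
  neighbor_mode <- match.arg(neighbor_mode)
  if (!is.numeric(beta) || length(beta) != 1 || beta <= 1)
    abort("`beta` must be a single number > 1.")
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0)
    abort("`dt` must be a single positive number.")
  if (!is.numeric(eta) || length(eta) != 1 || eta < 0)
    abort("`eta` must be a single non-negative number.")
  if (!potential_exponent %in% c(1, 4))
    abort("`potential_exponent` must be 1 or 4.")
  if (!is.numeric(cutoff) || cutoff <= 0) abort("`cutoff` must be positive.")
  if (!is.numeric(prefilter_k) || prefilter_k < 1)
    abort("`prefilter_k` must be at least 1.")
  if (!is.numeric(neighbor_stride) || neighbor_stride < 1)
    abort("`neighbor_stride` must be at least 1.")
  structure(list(
    beta = beta, dt = dt, eta = eta,
    eta_pos = eta_pos %||% eta, eta_ab = eta_ab %||% eta,
    eta_pcp = eta_pcp %||% eta,
    potential_exponent = as.integer(potential_exponent),
    neighbor_mode = neighbor_mode, cutoff = cutoff,
    prefilter_k = prefilter_k, neighbor_stride = as.integer(neighbor_stride),
    angle_gate = isTRUE(angle_gate), seed = seed
  ), class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat("<model_config>\n")
  cat(sprintf("  potential: exponent %d, beta = %g\n",
              x$potential_exponent, x$beta))
  cat(sprintf("  integration: dt = %g, eta = (pos %g, ab %g, pcp %g)\n",
              x$dt, x$eta_pos, x$eta_ab, x$eta_pcp))
  cat(sprintf("  neighbors: %s (prefilter_k = %g, stride = %d)\n",
              x$neighbor_mode, x$prefilter_k, x$neighbor_stride))
  if (x$angle_gate) cat("  angle gate: on\n")
  invisible(x)
}

#' External fields acting on the cells
#'
#' Two optional external contributions: an isotropic medium resistance pushing
#' every cell toward the center of mass (force magnitude `P * r / r_max`,
#' constant in time at the periphery), and a gastrulation force acting on AB
#' polarity, `F = -k * rhat_perp * exp(-(x^2 + y^2) / sigma^2)`, where
#' `rhat_perp` is the unit vector from the z-axis to the cell in the xy-plane.
#'
#' @param pressure Medium stiffness `P` (>= 0); 0 disables the term.
#' @param force_k Strength of the AB-polarity force; 0 disables the term.
#' @param force_sigma Gaussian width of the AB-polarity force (> 0).
#' @param force_mask Logical vector (length N) choosing which cells the AB
#'   force acts on, or `NULL` for all cells.
#'
#' @return An object of class `external_fields`.
#' @export
external_fields <- function(pressure = 0, force_k = 0, force_sigma = 10,
                            force_mask = NULL) {
  if (!is.numeric(pressure) || pressure < 0)
    abort("`pressure` must be >= 0.")
  if (!is.numeric(force_sigma) || force_sigma <= 0)
    abort("`force_sigma` must be > 0.")
  structure(list(pressure = pressure, force_k = force_k,
                 force_sigma = force_sigma, force_mask = force_mask),
            class = "external_fields")
}

#' Load a simulation configuration from a YAML file
#'
#' Reads a YAML file whose keys mirror the arguments of [model_config()]
#' (under `model:`), [external_fields()] (under `fields:`), and an optional
#' `scenario:` block with a `name` and scenario-specific parameters. Missing
#' keys take the package defaults; unknown keys are an error.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `model` (a `model_config`), `fields`
#'   (an `external_fields`), and `scenario` (a named list or `NULL`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  # YAML 1.1 would read the bare key `n` (cell count) as a boolean; keep
  # single letters literal while still honoring true/false/yes/no values
  keep_letters <- function(v) {
    if (tolower(v) %in% c("y", "n")) v
    else tolower(v) %in% c("true", "yes", "on")
  }
  raw <- yaml::read_yaml(path, handlers = list("bool#yes" = keep_letters,
                                               "bool#no" = keep_letters))
  if (is.null(raw)) raw <- list()
  bad <- setdiff(names(raw), c("model", "fields", "scenario"))
  if (length(bad))
    abort(paste0("unknown top-level config keys: ", paste(bad, collapse = ", ")))
  m <- raw$model %||% list()
  bad <- setdiff(names(m), names(formals(model_config)))
  if (length(bad))
    abort(paste0("unknown model config keys: ", paste(bad, collapse = ", ")))
  f <- raw$fields %||% list()
  bad <- setdiff(names(f), names(formals(external_fields)))
  if (length(bad))
    abort(paste0("unknown fields config keys: ", paste(bad, collapse = ", ")))
  if (!is.null(m$lambda)) abort("per-cell lambda belongs in the scenario block")
  sc <- raw$scenario
  if (!is.null(sc)) {
    if (is.null(sc$name)) abort("scenario block needs a `name`")
    lam <- sc[["lambda"]]
    if (!is.null(lam)) {
      lam <- as.numeric(lam)
      if (length(lam) != 3 || abs(sum(lam) - 1) > 1e-9 || any(lam < 0))
        abort("scenario lambda must be three non-negative values summing to 1")
    }
  }
  list(model = do.call(model_config, m),
       fields = do.call(external_fields, f),
       scenario = sc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
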