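#' Read and write cell states as CSV
#'
#' The canonical interchange format: one row per cell with the header
#' `x,y,z,px,py,pz,qx,qy,qz,l1,l2,l3,fixed,pcp_active`. Reading back
#' reproduces the state losslessly (positions round-trip bitwise at full
#' precision).
#'
#' @param state A `cell_state`.
#' @param path File path.
#' @return `write_state_csv()` returns `path` invisibly; `read_state_csv()`
#'   returns a `cell_state`.
#' @export
write_state_csv <- function(state, path) {
  df <- tibble::as_tibble(state)[state_cols]
  df$fixed <- as.integer(df$fixed)
  df$pcp_active <- as.integer(df$pcp_active)
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_state_csv
#' @param time Simulation time to attach (default 0).
#' @export
read_state_csv <- function(path, time = 0) {
  # base read.csv: correctly-rounded double parsing, so positions written by
  # write_state_csv() come back bitwise
  df <- utils::read.csv(path, colClasses = "numeric")
  df$fixed <- as.logical(df$fixed)
  df$pcp_active <- as.logical(df$pcp_active)
  as_cell_state(df, time = time)
}

#' Write a trajectory to disk
#'
#' `csv` writes one state file per sampled frame
#' (`frame_000001.csv`, ...) in the cell-state schema plus a `frames.csv`
#' index with the frame times. `xyz` writes a single multi-frame extended
#' XYZ file (`trajectory.xyz`) with per-atom polarity vector columns
#' (`Properties=species:S:1:pos:R:3:ab:R:3:pcp:R:3`), loadable in standard
#' molecular viewers.
#'
#' @param frames A list of frames (from [simulate_cells()] with
#'   `save_frames = TRUE`) or a `polarsim_run`/`polarsim_sim` containing one.
#' @param dir Output directory (created if needed).
#' @param format `"csv"` or `"xyz"`.
#' @param lambda Lambda weights written into CSV frames.
#' @return The output directory, invisibly.
#' @export
write_trajectory <- function(frames, dir, format = c("csv", "xyz"),
                             lambda = c(1, 0, 0)) {
  format <- match.arg(format)
  if (is.list(frames) && !is.null(frames$frames)) frames <- frames$frames
  if (length(frames) == 0) abort("no frames to write")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (format == "csv") {
    idx <- tibble::tibble(frame = seq_along(frames),
                          time = purrr::map_dbl(frames, "time"),
                          file = sprintf("frame_%06d.csv",
                                         seq_along(frames)))
    purrr::walk2(frames, idx$file, function(fr, f) {
      st <- cell_state(fr$positions, ab = fr$ab, pcp = fr$pcp,
                       lambda = lambda, time = fr$time)
      write_state_csv(st, file.path(dir, f))
    })
    readr::write_csv(idx, file.path(dir, "frames.csv"))
  } else {
    path <- file.path(dir, "trajectory.xyz")
    con <- file(path, open = "w")
    on.exit(close(con))
    for (fr in frames) {
      n <- nrow(fr$positions)
      writeLines(as.character(n), con)
      writeLines(sprintf(
        paste0("Time=%.17g Properties=species:S:1:pos:R:3:ab:R:3:pcp:R:3"),
        fr$time), con)
      m <- cbind(fr$positions, fr$ab, fr$pcp)
      writeLines(paste("C", apply(format(m, digits = 17, trim = TRUE,
                                         scientific = FALSE), 1,
                                  paste, collapse = " ")), con)
    }
  }
  invisible(dir)
}

#' Read a CSV trajectory written by [write_trajectory()]
#'
#' @param dir Directory containing `frames.csv` and the per-frame files.
#' @return A list of `cell_state` objects, one per frame.
#' @export
read_trajectory_csv <- function(dir) {
  idx <- readr::read_csv(file.path(dir, "frames.csv"),
                         col_types = readr::cols(frame = "i", time = "d",
                                                 file = "c"))
  purrr::map2(idx$file, idx$time,
              function(f, t) read_state_csv(file.path(dir, f), time = t))
}

#' Write and read a run manifest
#'
#' The manifest records everything needed to reproduce a scenario run
#' bitwise on the same platform: scenario name, seed, resolved model
#' configuration, scenario parameters, and the package version.
#'
#' @param run A `polarsim_run`.
#' @param path JSON output path.
#' @return `write_manifest()` returns `path` invisibly; `read_manifest()`
#'   the manifest list.
#' @export
write_manifest <- function(run, path) {
  jsonlite::write_json(run$manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Re-run a scenario from its manifest
#'
#' @param manifest A manifest list (or path to a manifest JSON).
#' @param save_frames Keep sampled frames.
#' @return A `polarsim_run` reproducing the original trajectory.
#' @export
replay_manifest <- function(manifest, save_frames = FALSE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  fn <- switch(manifest$scenario,
               bulk_random = scenario_bulk_random,
               boundary = scenario_boundary,
               organoid = scenario_organoid,
               tube = scenario_tube,
               gastrulation = scenario_gastrulation,
               abort(paste0("unknown scenario: ", manifest$scenario)))
  args <- manifest$params
  args$seed <- manifest$seed
  if ("save_frames" %in% names(formals(fn)))
    args$save_frames <- save_frames
  do.call(fn, args)
}
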