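#' Track the in-plane position of a sub-domain over a trajectory
#'
#' Per frame, the geometric center of the tracked selection is projected
#' into the membrane plane relative to that frame's barrel center, so the
#' track is invariant to rigid motions of the whole complex. The canonical
#' use is POTRA5, the periplasmic domain immediately below the barrel, whose
#' in-plane excursions distinguish dynamic from static conformational
#' states.
#'
#' @param traj A [trajectory()].
#' @param selection A [complex_selection()].
#' @param entry Which selection to track; defaults to `selection$potra5`.
#' @param mode Membrane-frame mode (per frame), see [membrane_frame()].
#' @return A `track_series` tibble with columns `time_ns`, `x`, `y`
#'   (angstrom, in-plane, barrel-relative).
#' @export
track_center <- function(traj, selection, entry = NULL, mode = "z_axis") {
  stopifnot(inherits(traj, "trajectory"))
  entry <- entry %||% selection$potra5
  pts <- t(vapply(seq_len(n_frames(traj)), function(i) {
    m <- frame_model(traj, i)
    frame <- membrane_frame(m, selection, mode)
    ctr <- geometric_center(select_atoms(m, entry))
    in_plane(frame, ctr - frame$origin)
  }, numeric(2L)))
  out <- tibble::tibble(time_ns = traj$times, x = pts[, 1L], y = pts[, 2L])
  structure(out, class = c("track_series", class(out)), label = entry$name)
}

#' Displacement of a sub-domain between two conformational states
#'
#' Superposes `b`'s barrel C-alpha atoms onto `a`'s (pairing by residue
#' number) and reports the distance between the two POTRA5 (or other
#' selection) C-alpha geometric centers - e.g. the roughly 13 A separation
#' between the inward-open and outward-open POTRA5 positions.
#'
#' @param a,b [structure_model()]s of the two states.
#' @param selection A [complex_selection()].
#' @param entry Tracked selection; defaults to `selection$potra5`.
#' @return Distance in angstrom.
#' @export
displacement_between_states <- function(a, b, selection, entry = NULL) {
  entry <- entry %||% selection$potra5
  fit <- rmsd_between_models(a, b, sel_entry(selection$barrel$chain,
                                             selection$barrel$resno, "CA",
                                             "barrel_CA"))
  b <- apply_fit(fit, b)
  ca <- geometric_center(select_atoms(a, entry))
  cb <- geometric_center(select_atoms(b, entry))
  sqrt(sum((ca - cb)^2))
}

#' Area explored by a track in the membrane plane
#'
#' Two estimators: the area of the 2D convex hull of the track points
#' (default; deterministic and easy to verify), or an occupancy grid -
#' the number of visited cells times the cell area, which unlike the hull
#' does not credit unvisited interior space.
#'
#' @param track A [track_center()] result (any table with `x`, `y`).
#' @param method `"convex_hull"` or `"occupancy_grid"`.
#' @param cell Occupancy grid cell edge, angstrom.
#' @return Area in square angstrom. Degenerate hull input (< 3 distinct
#'   non-collinear points) returns 0 with a warning.
#' @export
explored_area <- function(track, method = c("convex_hull", "occupancy_grid"),
                          cell = 1) {
  method <- match.arg(method)
  if (method == "occupancy_grid") {
    if (cell <= 0) stop("explored_area: cell must be positive", call. = FALSE)
    cells <- unique(paste(floor(track$x / cell), floor(track$y / cell)))
    return(length(cells) * cell^2)
  }
  pts <- unique(cbind(track$x, track$y))
  if (nrow(pts) < 3L) {
    warning("explored_area: fewer than 3 distinct points; area is 0")
    return(0)
  }
  hull <- grDevices::chull(pts)
  if (length(hull) < 3L) {
    warning("explored_area: collinear points; area is 0")
    return(0)
  }
  polygon_area(pts[hull, , drop = FALSE])
}

# shoelace formula, vertices in ring order
polygon_area <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  xs <- c(x[-1L], x[1L]); ys <- c(y[-1L], y[1L])
  abs(sum(x * ys - xs * y)) / 2
}
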