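#' Build a structure model from an atom table
#'
#' A `structure_model` is a tibble of atoms carrying chain and residue
#' identity plus 3D coordinates in angstrom. It is the common currency of the
#' package: every reader returns one, every selection and metric consumes one.
#'
#' @param atoms Data frame with columns `serial`, `atom` (atom name, e.g.
#'   `"CA"`), `resid` (3-letter residue name), `chain`, `resno` (author
#'   residue numbering, kept verbatim), `ins` (insertion code, `""` if none),
#'   `x`, `y`, `z` (angstrom) and optionally `elem`, `occ`.
#' @param identifier Free-form identifier (e.g. a PDB ID), stored as an
#'   attribute.
#' @param model_index Which model of a multi-model file this is.
#'
#' @return A tibble of class `structure_model`.
#' @export
structure_model <- function(atoms, identifier = "", model_index = 1L) {
  atoms <- tibble::as_tibble(atoms)
  needed <- c("serial", "atom", "resid", "chain", "resno", "x", "y", "z")
  missing <- setdiff(needed, names(atoms))
  if (length(missing) > 0L) {
    stop("structure_model: missing atom columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(atoms) == 0L) {
    stop("structure_model: empty model (no atoms)", call. = FALSE)
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("structure_model: non-finite coordinates", call. = FALSE)
  }
  if (!"ins" %in% names(atoms)) atoms$ins <- ""
  atoms$ins[is.na(atoms$ins)] <- ""
  if (!"occ" %in% names(atoms)) atoms$occ <- 1
  if (!"elem" %in% names(atoms)) atoms$elem <- substr(atoms$atom, 1L, 1L)
  key <- paste(atoms$chain, atoms$resno, atoms$ins, atoms$atom)
  if (anyDuplicated(key)) {
    stop("structure_model: duplicated (chain, resno, atom) keys, e.g. ",
         key[duplicated(key)][1L], call. = FALSE)
  }
  structure(atoms,
            class = c("structure_model", class(tibble::tibble())),
            identifier = identifier,
            model_index = as.integer(model_index))
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %s (model %d): %d atoms, %d chains\n",
              attr(x, "identifier"), attr(x, "model_index"),
              nrow(x), length(unique(x$chain))))
  NextMethod()
}

#' Coordinates of a structure model as an n x 3 matrix
#' @param model A `structure_model`.
#' @return Numeric matrix with columns x, y, z.
#' @export
coords <- function(model) {
  cbind(x = model$x, y = model$y, z = model$z)
}

#' Replace the coordinates of a structure model
#' @param model A `structure_model`.
#' @param xyz n x 3 matrix, or flat vector of length 3n in (x1, y1, z1, ...)
#'   order.
#' @return The model with new coordinates.
#' @export
set_coords <- function(model, xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3L, byrow = TRUE)
  stopifnot(nrow(xyz) == nrow(model))
  model$x <- xyz[, 1L]
  model$y <- xyz[, 2L]
  model$z <- xyz[, 3L]
  model
}

#' Trajectory of frames over one topology
#'
#' Frames share the topology's atom order; coordinates are stored in the
#' bio3d flat convention, one row per frame of `(x1, y1, z1, x2, ...)`.
#'
#' @param topology A `structure_model`.
#' @param xyz Numeric matrix, frames x (3 * n_atoms).
#' @param times Per-frame time stamps in ns, strictly increasing.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(topology, xyz, times = NULL) {
  if (!inherits(topology, "structure_model")) {
    stop("trajectory: topology must be a structure_model", call. = FALSE)
  }
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  if (ncol(xyz) != 3L * nrow(topology)) {
    stop(sprintf(
      "trajectory: frames have %d coordinates but topology needs %d (%d atoms)",
      ncol(xyz), 3L * nrow(topology), nrow(topology)), call. = FALSE)
  }
  if (is.null(times)) times <- seq_len(nrow(xyz)) - 1
  if (length(times) != nrow(xyz)) {
    stop("trajectory: times length must match frame count", call. = FALSE)
  }
  if (nrow(xyz) > 1L && any(diff(times) <= 0)) {
    stop("trajectory: times must be strictly increasing", call. = FALSE)
  }
  structure(list(topology = topology, xyz = xyz, times = as.numeric(times)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d atoms, t = %.3g..%.3g ns\n",
              n_frames(x), nrow(x$topology), min(x$times), max(x$times)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `trajectory`.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' Extract one frame of a trajectory as a structure model
#' @param traj A `trajectory`.
#' @param i Frame index (1-based).
#' @export
frame_model <- function(traj, i) {
  stopifnot(i >= 1L, i <= n_frames(traj))
  set_coords(traj$topology, traj$xyz[i, ])
}
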