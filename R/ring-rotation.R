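#' Build the 0-degree reference for the periplasmic-ring rotation angle
#'
#' The rotation metric measures the signed in-plane angle between two
#' vectors, both anchored at the barrel center (geometric center of the
#' carbonyl carbons of barrel residues 425-810 by default). The reference
#' vector points from the barrel center to the geometric center of all
#' carbonyl carbons of the accessory lipoproteins (BamB, C, D, E) in the
#' reference structure - conventionally the inward-open complex at the start
#' of the simulation, which defines 0 degrees. Accessory components absent
#' from the reference model are excluded, and [rotation_angle()] excludes
#' the same components from the measurement so reference and measurement
#' always count the same bodies.
#'
#' @param reference_model A [structure_model()] (e.g. the frame-0 structure
#'   or an inward-open deposited model).
#' @param selection A [complex_selection()]; its `accessory` entries define
#'   the candidate components.
#' @param mode Membrane-frame mode, see [membrane_frame()].
#' @return A `rotation_reference` carrying the frame, the unit in-plane
#'   reference vector, the accessory set used, and the reference barrel
#'   C-alpha coordinates (used to superpose static structures before
#'   measuring).
#' @export
build_reference <- function(reference_model, selection, mode = "z_axis") {
  frame <- membrane_frame(reference_model, selection, mode)
  present <- accessory_present(reference_model, selection)
  if (length(present) == 0L) {
    stop("build_reference: no accessory component present in the model",
         call. = FALSE)
  }
  acc_center <- accessory_center(reference_model, selection, present)
  v <- in_plane(frame, acc_center - frame$origin)
  len <- sqrt(sum(v^2))
  if (len < 1e-9) {
    stop("build_reference: accessory center projects onto the barrel axis ",
         "(degenerate 0-degree reference)", call. = FALSE)
  }
  barrel_ca <- select_atoms(reference_model,
                            sel_entry(selection$barrel$chain,
                                      selection$barrel$resno, "CA",
                                      "barrel_CA"))
  structure(list(frame = frame, reference_vector = v / len,
                 accessory_set = present,
                 barrel_ca = barrel_ca[, c("chain", "resno", "ins",
                                           "x", "y", "z")],
                 source = attr(reference_model, "identifier")),
            class = "rotation_reference")
}

#' @export
print.rotation_reference <- function(x, ...) {
  cat(sprintf(
    "<rotation_reference> from '%s', accessory set {%s}, vector (%.3f, %.3f)\n",
    x$source, paste(x$accessory_set, collapse = ", "),
    x$reference_vector[1L], x$reference_vector[2L]))
  invisible(x)
}

accessory_present <- function(model, selection) {
  names(selection$accessory)[vapply(selection$accessory, function(e) {
    any(model$chain %in% e$chain)
  }, logical(1L))]
}

accessory_center <- function(model, selection, set) {
  entries <- selection$accessory[set]
  parts <- lapply(entries, function(e) select_atoms(model, e))
  geometric_center(dplyr::bind_rows(parts))
}

#' Periplasmic-ring rotation angle of a structure
#'
#' Signed angle from the reference vector to the current in-plane vector
#' (current accessory carbonyl-carbon center minus current barrel center),
#' measured counterclockwise as viewed from the extracellular space (the
#' +normal side of the membrane frame) and wrapped to (-180, 180]. Accessory
#' components missing from either the reference or the current model are
#' excluded from both sides of the comparison.
#'
#' For a pair of independently deposited structures (`superpose = TRUE`),
#' the mobile structure's barrel C-alpha atoms are first Kabsch-superposed
#' onto the reference barrel so both are measured in the reference membrane
#' frame.
#'
#' @param model A [structure_model()] or a single trajectory frame.
#' @param selection A [complex_selection()].
#' @param reference A [build_reference()] result.
#' @param superpose Superpose the model's barrel onto the reference barrel
#'   first (needed for static structure pairs; frames of a trajectory that
#'   already share the reference coordinate frame do not need it).
#' @return Angle in degrees.
#' @export
rotation_angle <- function(model, selection, reference, superpose = FALSE) {
  stopifnot(inherits(reference, "rotation_reference"))
  set <- intersect(reference$accessory_set,
                   accessory_present(model, selection))
  if (length(set) == 0L) {
    stop("rotation_angle: none of the reference accessory components ",
         "present in the model", call. = FALSE)
  }
  if (superpose) {
    ca <- select_atoms(model, sel_entry(selection$barrel$chain,
                                        selection$barrel$resno, "CA",
                                        "barrel_CA"))
    ka <- paste(ca$chain, ca$resno, ca$ins)
    kb <- paste(reference$barrel_ca$chain, reference$barrel_ca$resno,
                reference$barrel_ca$ins)
    common <- intersect(kb, ka)
    if (length(common) < 3L) {
      stop("rotation_angle: fewer than 3 common barrel C-alpha atoms for ",
           "superposition", call. = FALSE)
    }
    fit <- kabsch_superpose(
      coords(reference$barrel_ca[match(common, kb), ]),
      coords(ca[match(common, ka), ]))
    model <- apply_fit(fit, model)
  }
  frame <- reference$frame
  barrel <- select_atoms(model, selection$barrel)
  acc_center <- accessory_center(model, selection, set)
  v <- in_plane(frame, acc_center - geometric_center(barrel))
  if (sqrt(sum(v^2)) < 1e-9) {
    stop("rotation_angle: degenerate in-plane accessory vector",
         call. = FALSE)
  }
  r <- reference$reference_vector
  ang <- atan2(r[1L] * v[2L] - r[2L] * v[1L], r[1L] * v[1L] + r[2L] * v[2L]) *
    180 / pi
  if (ang <= -180) ang <- ang + 360   # keep the wrap half-open: (-180, 180]
  ang
}

#' Rotation-angle time series over a trajectory
#'
#' One angle per frame against a fixed reference (built from the first frame
#' when not supplied). Angles are emitted raw - wrapped to (-180, 180] -
#' with optional unwrapping for continuity across the branch cut; smoothing,
#' if wanted, is left to [moving_average()].
#'
#' @param traj A [trajectory()].
#' @param selection A [complex_selection()].
#' @param reference Optional [build_reference()] result; default builds it
#'   from frame 1 of `traj`.
#' @param unwrap Add multiples of 360 so consecutive angles never jump by
#'   more than 180 degrees.
#' @return An `angle_series` tibble with columns `time_ns`, `angle_deg`.
#' @export
rotation_series <- function(traj, selection, reference = NULL,
                            unwrap = FALSE) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(reference)) {
    reference <- build_reference(frame_model(traj, 1L), selection)
  }
  angles <- vapply(seq_len(n_frames(traj)), function(i) {
    rotation_angle(frame_model(traj, i), selection, reference)
  }, numeric(1L))
  if (unwrap) {
    angles <- angles + 360 * cumsum(c(0, round(-diff(angles) / 360)))
  }
  out <- tibble::tibble(time_ns = traj$times, angle_deg = angles)
  structure(out, class = c("angle_series", class(out)),
            reference = reference)
}
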