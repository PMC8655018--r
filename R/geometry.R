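#' Membrane frame of a barrel-containing structure
#'
#' An orthonormal right-handed triad `(in_plane_x, in_plane_y, normal)`
#' anchored at the barrel center, with `normal` pointing to the extracellular
#' side. Two construction modes:
#'
#' * `"z_axis"`: the membrane normal is the +z axis of the input coordinates
#'   (the convention of membrane MD systems); the origin is the barrel
#'   center.
#' * `"barrel_principal"`: the normal is the barrel's cylindrical symmetry
#'   axis, found as the spectrally isolated eigenvector of the barrel-atom
#'   covariance (for a cylindrically symmetric shell the two in-plane
#'   eigenvalues are nearly degenerate and the axis carries the odd one out,
#'   whether the barrel is tall or squat). Its sign is flipped if needed so
#'   that it points away from the periplasmic side, defined by the POTRA5
#'   center when resolvable.
#'
#' @param model A [structure_model()].
#' @param selection A [complex_selection()].
#' @param mode `"z_axis"` or `"barrel_principal"`.
#' @return A `membrane_frame` list with `origin`, `normal`, `in_plane_x`,
#'   `in_plane_y`.
#' @export
membrane_frame <- function(model, selection,
                           mode = c("z_axis", "barrel_principal")) {
  mode <- match.arg(mode)
  barrel <- select_atoms(model, selection$barrel)
  origin <- geometric_center(barrel)
  if (mode == "z_axis") {
    normal <- c(0, 0, 1)
  } else {
    xyz <- sweep(coords(barrel), 2L, origin)
    cv <- crossprod(xyz) / nrow(xyz)
    eg <- eigen(cv, symmetric = TRUE)
    ev <- eg$values            # descending
    if (ev[1L] - ev[3L] < 1e-9) {
      stop("membrane_frame: degenerate barrel atom distribution",
           call. = FALSE)
    }
    # unique-eigenvalue rule: larger spectral gap isolates the symmetry axis
    idx <- if ((ev[1L] - ev[2L]) > (ev[2L] - ev[3L])) 1L else 3L
    normal <- eg$vectors[, idx]
    flip_ref <- tryCatch(
      geometric_center(select_atoms(model, selection$potra5)),
      error = function(e) NULL)
    if (!is.null(flip_ref)) {
      if (sum(normal * (flip_ref - origin)) > 0) normal <- -normal
    } else if (normal[3L] < 0) {
      normal <- -normal
    }
  }
  seed <- if (abs(normal[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  ipx <- seed - sum(seed * normal) * normal
  ipx <- ipx / sqrt(sum(ipx^2))
  ipy <- cross3(normal, ipx)
  structure(list(origin = unname(origin), normal = unname(normal),
                 in_plane_x = ipx, in_plane_y = ipy, mode = mode),
            class = "membrane_frame")
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# project a 3-vector (or the offset of a point from the frame origin) into
# frame in-plane coordinates
in_plane <- function(frame, v) {
  c(sum(v * frame$in_plane_x), sum(v * frame$in_plane_y))
}

#' Kabsch superposition of two paired atom sets
#'
#' Finds the proper rotation and translation minimising the RMSD between two
#' equally sized, order-paired coordinate sets (SVD formulation with the
#' determinant correction), and reports the post-fit RMSD.
#'
#' @param reference,mobile n x 3 coordinate matrices or `structure_model`
#'   subsets, paired by row order, n >= 3.
#' @return A `kabsch_fit` list: `rotation` (3 x 3, applied on the right of a
#'   row-vector coordinate matrix), `translation`, `rmsd` (angstrom), `n`.
#'   Apply with [apply_fit()]. [generics::tidy()] and [generics::glance()]
#'   methods are provided.
#' @export
kabsch_superpose <- function(reference, mobile) {
  P <- as_xyz_matrix(reference)
  Q <- as_xyz_matrix(mobile)
  if (nrow(P) != nrow(Q)) {
    stop(sprintf("kabsch_superpose: atom counts differ (%d vs %d)",
                 nrow(P), nrow(Q)), call. = FALSE)
  }
  if (nrow(P) < 3L) {
    stop("kabsch_superpose: need at least 3 paired atoms", call. = FALSE)
  }
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2L, cp); Q0 <- sweep(Q, 2L, cq)
  H <- crossprod(Q0, P0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- Q0 %*% t(R)   # rows are coordinates, so the rotation transposes
  rmsd <- sqrt(mean(rowSums((fitted - P0)^2)))
  translation <- cp - as.vector(R %*% cq)
  structure(list(rotation = R, translation = translation,
                 rmsd = rmsd, n = nrow(P)),
            class = "kabsch_fit")
}

as_xyz_matrix <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 3L)
    return(unname(x))
  }
  if (is.data.frame(x)) return(unname(coords(x)))
  stop("expected an n x 3 matrix or an atom table", call. = FALSE)
}

#' Apply a Kabsch fit to coordinates or a model
#'
#' @param fit A `kabsch_fit` from [kabsch_superpose()].
#' @param x An n x 3 matrix, a `structure_model`, or a `trajectory`.
#' @return `x` transformed into the reference frame of the fit.
#' @export
apply_fit <- function(fit, x) {
  stopifnot(inherits(fit, "kabsch_fit"))
  tf <- function(m) sweep(m %*% t(fit$rotation), 2L, -fit$translation)
  if (is.matrix(x)) return(tf(x))
  if (inherits(x, "structure_model")) return(set_coords(x, tf(coords(x))))
  if (inherits(x, "trajectory")) {
    xyz <- t(apply(x$xyz, 1L, function(row) {
      as.vector(t(tf(matrix(row, ncol = 3L, byrow = TRUE))))
    }))
    x$xyz <- xyz
    return(x)
  }
  stop("apply_fit: unsupported input", call. = FALSE)
}

#' @export
print.kabsch_fit <- function(x, ...) {
  cat(sprintf("<kabsch_fit> %d paired atoms, post-fit RMSD %.4f A\n",
              x$n, x$rmsd))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy kabsch_fit
#' @export
tidy.kabsch_fit <- function(x, ...) {
  tibble::tibble(
    term = c("rmsd", "n_atoms", sprintf("translation_%s", c("x", "y", "z")),
             "rotation_angle_deg"),
    estimate = c(x$rmsd, x$n, x$translation,
                 acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) *
                   180 / pi))
}

#' @method glance kabsch_fit
#' @export
glance.kabsch_fit <- function(x, ...) {
  tibble::tibble(rmsd = x$rmsd, n_atoms = x$n)
}

#' RMSD between two structures under residue/name pairing
#'
#' Atoms are paired by the intersection of `(chain, resno, atom name)` under
#' the requested atom class (no sequence alignment; deposited BAM structures
#' share author numbering), Kabsch-fitted, and the post-fit RMSD reported
#' together with the number of paired atoms.
#'
#' @param a,b [structure_model()]s.
#' @param entry A [sel_entry()]; default pairs C-alpha atoms of everything.
#' @return A `kabsch_fit` (see [kabsch_superpose()]); `glance()` it for a
#'   one-row summary.
#' @export
rmsd_between_models <- function(a, b, entry = NULL) {
  if (!is.null(entry)) {
    a <- select_atoms(a, entry)
    b <- select_atoms(b, entry)
  } else {
    a <- a[a$atom == "CA", , drop = FALSE]
    b <- b[b$atom == "CA", , drop = FALSE]
  }
  ka <- paste(a$chain, a$resno, a$ins, a$atom)
  kb <- paste(b$chain, b$resno, b$ins, b$atom)
  common <- intersect(ka, kb)
  if (length(common) < 3L) {
    stop(sprintf("rmsd_between_models: only %d common atoms under pairing",
                 length(common)), call. = FALSE)
  }
  kabsch_superpose(coords(a[match(common, ka), ]),
                   coords(b[match(common, kb), ]))
}

#' Longest in-plane diameter of the barrel
#'
#' Maximum pairwise distance between barrel C-alpha atoms after projection
#' into the membrane plane; the quantity quoted as the width of the BamA
#' barrel along its longest axis (about 5 nm).
#'
#' @param model A [structure_model()].
#' @param selection A [complex_selection()].
#' @param mode Frame mode passed to [membrane_frame()].
#' @return Diameter in angstrom.
#' @export
barrel_inplane_diameter <- function(model, selection, mode = "z_axis") {
  frame <- membrane_frame(model, selection, mode)
  ca <- select_atoms(model, sel_entry(selection$barrel$chain,
                                      selection$barrel$resno, "CA",
                                      "barrel_CA"))
  xyz <- sweep(coords(ca), 2L, frame$origin)
  pts <- cbind(xyz %*% frame$in_plane_x, xyz %*% frame$in_plane_y)
  hull <- grDevices::chull(pts)
  max(stats::dist(pts[hull, , drop = FALSE]))
}
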