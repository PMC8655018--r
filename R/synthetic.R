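#' Specification for a synthetic BAM-like toy complex
#'
#' The generator emulates the geometry the metrics care about and nothing
#' else: a cylindrical beta-barrel-like shell of pseudo-residues along +z
#' (the membrane normal), compact accessory bodies below the membrane plane
#' at controllable in-plane angles (the periplasmic lipoprotein ring), and a
#' POTRA5-like cluster at a controllable offset. Pseudo-residues carry real
#' backbone atom names (N, CA, C, O, CB) and BamA-style author numbering so
#' every selection and metric runs unchanged on synthetic and deposited
#' structures.
#'
#' @param barrel_radius Barrel cylinder radius, angstrom (default 25, i.e. a
#'   50 A widest diameter, the size quoted for the BamA barrel).
#' @param barrel_height Barrel height, angstrom.
#' @param n_barrel_residues Number of barrel pseudo-residues (>= 8), spread
#'   over author numbers 425-810.
#' @param n_accessory_bodies Number of accessory bodies (chains B, C, D, E).
#' @param accessory_radius_offset Accessory center distance beyond the
#'   barrel radius, angstrom.
#' @param accessory_angles In-plane angular positions of the bodies,
#'   degrees; recycled to `n_accessory_bodies`. The default places the four
#'   bodies along a 180-degree arc on one side of the barrel, as the
#'   lipoprotein ring sits to one side rather than encircling the barrel,
#'   which keeps the ring's combined center well off the barrel axis - the
#'   property the rotation metric relies on.
#' @param n_accessory_residues Pseudo-residues per accessory body.
#' @param potra_offset 3-vector, angstrom: POTRA5 cluster center.
#' @param noise_sigma Isotropic Gaussian positional noise per atom,
#'   angstrom (applied fresh per frame by the trajectory generators).
#' @param seed Integer seed; fixed seed gives bit-identical structures.
#' @return A `toy_spec` list.
#' @export
toy_spec <- function(barrel_radius = 25, barrel_height = 30,
                     n_barrel_residues = 64, n_accessory_bodies = 4,
                     accessory_radius_offset = 20,
                     accessory_angles = c(-60, 0, 60, 120),
                     n_accessory_residues = 40,
                     potra_offset = c(14, -8, -22),
                     noise_sigma = 0, seed = 1L) {
  if (barrel_radius <= 0 || barrel_height <= 0) {
    stop("toy_spec: barrel dimensions must be positive", call. = FALSE)
  }
  if (n_barrel_residues < 8L) {
    stop("toy_spec: need at least 8 barrel residues", call. = FALSE)
  }
  if (n_accessory_bodies < 0L || n_accessory_bodies > 4L) {
    stop("toy_spec: accessory bodies must number 0-4", call. = FALSE)
  }
  structure(list(barrel_radius = barrel_radius,
                 barrel_height = barrel_height,
                 n_barrel_residues = as.integer(n_barrel_residues),
                 n_accessory_bodies = as.integer(n_accessory_bodies),
                 accessory_radius_offset = accessory_radius_offset,
                 accessory_angles = rep_len(accessory_angles,
                                            max(1L, n_accessory_bodies)),
                 n_accessory_residues = as.integer(n_accessory_residues),
                 potra_offset = potra_offset,
                 noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "toy_spec")
}

rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3L, 3L)
}

# one pseudo-residue: backbone-named atoms in a small local arrangement at
# center p with radial/tangent/axial unit vectors (u, t, k)
residue_atoms <- function(resno, chain, p, u, t, k) {
  offs <- rbind(N  = -1.4 * t,
                CA = c(0, 0, 0),
                C  = 1.4 * t,
                O  = 1.4 * t + 1.23 * u,
                CB = 1.5 * u + 0.5 * k)
  tibble::tibble(atom = rownames(offs),
                 resid = "ALA", chain = chain, resno = as.integer(resno),
                 x = unname(p[1L] + offs[, 1L]),
                 y = unname(p[2L] + offs[, 2L]),
                 z = unname(p[3L] + offs[, 3L]))
}

# compact cluster of pseudo-residues around a center (offsets fixed by the
# spec seed so topology is reproducible)
cluster_atoms <- function(resnos, chain, center, spread = 4) {
  purrr::map_dfr(seq_along(resnos), function(i) {
    off <- stats::rnorm(3L, sd = spread)
    residue_atoms(resnos[i], chain, center + off,
                  u = c(1, 0, 0), t = c(0, 1, 0), k = c(0, 0, 1))
  })
}

#' Generate a synthetic BAM-like complex
#'
#' See [toy_spec()] for what the geometry emulates. Deterministic for a
#' fixed spec seed. Barrel residues are chain A, numbered evenly across
#' 425-810; accessory bodies are chains B-E; the POTRA5 cluster is chain A,
#' residues 344-421.
#'
#' @param spec A [toy_spec()].
#' @return A [structure_model()].
#' @export
make_toy_complex <- function(spec) {
  stopifnot(inherits(spec, "toy_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  nb <- spec$n_barrel_residues
  resnos <- unique(round(seq(425, 810, length.out = nb)))
  ang <- 2 * pi * (resnos - 425) / 386
  zrow <- spec$barrel_height * (((seq_along(resnos) - 1L) %% 4L) / 3 - 0.5)
  barrel <- purrr::map_dfr(seq_along(resnos), function(i) {
    u <- c(cos(ang[i]), sin(ang[i]), 0)
    t <- c(-sin(ang[i]), cos(ang[i]), 0)
    p <- spec$barrel_radius * u + c(0, 0, zrow[i])
    residue_atoms(resnos[i], "A", p, u, t, c(0, 0, 1))
  })
  parts <- list(barrel)
  if (spec$n_accessory_bodies > 0L) {
    chains <- c("B", "C", "D", "E")[seq_len(spec$n_accessory_bodies)]
    r_acc <- spec$barrel_radius + spec$accessory_radius_offset
    z_acc <- -(spec$barrel_height / 2 + 15)
    for (i in seq_along(chains)) {
      th <- spec$accessory_angles[i] * pi / 180
      center <- c(r_acc * cos(th), r_acc * sin(th), z_acc)
      parts[[length(parts) + 1L]] <-
        cluster_atoms(seq_len(spec$n_accessory_residues), chains[i], center)
    }
  }
  parts[[length(parts) + 1L]] <-
    cluster_atoms(344:421, "A", spec$potra_offset)
  atoms <- dplyr::bind_rows(parts)
  atoms$serial <- seq_len(nrow(atoms))
  atoms$ins <- ""
  structure_model(atoms, identifier = "toy_complex")
}

# indices (into the topology) of atoms that belong to the periplasmic ring:
# accessory chains plus POTRA residues (chain A below the barrel range)
ring_atom_idx <- function(model) {
  which(model$chain %in% c("B", "C", "D", "E") |
          (model$chain == "A" & model$resno < 425))
}

# build a trajectory by applying per-frame coordinate transforms + noise
frames_from_transform <- function(model, n, sigma, dt_ns, transform) {
  base <- coords(model)
  xyz <- matrix(0, nrow = n, ncol = 3L * nrow(base))
  for (f in seq_len(n)) {
    cf <- transform(base, f)
    if (sigma > 0) {
      cf <- cf + matrix(stats::rnorm(length(cf), sd = sigma), ncol = 3L)
    }
    xyz[f, ] <- as.vector(t(cf))
  }
  trajectory(model, xyz, times = (seq_len(n) - 1) * dt_ns)
}

#' Synthetic trajectory with a scripted ring rotation
#'
#' The accessory bodies and the POTRA cluster rotate rigidly about +z (the
#' barrel axis) by the scheduled angle each frame while the barrel stays
#' fixed; fresh isotropic noise is applied to every atom every frame. The
#' schedule is the ground truth that [rotation_series()] should recover.
#'
#' @param spec A [toy_spec()].
#' @param angle_schedule Degrees per frame.
#' @param dt_ns Frame spacing, ns.
#' @return A [trajectory()]; the schedule is stored in attribute
#'   `ground_truth`.
#' @export
make_rotation_trajectory <- function(spec, angle_schedule, dt_ns = 1) {
  if (length(angle_schedule) == 0L) {
    stop("make_rotation_trajectory: empty schedule", call. = FALSE)
  }
  model <- make_toy_complex(spec)
  idx <- ring_atom_idx(model)
  # rotate about the barrel axis as the metric defines it: the vertical
  # line through the barrel carbonyl-carbon center
  pivot <- geometric_center(model[model$chain == "A" & model$atom == "C" &
                                    model$resno >= 425, , drop = FALSE])
  pivot[3L] <- 0
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed + 1L)
  traj <- frames_from_transform(
    model, length(angle_schedule), spec$noise_sigma, dt_ns,
    function(base, f) {
      out <- base
      ring <- sweep(base[idx, , drop = FALSE], 2L, pivot)
      out[idx, ] <- sweep(ring %*% t(rot_z(angle_schedule[f])), 2L, -pivot)
      out
    })
  attr(traj, "ground_truth") <- angle_schedule
  traj
}

#' Synthetic two-strand seam trajectory with a scripted bond count
#'
#' Builds an antiparallel two-strand backbone (chain A; acceptor strand
#' residues from 425 up, donor strand residues from 807 down, the BamA
#' beta1/beta16 register) in which exactly `bonds_schedule[f]` register
#' pairs sit at a canonical 2.9 A N...O hydrogen-bond geometry in frame `f`
#' and every other pair is at 6.5 A or farther. With a schedule of zeros
#' the strands are fully separated (no contact at all), which is the open
#' seam.
#'
#' @param bonds_schedule Integer bond counts per frame, each within the
#'   register length.
#' @param n_register Number of register pairs (max schedulable bonds).
#' @param noise_sigma Per-atom Gaussian noise, angstrom.
#' @param seed Integer seed.
#' @param dt_ns Frame spacing, ns.
#' @return A [trajectory()]; schedule in attribute `ground_truth`.
#' @export
make_seam_trajectory <- function(bonds_schedule, n_register = 8L,
                                 noise_sigma = 0, seed = 1L, dt_ns = 1) {
  if (length(bonds_schedule) == 0L) {
    stop("make_seam_trajectory: empty schedule", call. = FALSE)
  }
  if (any(bonds_schedule < 0L) || any(bonds_schedule > n_register)) {
    stop(sprintf(
      "make_seam_trajectory: schedule values must lie in [0, %d]",
      n_register), call. = FALSE)
  }
  spacing <- 3.4   # beta-strand rise per residue
  # acceptor strand: N, CA, C along y; carbonyl O points +x toward the donor
  acceptor <- purrr::map_dfr(seq_len(n_register), function(i) {
    residue_atoms(424L + i, "A", c(0, spacing * i, 0),
                  u = c(1, 0, 0), t = c(0, 1, 0), k = c(0, 0, 1))
  })
  # donor strand base geometry at unit separation; per frame the x offset of
  # each residue is set by the schedule (bonded 2.9 A, unbonded >= 6.5 A)
  donor <- purrr::map_dfr(seq_len(n_register), function(i) {
    residue_atoms(808L - i, "A", c(0, spacing * i + 1.4, 0),
                  u = c(1, 0, 0), t = c(0, -1, 0), k = c(0, 0, 1))
  })
  atoms <- dplyr::bind_rows(acceptor, donor)
  atoms$serial <- seq_len(nrow(atoms))
  model <- structure_model(atoms, identifier = "toy_seam")
  donor_rows <- which(model$resno >= 800)
  # x position of the acceptor O is 1.23 + 1.4 (wait: O = C + 1.23 u, C at
  # +1.4 t) -> O x = 1.23; donor N...O distance along x = donor_N_x - 1.23
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  traj <- frames_from_transform(
    model, length(bonds_schedule), noise_sigma, dt_ns,
    function(base, f) {
      k <- bonds_schedule[f]
      out <- base
      for (i in seq_len(n_register)) {
        res <- 808L - i
        rows <- donor_rows[model$resno[donor_rows] == res]
        dx <- if (k == 0L) 20 else if (i <= k) 2.9 else 6.5
        out[rows, 1L] <- base[rows, 1L] + 1.23 + dx
      }
      out
    })
  attr(traj, "ground_truth") <- bonds_schedule
  traj
}

#' Synthetic trajectory with a drifting POTRA cluster
#'
#' The POTRA cluster translates along a piecewise-linear in-plane path
#' through the supplied waypoints while barrel and accessory bodies stay
#' fixed; ground truth for [track_center()] and [explored_area()].
#'
#' @param spec A [toy_spec()].
#' @param waypoints k x 2 matrix of in-plane displacements (angstrom,
#'   relative to the spec's POTRA center), k >= 2.
#' @param n_frames Frames to interpolate along the path.
#' @param dt_ns Frame spacing, ns.
#' @return A [trajectory()]; the per-frame displacement path is stored in
#'   attribute `ground_truth`.
#' @export
make_drift_trajectory <- function(spec, waypoints, n_frames = 100L,
                                  dt_ns = 1) {
  waypoints <- as.matrix(waypoints)
  if (nrow(waypoints) < 2L || ncol(waypoints) != 2L) {
    stop("make_drift_trajectory: need a k x 2 waypoint matrix with k >= 2",
         call. = FALSE)
  }
  model <- make_toy_complex(spec)
  idx <- which(model$chain == "A" & model$resno >= 344 & model$resno <= 421)
  s <- seq(0, 1, length.out = n_frames)
  seg <- seq(0, 1, length.out = nrow(waypoints))
  path <- cbind(stats::approx(seg, waypoints[, 1L], xout = s)$y,
                stats::approx(seg, waypoints[, 2L], xout = s)$y)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed + 2L)
  traj <- frames_from_transform(
    model, n_frames, spec$noise_sigma, dt_ns,
    function(base, f) {
      out <- base
      out[idx, 1L] <- base[idx, 1L] + path[f, 1L]
      out[idx, 2L] <- base[idx, 2L] + path[f, 2L]
      out
    })
  attr(traj, "ground_truth") <- path
  traj
}
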