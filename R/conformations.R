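#' Synthetic inward-open / outward-open conformational state pair
#'
#' Generates a matched pair of synthetic BAM-like structures encoding the
#' geometric relationships that distinguish the two principal conformational
#' states, for exercising the state-comparison pipelines (rotation angle,
#' POTRA5 displacement, crosslink screening, RMSD) end to end without any
#' external structure. These are synthetic stand-ins, not deposited
#' coordinates: the state-defining parameters below are inputs, and the
#' package's metrics recover them through the same code paths used on real
#' structures.
#'
#' Relative to the inward-open model, the outward-open model has:
#' * the accessory ring (chains B-E) and the POTRA5 cluster rotated by
#'   `rotation_deg` counterclockwise about the barrel axis (viewed from the
#'   extracellular side);
#' * the POTRA5 cluster center displaced by `potra_displacement` angstrom in
#'   the membrane plane (tucked under the barrel);
#' * seam / loop marker residues (425, 431, 502, 503, 583, 584, 681, 706,
#'   807, 808 plus POTRA5 393, 396) placed so that each conformation-locking
#'   cysteine pair is within disulfide range in its intended state and
#'   15-23 A apart in the opposite state, the published design geometry.
#'
#' @param spec A [toy_spec()]; its seed fixes the shared scaffold.
#' @param rotation_deg Ring rotation between the states, degrees
#'   (default 63, the separation of the deposited inward- and outward-open
#'   reference structures).
#' @param potra_displacement POTRA5 center displacement between the states,
#'   angstrom (default 13).
#' @return Named list of two [structure_model()]s: `inward_open`,
#'   `outward_open`.
#' @export
make_state_pair <- function(spec = toy_spec(), rotation_deg = 63,
                            potra_displacement = 13) {
  base <- make_toy_complex(spec)
  # marker residues live on the barrel wall (cylinder of the spec's barrel
  # radius); the seam shear and loop separation between the states are
  # expressed as sliding along the wall, so the barrel stays barrel-sized
  on_wall <- function(theta_deg, z, r = spec$barrel_radius) {
    th <- theta_deg * pi / 180
    c(r * cos(th), r * sin(th), z)
  }
  markers_in <- rbind(
    "425" = on_wall(-5, 5),
    "431" = on_wall(9, -4),
    "807" = on_wall(9, 1),       # 431/807 at 5 A: inward seam closed
    "808" = on_wall(-45, 3),     # 425/808 ~17 A apart
    "502" = on_wall(100, 18),    # extracellular loop 3
    "706" = on_wall(107, 15),    # loop 6 near loop 3: 502/706 ~4.5 A
    "503" = on_wall(103, 17),
    "681" = on_wall(55, 12),     # 503/681 ~21 A
    "583" = on_wall(-100, -18),  # periplasmic turn 4
    "584" = on_wall(-104, -19))
  markers_out <- markers_in
  markers_out["807", ] <- on_wall(45, 2)    # seam shears open: 431/807 ~17 A
  markers_out["808", ] <- on_wall(-8, 2)    # 425/808 closes to ~3.5 A
  markers_out["706", ] <- on_wall(150, 16)  # loops separate: 502/706 ~21 A
  markers_out["681", ] <- on_wall(108, 14)  # 503/681 closes to ~4 A
  # POTRA5 rigid-body centers; 393/396 keep fixed internal offsets so the
  # POTRA5-T4 pairs bond only when the domain is tucked under the barrel
  # (near turn 4), and separate when it swings away in the inward state
  ctr_out <- c(-4, -21, -23)
  u <- c(1, 1, 0) / sqrt(2)
  ctr_in <- ctr_out + potra_displacement * u
  potra_offsets <- rbind("393" = c(-1.5, -3, 3.5), "396" = c(0, -2.5, 4))

  place <- function(model, markers, potra_ctr, ring_rotation) {
    keep <- !(model$chain == "A" &
                model$resno %in% as.integer(rownames(markers)))
    model <- model[keep, , drop = FALSE]
    extra <- purrr::map_dfr(rownames(markers), function(rn) {
      residue_atoms(as.integer(rn), "A", markers[rn, ],
                    u = c(1, 0, 0), t = c(0, 1, 0), k = c(0, 0, 1))
    })
    # rebuild the POTRA5 cluster (344-421) about the state's center,
    # deterministic offsets shared by both states
    pot_rows <- model$chain == "A" & model$resno >= 344 & model$resno <= 421
    pot <- model[pot_rows, , drop = FALSE]
    old_ctr <- geometric_center(pot)
    pot$x <- pot$x - old_ctr[1L] + potra_ctr[1L]
    pot$y <- pot$y - old_ctr[2L] + potra_ctr[2L]
    pot$z <- pot$z - old_ctr[3L] + potra_ctr[3L]
    for (rn in rownames(potra_offsets)) {
      rows <- pot$resno == as.integer(rn)
      tgt <- potra_ctr + potra_offsets[rn, ]
      ctr_res <- geometric_center(pot[rows & pot$atom == "CA", , drop = FALSE])
      pot$x[rows] <- pot$x[rows] - ctr_res[1L] + tgt[1L]
      pot$y[rows] <- pot$y[rows] - ctr_res[2L] + tgt[2L]
      pot$z[rows] <- pot$z[rows] - ctr_res[3L] + tgt[3L]
    }
    model <- dplyr::bind_rows(model[!pot_rows, , drop = FALSE], pot, extra)
    if (ring_rotation != 0) {
      # rotate the lipoprotein ring about the barrel axis as the metric
      # defines it: the vertical line through the barrel carbonyl center
      pivot <- geometric_center(
        model[model$chain == "A" & model$atom == "C" &
                model$resno >= 425 & model$resno <= 810, , drop = FALSE])
      pivot[3L] <- 0
      idx <- which(model$chain %in% c("B", "C", "D", "E"))
      xyz <- coords(model)
      ring <- sweep(xyz[idx, , drop = FALSE], 2L, pivot)
      xyz[idx, ] <- sweep(ring %*% t(rot_z(ring_rotation)), 2L, -pivot)
      model <- set_coords(model, xyz)
    }
    model$serial <- seq_len(nrow(model))
    tibble::as_tibble(model)
  }

  inward <- place(base, markers_in, ctr_in, 0)
  outward <- place(base, markers_out, ctr_out, rotation_deg)
  list(inward_open = structure_model(inward,
                                     identifier = "synthetic_inward_open"),
       outward_open = structure_model(outward,
                                      identifier = "synthetic_outward_open"))
}

#' Perturb a model with isotropic coordinate noise
#'
#' Adds i.i.d. Gaussian noise to every coordinate - a synthetic emulation of
#' the coordinate differences between independently refined models of the
#' same conformation. The expected all-atom post-fit RMSD of the perturbed
#' model against the original is close to `sqrt(3) * sigma`.
#'
#' @param model A [structure_model()].
#' @param sigma Noise standard deviation per coordinate, angstrom.
#' @param seed Integer seed.
#' @return The perturbed model.
#' @export
perturb_model <- function(model, sigma, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  xyz <- coords(model) + matrix(stats::rnorm(3L * nrow(model), sd = sigma),
                                ncol = 3L)
  out <- set_coords(model, xyz)
  attr(out, "identifier") <- paste0(attr(model, "identifier"), "_perturbed")
  out
}
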