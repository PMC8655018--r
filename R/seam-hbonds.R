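#' Backbone hydrogen-bond criteria
#'
#' The counts in the seam time series depend on a geometric definition the
#' user controls. Defaults are the conventional backbone cutoffs: donor to
#' acceptor N...O distance at most 3.5 A, and an angular condition - with
#' explicit amide hydrogens, D-H...A angle at least 150 degrees; without
#' hydrogens (the usual case for deposited structures and the synthetic
#' generator), the N...O=C angle at the acceptor must be at least 120
#' degrees.
#'
#' @param donor_acceptor_max N...O distance cutoff, angstrom.
#' @param angle_min Angle cutoff in degrees; interpreted at the donor
#'   (D-H...A) with explicit H, at the acceptor (N...O=C) without.
#' @param use_explicit_H Require and use amide H atoms.
#' @return An `hbond_criteria` list.
#' @export
hbond_criteria <- function(donor_acceptor_max = 3.5,
                           angle_min = if (use_explicit_H) 150 else 120,
                           use_explicit_H = FALSE) {
  if (donor_acceptor_max <= 0) {
    stop("hbond_criteria: donor_acceptor_max must be positive", call. = FALSE)
  }
  if (angle_min <= 0 || angle_min > 180) {
    stop("hbond_criteria: angle_min must be in (0, 180]", call. = FALSE)
  }
  structure(list(donor_acceptor_max = donor_acceptor_max,
                 angle_min = angle_min,
                 use_explicit_H = isTRUE(use_explicit_H)),
            class = "hbond_criteria")
}

# residue-wise backbone atom tables for one strand selection
strand_backbone <- function(model, entry) {
  atoms <- select_atoms(model, sel_entry(entry$chain, entry$resno,
                                         "all", entry$name))
  atoms <- atoms[atoms$atom %in% c("N", "C", "O", "H"), , drop = FALSE]
  tidyr::pivot_wider(
    dplyr::select(atoms, "chain", "resno", "atom", "x", "y", "z"),
    names_from = "atom", values_from = c("x", "y", "z"))
}

angle_deg <- function(v1, v2) {
  num <- rowSums(v1 * v2)
  den <- sqrt(rowSums(v1^2) * rowSums(v2^2))
  acos(pmin(1, pmax(-1, num / den))) * 180 / pi
}

# bonds with donors on `don` strand and acceptors on `acc` strand;
# one bond per donor (nearest qualifying acceptor)
hbonds_one_way <- function(don, acc, criteria) {
  need <- function(df, col, what, side) {
    if (!col %in% names(df) || anyNA(df[[col]])) {
      bad <- if (col %in% names(df)) df$resno[is.na(df[[col]])][1L]
             else df$resno[1L]
      stop(sprintf("detect_backbone_hbonds: residue %s missing backbone %s (%s)",
                   bad, what, side), call. = FALSE)
    }
  }
  need(don, "x_N", "N", "donor strand")
  need(acc, "x_O", "O", "acceptor strand")
  need(acc, "x_C", "C", "acceptor strand")
  if (criteria$use_explicit_H) need(don, "x_H", "H", "donor strand")
  N <- as.matrix(don[, c("x_N", "y_N", "z_N")])
  O <- as.matrix(acc[, c("x_O", "y_O", "z_O")])
  C <- as.matrix(acc[, c("x_C", "y_C", "z_C")])
  nd <- nrow(don); na <- nrow(acc)
  out <- vector("list", nd)
  for (i in seq_len(nd)) {
    dvec <- sweep(O, 2L, N[i, ])
    dist <- sqrt(rowSums(dvec^2))
    ok <- dist <= criteria$donor_acceptor_max
    if (any(ok)) {
      if (criteria$use_explicit_H) {
        H <- as.matrix(don[, c("x_H", "y_H", "z_H")])
        # D-H...A angle at the hydrogen: between H->N(=D) and H->O(=A)
        hd <- matrix(N[i, ] - H[i, ], nrow = na, ncol = 3L, byrow = TRUE)
        ha <- sweep(O, 2L, H[i, ])
        ang <- angle_deg(hd, ha)
      } else {
        # N...O=C angle at the acceptor oxygen
        ang <- angle_deg(-dvec, C - O)
      }
      ok <- ok & ang >= criteria$angle_min
    }
    if (any(ok)) {
      j <- which(ok)[which.min(dist[ok])]
      out[[i]] <- tibble::tibble(
        donor_chain = don$chain[i], donor_resno = don$resno[i],
        acceptor_chain = acc$chain[j], acceptor_resno = acc$resno[j],
        distance = dist[j], angle = ang[j])
    }
  }
  dplyr::bind_rows(out)
}

#' Detect backbone hydrogen bonds between the two lateral-seam strands
#'
#' Bonds are counted in both directions (strand-1 donors to strand-16
#' acceptors and vice versa); each donor is matched to at most one acceptor,
#' the nearest that satisfies the criteria, which keeps the small integer
#' per-frame counts free of double-counted bifurcated contacts.
#'
#' @param model A [structure_model()] (one frame).
#' @param seam1,seam16 [sel_entry()]s for the two strands.
#' @param criteria An [hbond_criteria()].
#' @return Tibble with one row per bond: donor/acceptor chain and residue,
#'   `distance` (A), `angle` (deg), `direction`.
#' @export
detect_backbone_hbonds <- function(model, seam1, seam16,
                                   criteria = hbond_criteria()) {
  s1 <- strand_backbone(model, seam1)
  s16 <- strand_backbone(model, seam16)
  fwd <- hbonds_one_way(s1, s16, criteria)
  rev <- hbonds_one_way(s16, s1, criteria)
  if (nrow(fwd) > 0L) fwd$direction <- "seam1_donor"
  if (nrow(rev) > 0L) rev$direction <- "seam16_donor"
  dplyr::bind_rows(fwd, rev)
}

# number of N...O contact pairs within the distance cutoff, either
# direction, ignoring the angular term (used by the open/tenuous rule)
seam_contact_count <- function(model, seam1, seam16, criteria) {
  s1 <- strand_backbone(model, seam1)
  s16 <- strand_backbone(model, seam16)
  count_dir <- function(don, acc) {
    if (!"x_N" %in% names(don) || !"x_O" %in% names(acc)) return(0L)
    N <- as.matrix(don[, c("x_N", "y_N", "z_N")])
    O <- as.matrix(acc[, c("x_O", "y_O", "z_O")])
    d2 <- outer(rowSums(N^2), rowSums(O^2), "+") - 2 * N %*% t(O)
    sum(d2 <= criteria$donor_acceptor_max^2 + 1e-12)
  }
  count_dir(s1, s16) + count_dir(s16, s1)
}

#' Centered moving average with shrinking edge windows
#'
#' @param x Numeric vector.
#' @param window Odd window length in frames; 1 is the identity.
#' @return Numeric vector of the same length; at the edges the window
#'   shrinks symmetrically to what is available.
#' @export
moving_average <- function(x, window) {
  if (window < 1L || window %% 2L == 0L) {
    stop("moving_average: window must be a positive odd integer",
         call. = FALSE)
  }
  n <- length(x)
  half <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - half):min(n, i + half)])
  }, numeric(1L))
}

#' Hydrogen-bond count time series at the lateral seam
#'
#' Per-frame backbone hydrogen-bond counts between the two seam strands,
#' plus a centered moving average (the quantity plotted against time when
#' monitoring seam closure).
#'
#' @param traj A [trajectory()].
#' @param selection A [complex_selection()] providing `seam1` and `seam16`.
#' @param criteria An [hbond_criteria()].
#' @param window Odd moving-average window in frames (default 51).
#' @return An `hbond_series` tibble: `time_ns`, `count`, `smoothed`,
#'   `n_contacts` (distance-only contact pairs, used by
#'   [classify_seam_state()]), and a `bonds` list-column of per-frame bond
#'   tables.
#' @export
hbond_series <- function(traj, selection, criteria = hbond_criteria(),
                         window = 51L) {
  stopifnot(inherits(traj, "trajectory"))
  if (window < 1L || window %% 2L == 0L) {
    stop("hbond_series: window must be a positive odd integer",
         call. = FALSE)
  }
  frames <- lapply(seq_len(n_frames(traj)), function(i) {
    m <- frame_model(traj, i)
    list(bonds = detect_backbone_hbonds(m, selection$seam1,
                                        selection$seam16, criteria),
         contacts = seam_contact_count(m, selection$seam1,
                                       selection$seam16, criteria))
  })
  counts <- vapply(frames, function(f) nrow(f$bonds), integer(1L))
  out <- tibble::tibble(
    time_ns = traj$times,
    count = counts,
    smoothed = moving_average(counts, window),
    n_contacts = vapply(frames, function(f) as.integer(f$contacts),
                        integer(1L)),
    bonds = lapply(frames, function(f) f$bonds))
  structure(out, class = c("hbond_series", class(out)), window = window)
}

#' Classify per-frame seam state from the smoothed bond count
#'
#' Three labels: `closed` when the moving average is at or above
#' `closed_min`; `open` when it is below `open_max` *and* the frame has no
#' seam contact pair within the distance cutoff (a low average alone does
#' not imply an open seam - a persistent single contact is the hallmark of
#' a tenuous closed state); `tenuous` otherwise.
#'
#' @param series An [hbond_series()] result.
#' @param closed_min Smoothed count at or above which the seam is closed.
#' @param open_max Smoothed count below which, contacts permitting, the seam
#'   is open.
#' @return The series with a `state` factor column appended.
#' @export
classify_seam_state <- function(series, closed_min = 2, open_max = 1) {
  if (open_max > closed_min) {
    stop("classify_seam_state: open_max must not exceed closed_min",
         call. = FALSE)
  }
  state <- ifelse(series$smoothed >= closed_min, "closed",
                  ifelse(series$smoothed < open_max & series$n_contacts == 0L,
                         "open", "tenuous"))
  series$state <- factor(state, levels = c("open", "tenuous", "closed"))
  series
}
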