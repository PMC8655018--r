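# Independent oracles used across the suite. Each is a deliberately naive
# re-derivation (enumeration, closed form, alternative algorithm) kept
# separate from the package's own code paths.

# Horn's quaternion method for optimal superposition RMSD: eigendecomposition
# of the 4x4 key matrix. Independent of the SVD-based Kabsch implementation.
quaternion_rmsd <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  M <- crossprod(Q0, P0)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,      -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,      -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lmax <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(P0^2) + sum(Q0^2) - 2 * lmax) / nrow(P)
  sqrt(max(0, msd))
}

# Exhaustive all-pairs backbone H-bond scan under the no-hydrogen criteria:
# every donor N against every acceptor O in both directions, angle at the
# acceptor, then per-donor nearest qualifying acceptor. Plain double loop.
brute_force_hbonds <- function(model, seam1_resno, seam16_resno,
                               dmax = 3.5, amin = 120) {
  grab <- function(resnos, name) {
    rows <- model[model$resno %in% resnos & model$atom == name, ,
                  drop = FALSE]
    rows[order(rows$resno), , drop = FALSE]
  }
  one_way <- function(don_res, acc_res) {
    Nt <- grab(don_res, "N"); Ot <- grab(acc_res, "O"); Ct <- grab(acc_res, "C")
    bonds <- NULL
    for (i in seq_len(nrow(Nt))) {
      best <- NULL
      for (j in seq_len(nrow(Ot))) {
        nv <- c(Nt$x[i], Nt$y[i], Nt$z[i])
        ov <- c(Ot$x[j], Ot$y[j], Ot$z[j])
        cv <- c(Ct$x[j], Ct$y[j], Ct$z[j])
        d <- sqrt(sum((nv - ov)^2))
        if (d > dmax) next
        v1 <- nv - ov; v2 <- cv - ov
        ang <- acos(min(1, max(-1, sum(v1 * v2) /
                                 sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
        if (ang < amin) next
        if (is.null(best) || d < best$d) {
          best <- list(d = d, donor = Nt$resno[i], acceptor = Ot$resno[j])
        }
      }
      if (!is.null(best)) bonds <- rbind(bonds, as.data.frame(best))
    }
    bonds
  }
  rbind(one_way(seam1_resno, seam16_resno),
        one_way(seam16_resno, seam1_resno))
}

# Gift-wrapping (Jarvis march) convex hull area, O(n h); independent of
# grDevices::chull + shoelace inside the package.
gift_wrap_area <- function(x, y) {
  pts <- unique(cbind(x, y))
  n <- nrow(pts)
  if (n < 3) return(0)
  start <- which.min(pts[, 1] + 1e-12 * pts[, 2])
  hull <- start
  repeat {
    p <- hull[length(hull)]
    cand <- setdiff(seq_len(n), p)
    q <- cand[1]
    for (r in cand[-1]) {
      cr <- (pts[q, 1] - pts[p, 1]) * (pts[r, 2] - pts[p, 2]) -
            (pts[q, 2] - pts[p, 2]) * (pts[r, 1] - pts[p, 1])
      if (cr < 0 ||
          (abs(cr) < 1e-12 &&
           sum((pts[r, ] - pts[p, ])^2) > sum((pts[q, ] - pts[p, ])^2))) {
        q <- r
      }
    }
    if (q == start) break
    hull <- c(hull, q)
    if (length(hull) > n) stop("gift wrap failed to close")
  }
  v <- pts[hull, , drop = FALSE]
  xs <- v[, 1]; ys <- v[, 2]
  abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
}

# small hand-built structure: k atoms on given coordinates, one residue each
tiny_model <- function(xyz, atom = "CA", chain = "A",
                       resno = seq_len(nrow(xyz))) {
  structure_model(tibble::tibble(
    serial = seq_len(nrow(xyz)), atom = atom, resid = "ALA",
    chain = chain, resno = resno, ins = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

cross3_test <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

rot_z_test <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}
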