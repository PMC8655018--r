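#' Nanodisc averaging simulation parameters
#'
#' Bundle of parameters for the nanodisc density-averaging experiment: a
#' ring (the membrane-scaffold-protein belt at the nanodisc perimeter) is
#' rasterized, displaced by random in-plane shifts bounded by the free room
#' the particle has inside the disc, and averaged over many copies - the
#' situation of single-particle alignment on the protein while the nanodisc
#' sits anywhere around it. The maximum shift is the nanodisc radius minus
#' the radius of the protein core (estimated 40 A diameter for BAM) minus
#' the alignment mask (10 A).
#'
#' @param disc_diameter Outer nanodisc diameter, angstrom. The three
#'   scaffold belts of interest are about 110 (MSP1D1), 130 (MSP1E3D1) and
#'   170 (MSP2N2).
#' @param ring_width Belt width, angstrom.
#' @param core_diameter Protein core diameter, angstrom.
#' @param mask Alignment mask margin, angstrom.
#' @param n_copies Number of randomly shifted copies averaged.
#' @param grid_size Grid edge, pixels (must hold the disc plus shifts).
#' @param pixel_size Angstrom per pixel.
#' @param shift_distribution `"uniform_disk"` (uniform over lattice offsets
#'   within the max-shift radius) or `"uniform_square"` (independent per
#'   axis in \[-max, +max\]). Shifts are realised on the pixel lattice so
#'   that every copy is an exact displacement of the same rasterized ring
#'   and the average conserves mass exactly.
#' @param seed Integer seed; fixed seed gives a bit-identical map.
#' @return A `ring_spec` list.
#' @export
ring_spec <- function(disc_diameter = 130, ring_width = 10,
                      core_diameter = 40, mask = 10, n_copies = 5000,
                      grid_size = 320, pixel_size = 1,
                      shift_distribution = c("uniform_disk",
                                             "uniform_square"),
                      seed = 1L) {
  shift_distribution <- match.arg(shift_distribution)
  lens <- c(disc_diameter = disc_diameter, ring_width = ring_width,
            core_diameter = core_diameter, mask = mask,
            pixel_size = pixel_size)
  if (any(lens <= 0)) {
    stop("ring_spec: all lengths must be positive (",
         paste(names(lens)[lens <= 0], collapse = ", "), ")", call. = FALSE)
  }
  if (n_copies < 1L) stop("ring_spec: n_copies must be >= 1", call. = FALSE)
  if (grid_size < 2L) stop("ring_spec: grid_size must be >= 2", call. = FALSE)
  spec <- structure(list(disc_diameter = disc_diameter,
                         ring_width = ring_width,
                         core_diameter = core_diameter, mask = mask,
                         n_copies = as.integer(n_copies),
                         grid_size = as.integer(grid_size),
                         pixel_size = pixel_size,
                         shift_distribution = shift_distribution,
                         seed = as.integer(seed)),
                    class = "ring_spec")
  if (disc_diameter / 2 - core_diameter / 2 - mask < 0) {
    stop("ring_spec: disc too small for core + mask (max shift negative)",
         call. = FALSE)
  }
  spec
}

#' Maximum in-plane shift allowed by a ring spec
#'
#' `disc_diameter / 2 - core_diameter / 2 - mask`: the room the nanodisc
#' boundary has to move while the masked protein core stays inside.
#'
#' @param spec A [ring_spec()].
#' @return Shift bound in angstrom.
#' @export
max_shift <- function(spec) {
  stopifnot(inherits(spec, "ring_spec"))
  ms <- spec$disc_diameter / 2 - spec$core_diameter / 2 - spec$mask
  if (ms < 0) stop("max_shift: negative (invalid spec)", call. = FALSE)
  ms
}

# pixel-center coordinate grids; center pixel is index n %/% 2 + 1
grid_axes <- function(spec) {
  n <- spec$grid_size
  (seq_len(n) - (n %/% 2L + 1L)) * spec$pixel_size
}

#' Rasterize the nanodisc boundary ring
#'
#' Annulus of outer diameter `disc_diameter` and radial width `ring_width`,
#' value 1 inside and 0 outside, centered on the grid-center pixel.
#'
#' @param spec A [ring_spec()].
#' @param check_shift_room Also require room for the maximum shift (the
#'   simulation needs it; a bare ring does not).
#' @return A [density_map2d()].
#' @export
rasterize_ring <- function(spec, check_shift_room = TRUE) {
  stopifnot(inherits(spec, "ring_spec"))
  ax <- grid_axes(spec)
  r_out <- spec$disc_diameter / 2
  need <- r_out + if (check_shift_room) max_shift(spec) else 0
  if (-min(ax) < need || max(ax) < need) {
    stop(sprintf(
      "rasterize_ring: grid %d px @ %g A/px too small; need >= %d px",
      spec$grid_size, spec$pixel_size,
      2L * ceiling(need / spec$pixel_size) + 1L), call. = FALSE)
  }
  r2 <- outer(ax^2, ax^2, "+")
  ring <- (r2 <= r_out^2) & (r2 >= (r_out - spec$ring_width)^2)
  density_map2d(ring + 0, pixel_size = spec$pixel_size)
}

# integer lattice offsets (pixels) drawn from the shift distribution
draw_shifts <- function(spec) {
  m <- floor(max_shift(spec) / spec$pixel_size)
  n <- spec$n_copies
  if (m == 0L) return(matrix(0L, nrow = n, ncol = 2L))
  if (spec$shift_distribution == "uniform_square") {
    return(matrix(sample.int(2L * m + 1L, 2L * n, replace = TRUE) - m - 1L,
                  ncol = 2L))
  }
  out <- matrix(0L, nrow = 0L, ncol = 2L)
  r2max <- (max_shift(spec) / spec$pixel_size)^2
  while (nrow(out) < n) {
    cand <- matrix(sample.int(2L * m + 1L, 2L * 2L * n, replace = TRUE) -
                     m - 1L, ncol = 2L)
    cand <- cand[cand[, 1L]^2 + cand[, 2L]^2 <= r2max, , drop = FALSE]
    out <- rbind(out, cand)
  }
  out[seq_len(n), , drop = FALSE]
}

#' Monte-Carlo averaged nanodisc density map
#'
#' Averages `n_copies` displaced copies of the rasterized ring, with
#' displacements drawn from the spec's shift distribution bounded by
#' [max_shift()]. Deterministic for a fixed seed; the mean conserves the
#' single-ring integrated intensity exactly because every copy is a pure
#' displacement on the pixel lattice and the grid is validated to contain
#' the ring at its largest excursion.
#'
#' @param spec A [ring_spec()].
#' @return A [density_map2d()].
#' @export
simulate_average_map <- function(spec) {
  base <- rasterize_ring(spec)$values
  n <- spec$grid_size
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  shifts <- draw_shifts(spec)
  acc <- matrix(0, n, n)
  # accumulate over unique offsets with multiplicity: identical to summing
  # one shifted copy per draw, just fewer matrix operations
  key <- paste(shifts[, 1L], shifts[, 2L])
  for (k in unique(key)) {
    idx <- which(key == k)[1L]
    dx <- shifts[idx, 1L]; dy <- shifts[idx, 2L]
    w <- sum(key == k)
    src_r <- (max(1L, 1L - dx)):(min(n, n - dx))
    src_c <- (max(1L, 1L - dy)):(min(n, n - dy))
    acc[src_r + dx, src_c + dy] <-
      acc[src_r + dx, src_c + dy] + w * base[src_r, src_c]
  }
  density_map2d(acc / spec$n_copies, pixel_size = spec$pixel_size)
}

#' Exact expectation of the averaged nanodisc map
#'
#' The analytic oracle for [simulate_average_map()]: the rasterized ring
#' convolved (discretely, via FFT) with the exact probability mass of the
#' shift distribution on the pixel lattice. For a fixed spec this is the
#' exact expectation of the Monte-Carlo average, so the only discrepancy
#' between the two is Monte-Carlo variance.
#'
#' @param spec A [ring_spec()].
#' @return A [density_map2d()].
#' @export
analytic_expected_map <- function(spec) {
  base <- rasterize_ring(spec)$values
  n <- spec$grid_size
  m <- floor(max_shift(spec) / spec$pixel_size)
  if (m == 0L) return(density_map2d(base, pixel_size = spec$pixel_size))
  off <- seq(-m, m)
  if (spec$shift_distribution == "uniform_square") {
    kern2 <- matrix(1, length(off), length(off))
  } else {
    r2max <- (max_shift(spec) / spec$pixel_size)^2
    kern2 <- outer(off^2, off^2, "+") <= r2max
    kern2 <- kern2 + 0
  }
  kern2 <- kern2 / sum(kern2)
  # place the kernel wrapped around the FFT origin
  kern <- matrix(0, n, n)
  ridx <- ((off) %% n) + 1L
  kern[ridx, ridx] <- kern2
  out <- Re(stats::fft(stats::fft(base) * stats::fft(kern), inverse = TRUE)) /
    n^2
  out[abs(out) < 1e-12] <- 0
  density_map2d(out, pixel_size = spec$pixel_size)
}

#' Normalized distance between two density maps
#'
#' Root-mean-square pixel difference normalized by the intensity range of
#' the reference map (min-max normalized RMSE, the convention of image
#' comparison toolkits). Also available: the Frobenius-ratio relative L2
#' error.
#'
#' @param map,reference [density_map2d()]s on the same grid.
#' @param method `"nrmse"` (min-max normalized RMSE) or `"rel_l2"`.
#' @return Dimensionless error (multiply by 100 for percent).
#' @export
map_distance <- function(map, reference, method = c("nrmse", "rel_l2")) {
  method <- match.arg(method)
  a <- map$values; b <- reference$values
  stopifnot(all(dim(a) == dim(b)))
  d <- sqrt(sum((a - b)^2))
  if (method == "rel_l2") return(d / sqrt(sum(b^2)))
  (d / sqrt(length(b))) / (max(b) - min(b))
}

#' Integrated intensity of a map
#' @param map A [density_map2d()].
#' @return Sum of pixel values times pixel area (angstrom^2).
#' @export
map_mass <- function(map) sum(map$values) * map$pixel_size^2

#' Radial intensity profile of a map
#'
#' Mean intensity per radial bin from the grid-center pixel.
#'
#' @param map A [density_map2d()].
#' @param bin Radial bin width, angstrom.
#' @return Tibble with `r_mid` (bin center, angstrom), `mean_intensity`,
#'   `n_px`.
#' @export
radial_profile <- function(map, bin = 2) {
  if (bin <= 0) stop("radial_profile: bin must be positive", call. = FALSE)
  n <- nrow(map$values)
  ax <- (seq_len(n) - (n %/% 2L + 1L)) * map$pixel_size
  r <- sqrt(outer(ax^2, ax^2, "+"))
  idx <- floor(r / bin)
  agg <- tapply(as.vector(map$values), as.vector(idx), mean)
  cnt <- tapply(rep(1, length(idx)), as.vector(idx), sum)
  ks <- as.integer(names(agg))
  tibble::tibble(r_mid = (ks + 0.5) * bin,
                 mean_intensity = as.numeric(agg),
                 n_px = as.integer(cnt))
}

#' Peak-to-mean ratio of the averaged radial profile
#'
#' Summary of how concentrated the averaged nanodisc density is: the
#' maximum of the radial profile divided by its mean over the support of
#' the averaged ring (radii up to the disc radius plus the maximum shift).
#' Larger nanodiscs smear their boundary over a wider annulus, so the ratio
#' decreases with disc diameter - the "averaged out" behaviour.
#'
#' @param map A [density_map2d()] from [simulate_average_map()] or
#'   [analytic_expected_map()].
#' @param spec The [ring_spec()] that produced it.
#' @param bin Radial bin width, angstrom.
#' @return Dimensionless ratio >= 1.
#' @export
peak_to_mean_ratio <- function(map, spec, bin = 2) {
  prof <- radial_profile(map, bin)
  support <- prof$r_mid <= spec$disc_diameter / 2 + max_shift(spec)
  p <- prof$mean_intensity[support]
  max(p) / mean(p)
}
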