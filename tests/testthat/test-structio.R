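test_that("a hand-written PDB round-trips with exact coordinates", {
  lines <- c(
    "ATOM      1  N   ALA A 425      11.104  13.207   2.300  1.00 20.00           N",
    "ATOM      2  CA  ALA A 425      12.560  13.300   2.400  1.00 20.00           C",
    "ATOM      3  C   ALA A 425      13.104  14.207   3.500  1.00 20.00           C",
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, f)
  m <- read_structure(f)
  expect_s3_class(m, "structure_model")
  expect_equal(nrow(m), 3L)
  expect_equal(m$atom, c("N", "CA", "C"))
  expect_equal(m$x, c(11.104, 12.560, 13.104))
  expect_equal(m$resno, rep(425L, 3L))

  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m, f2)
  m2 <- read_structure(f2)
  expect_equal(coords(m2), coords(m), tolerance = 1e-8)
  expect_equal(m2$atom, m$atom)
  expect_equal(m2$resno, m$resno)
})

test_that("alternate locations resolve to highest occupancy, first on ties", {
  lines <- c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.60 20.00           C",
    "ATOM      2  CA BALA A   1       9.000   0.000   0.000  0.40 20.00           C",
    "ATOM      3  CA AGLY A   2       2.000   0.000   0.000  0.50 20.00           C",
    "ATOM      4  CA BGLY A   2       8.000   0.000   0.000  0.50 20.00           C",
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, f)
  m <- read_structure(f)
  expect_equal(nrow(m), 2L)
  expect_equal(m$x, c(1, 2))   # occ 0.6 beats 0.4; 0.5 tie -> first listed
})

test_that("unreadable and empty inputs raise informative errors", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("REMARK nothing here", "END"), f)
  expect_error(read_structure(f), "empty|parse")
  expect_error(read_structure("no/such/file.pdb"), "no such file")
})

test_that("multi-model PDB trajectories round-trip frame counts and coordinates", {
  spec <- toy_spec(seed = 7, noise_sigma = 0.4, n_barrel_residues = 16,
                   n_accessory_bodies = 1, n_accessory_residues = 8)
  traj <- make_rotation_trajectory(spec, seq(0, 40, length.out = 5))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(traj, f)
  back <- read_trajectory(f)
  expect_equal(n_frames(back), 5L)
  expect_equal(nrow(back$topology), nrow(traj$topology))
  # PDB text carries 3 decimals
  expect_equal(back$xyz, traj$xyz, tolerance = 1e-3)

  one <- withr::local_tempfile(fileext = ".pdb")
  write_structure(frame_model(traj, 1L), one)
  t1 <- read_trajectory(one)
  expect_equal(n_frames(t1), 1L)
  expect_equal(frame_model(t1, 1L)$x, read_structure(one)$x)
})

test_that("trajectory congruence against a mismatched topology errors", {
  spec <- toy_spec(seed = 1, n_barrel_residues = 16,
                   n_accessory_bodies = 1, n_accessory_residues = 8)
  traj <- make_rotation_trajectory(spec, c(0, 10))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(traj, f)
  small <- frame_model(traj, 1L)[1:10, ]
  small <- structure_model(small)
  expect_error(read_trajectory(f, topology = small), "atom count")
})

test_that("time-series CSV writes a header plus one row per frame and round-trips", {
  s <- tibble::tibble(time_ns = c(0, 1, 2), value = c(1.25, 1.25, 1.25))
  f <- withr::local_tempfile(fileext = ".csv")
  write_timeseries(s, f)
  expect_length(readLines(f), 4L)
  back <- read_timeseries(f)
  expect_equal(back$value, s$value)
  expect_equal(back$time_ns, s$time_ns)

  angles <- tibble::tibble(time_ns = seq(0, 9), angle_deg = sin(0:9) * 57.3)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_timeseries(angles, f2)
  expect_equal(read_timeseries(f2)$angle_deg, angles$angle_deg,
               tolerance = 1e-6)
  expect_error(write_timeseries(angles[0, ], f2), "empty")
})

test_that("2D maps round-trip in both text and MRC form", {
  z <- density_map2d(matrix(0, 2, 2), pixel_size = 1.5)
  f <- withr::local_tempfile(fileext = ".map")
  write_map2d(z, f)
  back <- read_map2d(f)
  expect_equal(back$values, z$values)
  expect_equal(back$pixel_size, 1.5)

  spec <- ring_spec(disc_diameter = 60, core_diameter = 40, mask = 10,
                    grid_size = 101, n_copies = 1, seed = 1)
  ring <- rasterize_ring(spec)
  ft <- withr::local_tempfile(fileext = ".map")
  write_map2d(ring, ft, format = "text")
  expect_lt(max(abs(read_map2d(ft)$values - ring$values)), 1e-6)
  fm <- withr::local_tempfile(fileext = ".mrc")
  write_map2d(ring, fm, format = "mrc")
  back_m <- read_map2d(fm, format = "mrc")
  expect_lt(max(abs(back_m$values - ring$values)), 1e-6)
  expect_equal(back_m$pixel_size, ring$pixel_size, tolerance = 1e-6)

  expect_error(density_map2d(matrix(0, 0, 0)), "zero")
  expect_error(density_map2d(matrix(0, 2, 2), pixel_size = -1), "pixel_size")
})
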