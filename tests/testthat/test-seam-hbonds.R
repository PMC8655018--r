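sel <- complex_selection()

test_that("ideal antiparallel strands yield exactly the constructed bond count", {
  for (k in c(0L, 1L, 4L)) {
    traj <- make_seam_trajectory(k, seed = 31)
    bonds <- detect_backbone_hbonds(frame_model(traj, 1),
                                    sel$seam1, sel$seam16)
    expect_equal(nrow(bonds), k)
    if (k > 0) {
      expect_true(all(bonds$distance < 3.5))
      expect_true(all(bonds$angle >= 120))
    }
  }
})

test_that("strands pulled far apart have no bonds at all", {
  traj <- make_seam_trajectory(c(4L, 0L), seed = 32)
  far <- frame_model(traj, 2)
  expect_equal(nrow(detect_backbone_hbonds(far, sel$seam1, sel$seam16)), 0L)
})

test_that("a single engineered contact reports the right residue pair", {
  # one register bond; the generator pairs acceptor 425+1 with donor 808-1
  traj <- make_seam_trajectory(1L, seed = 33)
  bonds <- detect_backbone_hbonds(frame_model(traj, 1),
                                  sel$seam1, sel$seam16)
  expect_equal(nrow(bonds), 1L)
  expect_equal(bonds$donor_resno, 807)
  expect_equal(bonds$acceptor_resno, 425)
  expect_equal(bonds$distance, sqrt(2.9^2 + 1.4^2), tolerance = 1e-6)
})

test_that("detection equals the exhaustive brute-force scan on random fixtures", {
  set.seed(41)
  for (i in 1:100) {
    k <- sample(0:6, 1)
    traj <- make_seam_trajectory(k, n_register = 6L,
                                 noise_sigma = stats::runif(1, 0, 0.4),
                                 seed = 1000L + i)
    m <- frame_model(traj, 1)
    mine <- detect_backbone_hbonds(m, sel$seam1, sel$seam16)
    oracle <- brute_force_hbonds(m, 424:435, 800:810)
    n_oracle <- if (is.null(oracle)) 0L else nrow(oracle)
    expect_equal(nrow(mine), n_oracle)
    if (n_oracle > 0) {
      expect_setequal(paste(mine$donor_resno, mine$acceptor_resno),
                      paste(oracle$donor, oracle$acceptor))
    }
  }
})

test_that("detection is symmetric under swapping the strand selections", {
  traj <- make_seam_trajectory(3L, noise_sigma = 0.2, seed = 51)
  m <- frame_model(traj, 1)
  ab <- detect_backbone_hbonds(m, sel$seam1, sel$seam16)
  ba <- detect_backbone_hbonds(m, sel$seam16, sel$seam1)
  expect_equal(nrow(ab), nrow(ba))
  expect_setequal(paste(ab$donor_resno, ab$acceptor_resno),
                  paste(ba$donor_resno, ba$acceptor_resno))
})

test_that("bond counts are invariant under rigid motion of the frame", {
  traj <- make_seam_trajectory(2L, seed = 61)
  m <- frame_model(traj, 1)
  set.seed(62)
  moved <- set_coords(m, coords(m) %*% t(random_rotation()) + 13)
  a <- detect_backbone_hbonds(m, sel$seam1, sel$seam16)
  b <- detect_backbone_hbonds(moved, sel$seam1, sel$seam16)
  expect_equal(nrow(a), nrow(b))
  expect_equal(sort(a$distance), sort(b$distance), tolerance = 1e-9)
})

test_that("criteria validation and missing-atom errors are informative", {
  expect_error(hbond_criteria(donor_acceptor_max = -1), "positive")
  expect_error(hbond_criteria(angle_min = 200), "angle_min")
  traj <- make_seam_trajectory(2L, seed = 71)
  m <- frame_model(traj, 1)
  expect_error(
    detect_backbone_hbonds(m, sel$seam1, sel$seam16,
                           hbond_criteria(use_explicit_H = TRUE)),
    "missing backbone H")
  no_o <- structure_model(m[m$atom != "O", ])
  expect_error(detect_backbone_hbonds(no_o, sel$seam1, sel$seam16),
               "missing backbone O")
})

test_that("moving averages follow the hand-computed shrinking-window values", {
  expect_equal(moving_average(c(0, 0, 0, 4, 4, 4), 3),
               c(0, 0, 4 / 3, 8 / 3, 4, 4))
  x <- c(2, 5, 1, 7, 0)
  expect_equal(moving_average(x, 1), x)
  expect_equal(moving_average(rep(3, 10), 5), rep(3, 10))
  expect_error(moving_average(x, 2), "odd")
  # bounded by the raw range
  set.seed(81)
  y <- sample(0:4, 50, replace = TRUE)
  sm <- moving_average(y, 7)
  expect_true(all(sm >= min(y) & sm <= max(y)))
})

test_that("hbond series tracks a scripted schedule and smooths it", {
  sched <- c(0L, 1L, 2L, 3L, 4L, 4L, 4L, 0L)
  traj <- make_seam_trajectory(sched, seed = 91)
  series <- hbond_series(traj, sel, window = 1L)
  expect_equal(series$count, sched)
  expect_equal(series$smoothed, as.numeric(sched))
  series3 <- hbond_series(traj, sel, window = 3L)
  expect_equal(series3$smoothed, moving_average(sched, 3))
  expect_error(hbond_series(traj, sel, window = 4L), "odd")
})

test_that("seam states classify as open, tenuous or closed per the rules", {
  # sustained four bonds: closed throughout
  closed <- hbond_series(make_seam_trajectory(rep(4L, 6), seed = 101),
                         sel, window = 3L)
  expect_true(all(classify_seam_state(closed)$state == "closed"))
  # fully separated strands: open
  open_tr <- hbond_series(make_seam_trajectory(rep(0L, 6), seed = 102),
                          sel, window = 3L)
  expect_true(all(classify_seam_state(open_tr)$state == "open"))
  # a persistent single contact with sub-1 average: tenuous, not open
  tenuous <- hbond_series(make_seam_trajectory(c(1L, 1L, 0L, 1L, 0L, 1L),
                                               seed = 103),
                          sel, window = 5L)
  lab <- classify_seam_state(tenuous)
  expect_true(all(lab$state[lab$n_contacts > 0] %in% c("tenuous", "closed")))
  expect_true(any(lab$state == "tenuous"))
  expect_error(classify_seam_state(closed, closed_min = 1, open_max = 2),
               "open_max")
})
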