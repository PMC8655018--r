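test_that("the reference structure measures exactly zero against itself", {
  model <- make_toy_complex(toy_spec(seed = 2))
  sel <- complex_selection()
  ref <- build_reference(model, sel)
  expect_equal(rotation_angle(model, sel, ref), 0, tolerance = 1e-12)
  expect_equal(sqrt(sum(ref$reference_vector^2)), 1, tolerance = 1e-12)
  expect_setequal(ref$accessory_set, c("BamB", "BamC", "BamD", "BamE"))
})

test_that("a single accessory body on +x defines the +x reference vector", {
  spec <- toy_spec(seed = 4, n_accessory_bodies = 1, accessory_angles = 0)
  model <- make_toy_complex(spec)
  sel <- complex_selection(accessory = list(BamB = "B"))
  ref <- build_reference(model, sel)
  # carbonyl offsets tilt the center slightly off the body-placement axis
  expect_gt(ref$reference_vector[1], 0.998)
  expect_lt(abs(ref$reference_vector[2]), 0.05)
})

test_that("missing accessory components are excluded from both sides", {
  spec <- toy_spec(seed = 6, n_accessory_bodies = 2,
                   accessory_angles = c(0, 90))
  full <- make_toy_complex(spec)
  sel <- complex_selection(accessory = list(BamB = "B", BamC = "C"))
  ref_full <- build_reference(full, sel)
  # drop chain C: the survivor's direction defines the vector
  no_c <- structure_model(full[full$chain != "C", ])
  ref_survivor <- build_reference(no_c, sel)
  expect_setequal(ref_survivor$accessory_set, "BamB")
  expect_gt(sum(ref_full$reference_vector * c(1, 1) / sqrt(2)), 0.9)
  expect_gt(ref_survivor$reference_vector[1], 0.998)
  # measuring a reduced model against a full reference intersects the
  # accessory sets, so the two measurements differ by exactly the signed
  # angle between the two reference vectors
  ang <- rotation_angle(no_c, sel, ref_full)
  ang_b_only <- rotation_angle(no_c, sel, ref_survivor)
  v1 <- ref_full$reference_vector; v2 <- ref_survivor$reference_vector
  between <- atan2(v1[1] * v2[2] - v1[2] * v2[1],
                   sum(v1 * v2)) * 180 / pi
  expect_equal(ang - ang_b_only, between, tolerance = 1e-6)
})

test_that("a scripted rigid ring rotation is recovered frame by frame", {
  spec <- toy_spec(seed = 8, noise_sigma = 0)
  sched <- c(0, 30, 60, -45, 170, -170)
  traj <- make_rotation_trajectory(spec, sched)
  series <- rotation_series(traj, complex_selection())
  expect_s3_class(series, "angle_series")
  expect_lt(max(abs(series$angle_deg - sched)), 0.1)
})

test_that("rotation series recovers a noisy 0-to-60-degree schedule within a degree", {
  spec <- toy_spec(seed = 10, noise_sigma = 0.5)
  sched <- seq(0, 60, length.out = 100)
  traj <- make_rotation_trajectory(spec, sched)
  series <- rotation_series(traj, complex_selection())
  rmse <- sqrt(mean((series$angle_deg - sched)^2))
  expect_lte(rmse, 1)
  expect_lt(abs(series$angle_deg[100] - 60), 0.5)
})

test_that("handedness: clockwise motion viewed from extracellular is negative", {
  spec <- toy_spec(seed = 12, noise_sigma = 0.2)
  traj <- make_rotation_trajectory(spec, c(0, -10, -20, -30))
  series <- rotation_series(traj, complex_selection())
  expect_true(all(series$angle_deg[-1] < 0))
  expect_lt(abs(series$angle_deg[4] - (-30)), 0.5)
})

test_that("the metric is invariant when structure and frame rotate together", {
  spec <- toy_spec(seed = 14)
  model <- make_toy_complex(spec)
  sel <- complex_selection()
  ref <- build_reference(model, sel)
  rotated <- make_rotation_trajectory(spec, 25)
  ang <- rotation_angle(frame_model(rotated, 1), sel, ref)
  expect_lt(abs(ang - 25), 1e-6)
  # translate everything: barrel-relative vectors unchanged
  shifted <- set_coords(frame_model(rotated, 1),
                        sweep(coords(frame_model(rotated, 1)), 2,
                              c(-30, 12, 7)))
  expect_equal(rotation_angle(shifted, sel, ref), ang, tolerance = 1e-9)
})

test_that("rotating accessory bodies by phi changes the angle by exactly phi mod 360", {
  spec <- toy_spec(seed = 16)
  sel <- complex_selection()
  base <- make_toy_complex(spec)
  ref <- build_reference(base, sel)
  for (phi in c(10, 95, 181, 359, -250)) {
    traj <- make_rotation_trajectory(spec, phi)
    ang <- rotation_angle(frame_model(traj, 1), sel, ref)
    expected <- ((phi + 180) %% 360) - 180
    expect_lt(abs(ang - expected), 1e-6)
  }
})

test_that("angles wrap to (-180, 180] and unwrapping restores continuity", {
  spec <- toy_spec(seed = 18, noise_sigma = 0)
  sched <- seq(0, 400, length.out = 41)
  traj <- make_rotation_trajectory(spec, sched)
  wrapped <- rotation_series(traj, complex_selection())
  expect_true(all(wrapped$angle_deg > -180 & wrapped$angle_deg <= 180))
  unwrapped <- rotation_series(traj, complex_selection(), unwrap = TRUE)
  expect_lt(max(abs(unwrapped$angle_deg - sched)), 0.1)
})

test_that("static structure pairs superpose the mobile barrel before measuring", {
  pair <- make_state_pair(toy_spec(seed = 20), rotation_deg = 63)
  sel <- complex_selection()
  ref <- build_reference(pair$inward_open, sel)
  expect_equal(rotation_angle(pair$inward_open, sel, ref, superpose = TRUE),
               0, tolerance = 1e-6)
  ang <- rotation_angle(pair$outward_open, sel, ref, superpose = TRUE)
  expect_lt(abs(ang - 63), 5)
  # a displaced copy of the outward model measures identically once superposed
  moved <- set_coords(pair$outward_open,
                      coords(pair$outward_open) %*% t(rot_z_test(40)) + 25)
  expect_lt(abs(rotation_angle(moved, sel, ref, superpose = TRUE) - ang),
            1e-6)
})


test_that("degenerate references are rejected", {
  spec <- toy_spec(seed = 22, n_accessory_bodies = 0)
  model <- make_toy_complex(spec)
  sel <- complex_selection()
  expect_error(build_reference(model, sel), "no accessory")
})
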