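test_that("atom selection honours residue ranges, gaps and atom classes", {
  model <- make_toy_complex(toy_spec(seed = 3, n_barrel_residues = 16))
  sel <- complex_selection()
  barrel_c <- select_atoms(model, sel$barrel)
  expect_true(all(barrel_c$atom == "C"))
  expect_true(all(barrel_c$resno >= 425 & barrel_c$resno <= 810))
  expect_equal(nrow(barrel_c), 16L)

  # missing residues inside the range are skipped, not an error
  gap <- sel_entry("A", 425:810, "carbonyl_C")
  sub <- structure_model(model[!(model$resno %in% 500:510), ])
  expect_silent(select_atoms(sub, gap))

  # CA selection equals a brute-force filter by name
  ca <- select_atoms(model, sel_entry("A", 425:810, "CA"))
  brute <- model[model$chain == "A" & model$atom == "CA" &
                   model$resno %in% 425:810, ]
  expect_equal(ca$x, brute$x)
  expect_error(select_atoms(model, sel_entry("Z", 1:5, "CA")),
               "empty selection")
})

test_that("geometric centers behave like unweighted means with symmetry", {
  one <- tiny_model(matrix(c(1, 2, 3), 1))
  expect_equal(unname(geometric_center(one)), c(1, 2, 3))
  two <- tiny_model(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(unname(geometric_center(two)), c(1, 0, 0))
  th <- seq(0, 2 * pi, length.out = 33)[-33]
  ringm <- tiny_model(cbind(cos(th), sin(th), 0))
  expect_equal(unname(geometric_center(ringm)), c(0, 0, 0),
               tolerance = 1e-9)
  expect_error(geometric_center(one[0, ]), "empty")
})

test_that("membrane frames recover the barrel axis in both modes and stay equivariant", {
  model <- make_toy_complex(toy_spec(seed = 5))
  sel <- complex_selection()
  fz <- membrane_frame(model, sel, "z_axis")
  fp <- membrane_frame(model, sel, "barrel_principal")
  expect_equal(fz$normal, c(0, 0, 1))
  expect_equal(abs(sum(fp$normal * c(0, 0, 1))), 1, tolerance = 1e-4)
  expect_gt(fp$normal[3], 0)   # POTRA side is periplasmic (-z here)
  # orthonormal right-handed triad
  for (f in list(fz, fp)) {
    expect_equal(sum(f$normal * f$in_plane_x), 0, tolerance = 1e-9)
    expect_equal(sum(f$in_plane_x * f$in_plane_y), 0, tolerance = 1e-9)
    expect_equal(cross3_test(f$in_plane_x, f$in_plane_y), f$normal,
                 tolerance = 1e-9)
  }
  # rigid 90-degree rotation about x carries the principal-mode normal along
  Rx <- matrix(c(1, 0, 0, 0, 0, -1, 0, 1, 0), 3, 3, byrow = TRUE)
  rot <- set_coords(model, coords(model) %*% t(Rx))
  fp_rot <- membrane_frame(rot, sel, "barrel_principal")
  expect_equal(fp_rot$normal, as.vector(Rx %*% fp$normal), tolerance = 1e-6)
  # z_axis mode ignores structure orientation by definition
  expect_equal(membrane_frame(rot, sel, "z_axis")$normal, c(0, 0, 1))
})


test_that("Kabsch superposition matches the quaternion oracle and its invariants", {
  set.seed(11)
  # identity and pure translation
  P <- matrix(stats::rnorm(30), ncol = 3)
  fit0 <- kabsch_superpose(P, P)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-9)
  fit_t <- kabsch_superpose(P, sweep(P, 2, c(-5, 0, 0)))
  expect_equal(fit_t$rmsd, 0, tolerance = 1e-9)

  for (rep in 1:100) {
    n <- sample(4:60, 1)
    P <- matrix(stats::rnorm(3 * n, sd = 8), ncol = 3)
    Q <- P %*% t(random_rotation()) +
      matrix(stats::rnorm(3 * n, sd = 0.2), ncol = 3)
    Q <- sweep(Q, 2, stats::runif(3, -10, 10))
    fit <- kabsch_superpose(P, Q)
    expect_equal(fit$rmsd, quaternion_rmsd(P, Q), tolerance = 1e-9)
    # fitted RMSD never exceeds the raw RMSD
    expect_lte(fit$rmsd, sqrt(mean(rowSums((Q - P)^2))) + 1e-12)
    # proper rotation
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
    # apply_fit reproduces the reported RMSD
    expect_equal(sqrt(mean(rowSums((apply_fit(fit, Q) - P)^2))), fit$rmsd,
                 tolerance = 1e-9)
  }
  expect_error(kabsch_superpose(P, P[-1, ]), "counts differ")
  expect_error(kabsch_superpose(P[1:2, ], P[1:2, ]), "at least 3")
})

test_that("noisy rotated clouds fit back to near the noise floor", {
  set.seed(21)
  n <- 500
  sigma <- 0.2
  P <- matrix(stats::rnorm(3 * n, sd = 10), ncol = 3)
  Q <- P %*% t(random_rotation()) + matrix(stats::rnorm(3 * n, sd = sigma),
                                           ncol = 3)
  fit <- kabsch_superpose(P, Q)
  expect_lt(abs(fit$rmsd - sqrt(3) * sigma), 0.05)
})

test_that("model RMSD pairs atoms by residue identity and survives deletions", {
  model <- make_toy_complex(toy_spec(seed = 9))
  expect_equal(rmsd_between_models(model, model)$rmsd, 0, tolerance = 1e-9)
  # deleting one residue from one side only drops it from the pairing
  drop1 <- structure_model(model[model$resno != 500 | model$chain != "A", ])
  fit <- rmsd_between_models(model, drop1)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  # RMSD is invariant under a common rigid motion
  R <- random_rotation()
  ma <- perturb_model(model, 1.0, seed = 2)
  fit_ab <- rmsd_between_models(model, ma)
  rot_a <- set_coords(model, coords(model) %*% t(R) + 5)
  rot_b <- set_coords(ma, coords(ma) %*% t(R) + 5)
  expect_equal(rmsd_between_models(rot_a, rot_b)$rmsd, fit_ab$rmsd,
               tolerance = 1e-9)
  expect_error(
    rmsd_between_models(model, structure_model(model[model$chain == "B", ]),
                        entry = sel_entry("A", 425:810, "CA")),
    "empty selection")
})

test_that("broom-style accessors expose fit summaries", {
  model <- make_toy_complex(toy_spec(seed = 9))
  fit <- rmsd_between_models(model, perturb_model(model, 0.5, seed = 3))
  g <- generics::glance(fit)
  expect_s3_class(g, "tbl_df")
  expect_named(g, c("rmsd", "n_atoms"))
  td <- generics::tidy(fit)
  expect_true(all(c("rmsd", "rotation_angle_deg") %in% td$term))
})

test_that("the toy barrel's longest in-plane diameter matches its construction", {
  spec <- toy_spec(seed = 13, barrel_radius = 25)
  model <- make_toy_complex(spec)
  d <- barrel_inplane_diameter(model, complex_selection())
  expect_lt(abs(d - 50), 1)
})
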