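# Leaflet assignment, COM height, reference vectors, tilt/rotation angles.

test_that("leaflet assignment splits on the phosphorus midplane and freezes", {
  top <- fix_bilayer_topology(hi = 4, lo = 0)
  lf <- assign_leaflets(top, attr(top, "xyz_nm"))
  expect_equal(lf$midplane_z, 2)
  expect_length(lf$upper_lipids, 18)
  expect_length(lf$lower_lipids, 18)
  expect_true(all(attr(top, "xyz_nm")[lf$upper_p_atoms, 3] == 4))

  # cholesterol has no phosphorus: excluded from the assignment
  chl <- fix_topology(c("P", "P", "O3"), c("POPC", "POPC", "CHL1"),
                      c(1, 2, 3),
                      xyz = rbind(c(0, 0, 4), c(0, 0, 0), c(0, 0, 3)))
  lf2 <- assign_leaflets(chl, attr(chl, "xyz_nm"))
  expect_equal(lf2$upper_lipids, 1)
  expect_equal(lf2$lower_lipids, 2)

  flat <- fix_topology(c("P", "P"), c("POPC", "POPC"), c(1, 2),
                       xyz = rbind(c(0, 0, 2), c(1, 1, 2)))
  expect_error(assign_leaflets(flat, attr(flat, "xyz_nm")), "degenerate")
})

test_that("COM height is the amino-acid COM minus the upper phosphate plane", {
  top <- fix_topology(c("CA", "P", "P"), c("GLY", "POPC", "POPC"),
                      c(1, 101, 102),
                      xyz = rbind(c(0, 0, 3.0), c(0, 0, 1.5), c(0, 0, -1.5)))
  lf <- assign_leaflets(top, attr(top, "xyz_nm"))
  expect_equal(com_height(attr(top, "xyz_nm"), 1L, lf, top), 1.5)
  # below the surface: negative, unclamped
  xyz2 <- attr(top, "xyz_nm")
  xyz2[1, 3] <- 1.0
  expect_equal(com_height(xyz2, 1L, lf, top), -0.5)
  expect_error(com_height(attr(top, "xyz_nm"), integer(0), lf, top), "empty")
  # non amino-acid atoms are rejected from the COM group
  expect_error(com_height(attr(top, "xyz_nm"), 2L, lf, top), "amino-acid")
})

test_that("reference vectors follow the head->loopII and loopIII->loopI COMs", {
  tpl <- three_finger_template()
  top <- fix_template_topology(tpl)
  v <- reference_vectors(tpl$xyz, tpl$groups, top)
  expect_equal(unname(v$A), c(0.8, 0, 0), tolerance = 1e-12)
  expect_equal(unname(v$B), c(0, 0.9, 0), tolerance = 1e-12)
  expect_equal(unname(v$F), c(0, 0, 1), tolerance = 1e-12)  # sheet normal
  bad_groups <- tpl$groups
  bad_groups$head <- 999L
  expect_error(reference_vectors(tpl$xyz, bad_groups, top), "head")
})

test_that("tilt angle is 90 minus the A/normal angle with the stated sign", {
  expect_equal(tilt_angle(fix_refvec(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0))), 90)
  expect_equal(tilt_angle(fix_refvec(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))), 0)
  expect_equal(tilt_angle(fix_refvec(c(1, 0, -1) / sqrt(2), c(0, 1, 0),
                                     c(0, 0, 1))), -45)
  # antisymmetry: A -> -A maps alpha -> -alpha
  set.seed(11)
  for (i in 1:50) {
    A <- stats::rnorm(3)
    a1 <- tilt_angle(fix_refvec(A, c(0, 1, 0), c(0, 0, 1)))
    a2 <- tilt_angle(fix_refvec(-A, c(0, 1, 0), c(0, 0, 1)))
    expect_equal(a1, -a2, tolerance = 1e-12)
  }
})

test_that("rotation angle implements the three-branch rule continuously", {
  # branch 1 (F_z >= 0)
  expect_equal(rotation_angle(fix_refvec(c(1, 0, 0), c(0, 0, 1), c(0, 0, 0.5))), 90)
  expect_equal(rotation_angle(fix_refvec(c(1, 0, 0), c(0, 0, -1), c(0, 0, 0.5))), -90)
  # branch 2 boundary (B_z = 0, F_z < 0)
  expect_equal(rotation_angle(fix_refvec(c(0, 0, 1), c(1, 0, 0), c(0, 0, -0.5))), 180)
  # branch 3 just across the boundary: continuous on the circle
  b3 <- rotation_angle(fix_refvec(c(0, 0, 1), c(1, 0, -0.01), c(0, 0, -0.5)))
  expect_equal(b3, -179.427, tolerance = 5e-3)
  expect_lt(circ_diff(b3, 180), 0.6)
  expect_error(rotation_angle(fix_refvec(c(1, 0, 0), c(0, 0, 0), c(0, 0, 1))),
               "zero-length")
})

test_that("the branch rule covers (-180, 180] without gaps off the poles", {
  th <- seq(1, 179, by = 2) * pi / 180
  ph <- seq(0, 358, by = 2) * pi / 180
  vals <- c()
  for (t in th) {
    B <- cbind(sin(t) * cos(ph), sin(t) * sin(ph), cos(t))
    for (fz in c(0.5, -0.5)) {
      vals <- c(vals, apply(B, 1, function(b)
        rotation_angle(fix_refvec(c(1, 0, 0), b, c(0, 0, fz)))))
    }
  }
  expect_true(all(vals > -180 & vals <= 180))
  hist_hit <- table(cut(vals, breaks = seq(-180, 180, by = 5)))
  expect_true(all(hist_hit > 0))
})

test_that("orientation series matches ground truth and is rigid-body invariant", {
  spec <- synthetic_spec(n_frames = 40)
  sim <- generate_trajectory(spec, seed = 17)
  os <- orientation_series(sim$trajectory, sim$groups)
  expect_equal(nrow(os), 40)
  expect_lt(max(abs(os$Z_nm - sim$ground_truth$Z_nm)), 1e-9)
  expect_lt(max(abs(os$alpha_deg - sim$ground_truth$alpha_deg)), 1e-9)
  expect_lt(max(circ_diff(os$beta_deg, sim$ground_truth$beta_deg)), 1e-9)

  # translate everything in xy and rotate everything about z: no output moves
  tr <- sim$trajectory
  thr <- 0.7
  R <- matrix(c(cos(thr), sin(thr), 0, -sin(thr), cos(thr), 0, 0, 0, 1), 3, 3)
  for (k in seq_len(tr$nframes)) {
    tr$coords[, , k] <- tr$coords[, , k] %*% R
    tr$coords[, 1, k] <- tr$coords[, 1, k] + 3.2
    tr$coords[, 2, k] <- tr$coords[, 2, k] - 1.1
  }
  os2 <- orientation_series(tr, sim$groups, unwrap = FALSE)
  expect_lt(max(abs(os2$Z_nm - os$Z_nm)), 1e-9)
  expect_lt(max(abs(os2$alpha_deg - os$alpha_deg)), 1e-9)
  expect_lt(max(circ_diff(os2$beta_deg, os$beta_deg)), 1e-9)

  # single-frame trajectory
  sim1 <- generate_trajectory(synthetic_spec(n_frames = 1), seed = 5)
  expect_equal(nrow(orientation_series(sim1$trajectory, sim1$groups)), 1)
})

test_that("series extremes recover the posed extreme rotations", {
  # poses at the reported extreme rotations (at zero tilt, where they are
  # geometrically admissible)
  tpl <- three_finger_template()
  top <- fix_template_topology(tpl)
  betas <- c(-82.1, 0, 89.6)
  meas <- sapply(betas, function(b) {
    xyz <- pose_protein(tpl, 2, 0, b, phi = 0.3)
    measure_pose(xyz, tpl, top)["beta"]
  })
  expect_equal(min(meas), -82.1, tolerance = 1e-9)
  expect_equal(max(meas), 89.6, tolerance = 1e-9)
})
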