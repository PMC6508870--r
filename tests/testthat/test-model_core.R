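test_that("joint frames are constructed from the intervertebral planes", {
  # parallel horizontal planes: origin at the midpoint, identity orientation
  fr <- compute_joint_frame(list(centre = c(0, 0, 0), normal = c(0, 1, 0)),
                            list(centre = c(0, 0.002, 0), normal = c(0, 1, 0)))
  expect_equal(fr$origin, c(0, 0.001, 0))
  expect_equal(fr$orientation, diag(3))

  # caudal plane tilted 10 degrees about z rotates the frame by 10 degrees
  th <- 10 * pi / 180
  n <- as.numeric(neckdyn:::rot_z(th) %*% c(0, 1, 0))
  fr <- compute_joint_frame(list(centre = c(0, 0, 0), normal = n),
                            list(centre = c(0, 0, 0), normal = n))
  expect_equal(fr$orientation, neckdyn:::rot_z(th), tolerance = 1e-12)
  expect_equal(fr$origin, c(0, 0, 0))
  expect_equal(acos(sum(fr$orientation[, 2] * c(0, 1, 0))), th,
               tolerance = 1e-12)

  # degenerate inputs
  expect_error(compute_joint_frame(list(centre = c(0, 0, 0),
                                        normal = c(0, 0, 0)),
                                   list(centre = c(0, 0, 0),
                                        normal = c(0, 1, 0))),
               "degenerate")
  expect_error(compute_joint_frame(list(centre = c(0, 0, 0),
                                        normal = c(1, 0, 0)),
                                   list(centre = c(0, 0, 0),
                                        normal = c(1, 0, 0))),
               "parallel")
})

test_that("specimen models have orthonormal frames and the stated layout", {
  geom <- specimen_geometry()
  m <- build_specimen_model(geom, mass_kg = 0.390)
  # equal mass split of 0.390 kg gives 0.078 kg per vertebra
  expect_equal(unname(vapply(m$segments, `[[`, numeric(1), "mass")),
               rep(0.078, 5))
  # orthonormal right-handed joint triads
  for (J in m$joints) {
    G <- J$orientation
    expect_lt(max(abs(t(G) %*% G - diag(3))), 1e-12)
    expect_equal(det(G), 1, tolerance = 1e-12)
  }
  # the joint y-axis makes the configured lordosis angle with vertical
  th <- geom$tilts[["C5C6"]]
  expect_equal(acos(sum(m$joints$C5C6$orientation[, 2] * c(0, 1, 0))), th,
               tolerance = 1e-12)
  # identity geometry: all joint frames axis-aligned
  m0 <- build_specimen_model(specimen_geometry(tilts_deg = rep(0, 4)))
  for (J in m0$joints) expect_equal(J$orientation, diag(3), tolerance = 1e-15)
  # constraint set of the experimental rig
  expect_equal(m$constraints[["C6"]], "fixed")
  expect_equal(m$constraints[["C2"]], "axial_translation_only")
  # invalid inputs
  expect_error(build_specimen_model(geom, mass_kg = -1), "positive")
  expect_error(build_specimen_model(geom, mass_split = rep(0.3, 5)),
               "summing to 1")
})

test_that("marker forward kinematics applies rigid-body poses", {
  m <- build_specimen_model(specimen_geometry())
  nfree <- neckdyn:::n_free_coordinates(m)
  rest <- forward_kinematics_markers(m, list(q = numeric(nfree)))
  expect_length(rest, 15)

  # translating C4 by (0, -1 mm, 0) shifts exactly the C4 cluster
  q <- numeric(nfree)
  # q layout: C2 ty, then 6 per body for C3, C4, C5
  q[1 + 6 + 2] <- -1e-3        # C4 ty
  shifted <- forward_kinematics_markers(m, list(q = q))
  for (mk in names(rest)) {
    delta <- shifted[[mk]] - rest[[mk]]
    if (grepl("^C4", mk)) {
      expect_equal(delta, c(0, -1e-3, 0), tolerance = 1e-15)
    } else {
      expect_equal(delta, c(0, 0, 0), tolerance = 1e-15)
    }
  }

  # rotating C3 90 degrees about its z maps offsets (a,b,c) -> (-b,a,c);
  # q layout is C2 ty, then (tx ty tz rx ry rz) per free body, so C3 rz = 7
  q <- numeric(nfree)
  q[7] <- pi / 2
  rot <- forward_kinematics_markers(m, list(q = q))
  com <- m$segments$C3$com
  for (mk in grep("^C3", names(rest), value = TRUE)) {
    off <- rest[[mk]] - com
    expect_equal(rot[[mk]] - com, c(-off[2], off[1], off[3]),
                 tolerance = 1e-12)
  }

  # rigid-body invariant: inter-marker distances preserved under any state
  set.seed(4)
  q <- c(rnorm(1, 0, 1e-3), rnorm(nfree - 1, 0, 5e-3))
  expect_rigid_markers(m, list(q = q), tol = 1e-12)

  expect_error(forward_kinematics_markers(m, list(q = numeric(nfree - 1))),
               "free DoF")
})

test_that("pack/unpack is a bijection on the 16 optimised entries", {
  m <- build_specimen_model(specimen_geometry())
  p <- pack_parameters(m$bushings)
  expect_length(p, 16)
  expect_equal(unname(p[1:4]), rep(1.1e6, 4))   # axial stiffness block
  round_trip <- pack_parameters(unpack_parameters(p, m$bushings))
  expect_identical(unname(round_trip), unname(p))

  # arbitrary vector installs exactly and leaves the fixed DoF alone
  p2 <- p * seq(1.1, 2.6, by = 0.1)
  b2 <- unpack_parameters(p2, m$bushings)
  expect_equal(unname(pack_parameters(b2)), unname(p2))
  for (j in seq_len(4)) {
    expect_identical(b2[[j]]$k_rot, m$bushings[[j]]$k_rot)
    expect_identical(b2[[j]]$b_rot, m$bushings[[j]]$b_rot)
    expect_identical(b2[[j]]$k_trans[3], m$bushings[[j]]$k_trans[3])
  }

  expect_error(unpack_parameters(p[1:15], m$bushings), "length 16")
  expect_error(unpack_parameters(-p, m$bushings), "non-negative")
  sets <- parameter_sets(p2)
  expect_named(sets, c("k_y", "b_y", "k_x", "b_x"))
  expect_equal(unname(sets$k_x), unname(p2[9:12]))
})
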