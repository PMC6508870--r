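test_that("bushing wrench follows the Kelvin-Voigt law", {
  bp <- bushing_parameters(c(63e3, 25.2e6, 63e3), c(1e3, 6.1e3, 1e3),
                           rep(50, 3), rep(1, 3))
  # zero deflection, zero rate -> zero wrench
  w0 <- bushing_wrench(bp, rep(0, 6), rep(0, 6))
  expect_equal(w0$force, rep(0, 3))
  expect_equal(w0$torque, rep(0, 3))

  # 1 mm axial compression against the identified median stiffness restores
  # with +25 200 N
  w <- bushing_wrench(bp, c(0, -1e-3, 0, 0, 0, 0), rep(0, 6))
  expect_equal(w$force[2], 25200)
  expect_equal(w$reaction_force[2], -25200)

  # pure axial rate against the median damping: F = -b * ddot
  w <- bushing_wrench(bp, rep(0, 6), c(0, -0.5, 0, 0, 0, 0))
  expect_equal(w$force[2], 3050)
  expect_error(bushing_wrench(bp, c(NA, rep(0, 5)), rep(0, 6)), "non-finite")
})

test_that("state derivative reduces to Newton's law for a single mass", {
  m <- single_dof_model(mass = 2, k = 1e4, b = 50, gravity = -9.81,
                        spring_force = 30)
  # displaced and moving: a = (-k d - b v - m g - F_spring - F_ext) / m
  d <- -2e-3
  v <- -0.1
  f_ext <- 100
  der <- state_derivative(m, list(q = d, u = v), external_load = f_ext)
  a_hand <- (-1e4 * d - 50 * v - 2 * 9.81 - 30 - f_ext) / 2
  expect_equal(der$udot, a_hand, tolerance = 1e-12)
  expect_equal(der$qdot, v)

  # equilibrium deflection, zero load -> zero acceleration
  d_eq <- -(2 * 9.81 + 30) / 1e4
  der <- state_derivative(m, list(q = d_eq, u = 0))
  expect_equal(der$udot, 0, tolerance = 1e-10)

  # doubling the mass halves the acceleration at fixed (non-gravity) force
  m1 <- single_dof_model(mass = 1, k = 1e4, b = 0, gravity = 0)
  m2 <- single_dof_model(mass = 2, k = 1e4, b = 0, gravity = 0)
  a1 <- state_derivative(m1, list(q = 1e-3, u = 0), external_load = 5)$udot
  a2 <- state_derivative(m2, list(q = 1e-3, u = 0), external_load = 5)$udot
  expect_equal(a1, 2 * a2, tolerance = 1e-12)
})

test_that("the integrator matches the closed-form damped oscillator", {
  # undamped: x(t) = x0 cos(omega t); at t = pi/omega the sign flips
  m <- single_dof_model(mass = 1, k = 1e4, b = 0, gravity = 0)
  t_half <- pi / 100
  sim <- simulate_specimen(m, zero_load(t_half + 1e-4), window_s = t_half,
                           q0 = 1e-3)
  x_end <- sim$Q[nrow(sim$Q), 1]
  expect_lt(abs(x_end - (-1e-3)), 1e-9)

  # full closed form over the window, sampled trajectory
  x_ref <- 1e-3 * cos(100 * sim$times)
  expect_lt(max(abs(sim$Q[, 1] - x_ref)), 1e-6 * 1e-3)

  # critically damped release never crosses zero
  mc <- single_dof_model(mass = 1, k = 1e4, b = 200, gravity = 0)
  simc <- simulate_specimen(mc, zero_load(0.06), window_s = 0.05, q0 = 1e-3)
  expect_gt(min(simc$Q[, 1]), 0)
  t <- simc$times
  x_ref <- 1e-3 * (1 + 100 * t) * exp(-100 * t)
  expect_lt(max(abs(simc$Q[, 1] - x_ref)), 1e-6 * 1e-3)
})

test_that("a preloaded chain at equilibrium stays put", {
  sp <- fx_specimen()
  m <- neckdyn:::set_model_parameters(sp$model, sp$truth)
  sim <- simulate_specimen(m, zero_load(0.006), window_s = 0.005)
  drift <- apply(abs(sim$markers$data - rep(sim$markers$data[1, , ],
                                            each = dim(sim$markers$data)[1])),
                 3, max)
  expect_lt(max(drift), 1e-6)
})

test_that("joint series have the documented reference conventions", {
  sp <- fx_specimen()
  m <- neckdyn:::set_model_parameters(sp$model, sp$truth)
  sim <- simulate_specimen(m, fx_trial()$force_window, window_s = 0.005)
  # displacement channels are zero at the preloaded equilibrium
  for (jn in names(m$joints)) {
    for (ch in c("axial_displacement", "shear_displacement")) {
      ser <- extract_joint_series(sim, jn, ch)
      expect_equal(ser$value[1], 0)
      expect_equal(nrow(ser), length(sim$times))
    }
  }
  # at t = 0 the axial bushing force at C2C3 carries the preload share:
  # 102 N spring + (C2 + plate) weight
  f0 <- extract_joint_series(sim, "C2C3", "axial_force")$value[1]
  share <- 102 + (m$segments$C2$mass + m$preload$plate_mass_kg) * 9.81
  expect_equal(f0, share, tolerance = 1e-3)
  expect_error(extract_joint_series(sim, "C9C10", "axial_force"), "unknown")

  # a static load settles at the static deflection -F/k (slowest pole of
  # the overdamped pair decays at ~113/s, so 0.1 s suffices)
  m1 <- single_dof_model(mass = 0.1, k = 1e4, b = 100, gravity = 0)
  tr <- force_trace(rep(10, 100001), fs = 1e6)
  sim1 <- simulate_specimen(m1, tr, window_s = 0.1)
  d_end <- extract_joint_series(sim1, "J", "axial_displacement")$value
  expect_lt(abs(d_end[length(d_end)] - (-10 / 1e4)), 1e-7)
})

test_that("mechanical energy decays under passive motion", {
  sp <- fx_specimen()
  m <- neckdyn:::set_model_parameters(sp$model, sp$truth)
  cm <- neckdyn:::as_chain_model(m)
  eq <- neckdyn:::solve_equilibrium(cm, 19)
  q0 <- eq$q
  q0[1] <- q0[1] - 5e-4        # axial perturbation of C2
  sim <- simulate_specimen(m, zero_load(0.006), window_s = 0.005, q0 = q0)
  E <- mechanical_energy(sim)
  expect_true(all(diff(E) <= 1e-9 * max(abs(E))))
  expect_lt(E[length(E)], E[1])
})

test_that("halving the step leaves marker endpoints unchanged to 1e-8 m", {
  sp <- fx_specimen()
  m <- neckdyn:::set_model_parameters(sp$model, sp$truth)
  fw <- fx_trial()$force_window
  cm <- neckdyn:::as_chain_model(m)
  eq <- neckdyn:::solve_equilibrium(cm, 19)
  s1 <- simulate_specimen(m, fw, window_s = 0.005, h = 1e-6, q0 = eq$q)
  s2 <- simulate_specimen(m, fw, window_s = 0.005, h = 5e-7,
                          record_every = 20L, q0 = eq$q)
  end1 <- s1$markers$data[dim(s1$markers$data)[1], , ]
  end2 <- s2$markers$data[dim(s2$markers$data)[1], , ]
  expect_lt(max(abs(end1 - end2)), 1e-8)
})

test_that("simulation rejects loads shorter than the window", {
  m <- single_dof_model()
  expect_error(simulate_specimen(m, zero_load(0.001), window_s = 0.005),
               "shorter")
})
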