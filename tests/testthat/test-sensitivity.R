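test_that("set perturbation scales exactly the targeted parameters", {
  p <- setNames(as.numeric(1:16), rownames(default_parameter_bounds()))
  expect_equal(perturb_sets(p, c(0, 0, 0, 0)), p)

  # the 50% lower bound halves every entry
  expect_equal(unname(perturb_sets(p, rep(-0.5, 4))), unname(p) / 2)

  # set isolation: only the four axial stiffnesses move
  p2 <- perturb_sets(p, c(0.5, 0, 0, 0))
  expect_equal(unname(p2[1:4]), unname(p[1:4]) * 1.5)
  expect_equal(unname(p2[5:16]), unname(p[5:16]))

  expect_error(perturb_sets(p, c(0.6, 0, 0, 0)), "-0.5")
  expect_error(perturb_sets(p, c(0, 0, 0)), "per parameter set")
})

test_that("Monte Carlo perturbation draws are reproducible and centred", {
  d1 <- neckdyn:::mc_draws(1000, seed = 11)
  d2 <- neckdyn:::mc_draws(1000, seed = 11)
  expect_identical(d1, d2)
  expect_true(all(d1 >= -0.5 & d1 <= 0.5))
  # uniform(-0.5, 0.5): column means concentrate near 0 (SE ~ 0.009)
  expect_true(all(abs(colMeans(d1)) < 0.05))
})

test_that("perturbation RMSE is anchored at the optimum", {
  sp <- fx_specimen()
  data <- fx_data()
  mc <- run_monte_carlo(sp$model, data, sp$truth, n = 12, seed = 3)
  expect_equal(nrow(mc), 12)
  expect_lt(attr(mc, "rmse_opt_mm"), 1e-3)
  # Delta-RMSE = RMSE_per - RMSE_opt by construction, non-negative at truth
  expect_equal(mc$delta_rmse_mm, mc$rmse_per_mm - attr(mc, "rmse_opt_mm"))
  expect_true(all(mc$delta_rmse_mm >= 0))
  # identical with the same seed
  mc2 <- run_monte_carlo(sp$model, data, sp$truth, n = 12, seed = 3)
  expect_identical(mc$rmse_per_mm, mc2$rmse_per_mm)
  expect_error(run_monte_carlo(sp$model, data, sp$truth, n = 0), "positive")

  # r = 0 gives Delta-RMSE = 0 exactly
  p0 <- perturb_sets(sp$truth, c(0, 0, 0, 0))
  expect_identical(p0, sp$truth)
  expect_equal(evaluate_with_fixed_parameters(sp$model, data, p0) -
                 attr(mc, "rmse_opt_mm"), 0)
})

test_that("individual-set sweeps bracket the optimum", {
  sp <- fx_specimen()
  data <- fx_data()
  sw <- sweep_parameter_set(sp$model, data, sp$truth, "k_y",
                            scales = c(0.5, 1, 1.5))
  expect_equal(nrow(sw), 3)
  expect_lt(sw$rmse_mm[2], 1e-3)           # scale 1 recovers RMSE_opt
  expect_true(all(sw$rmse_mm[-2] > sw$rmse_mm[2]))
  sw11 <- sweep_parameter_set(sp$model, data, sp$truth, "b_x")
  expect_equal(nrow(sw11), 11)
  expect_equal(range(sw11$scale), c(0.5, 1.5))
  expect_error(sweep_parameter_set(sp$model, data, sp$truth, "k_q"),
               "unknown parameter set")
})

test_that("cubic response surfaces are recovered exactly from cubic data", {
  # craft samples from a known cubic in (r_ky, r_bx), no noise
  set.seed(2)
  n <- 60
  samples <- data.frame(r_ky = runif(n, -0.5, 0.5), r_by = runif(n, -0.5, 0.5),
                        r_kx = runif(n, -0.5, 0.5), r_bx = runif(n, -0.5, 0.5))
  beta <- c(0.2, -1, 0.5, 2, -3, 1.5, 4, -2, 0.7, 1.1)
  X <- neckdyn:::cubic_basis(samples$r_ky, samples$r_bx)
  samples$delta_rmse_mm <- as.numeric(X %*% beta)
  samples$rmse_per_mm <- samples$delta_rmse_mm

  sf <- fit_pair_surface(samples, c("k_y", "b_x"))
  expect_lt(max(abs(sf$coefficients - beta)), 1e-8)
  expect_lt(sf$residual_norm, 1e-8)
  expect_equal(predict(sf, 0, 0), beta[1], tolerance = 1e-8)

  # constant response collapses to an intercept-only fit
  samples$delta_rmse_mm <- 0.42
  sf0 <- fit_pair_surface(samples, c("k_y", "b_x"))
  expect_equal(unname(sf0$coefficients[1]), 0.42, tolerance = 1e-10)
  expect_lt(max(abs(sf0$coefficients[-1])), 1e-9)

  # all six set pairs, exactly C(4,2)
  all6 <- fit_all_pair_surfaces(samples)
  expect_length(all6, 6)
  expect_setequal(names(all6), c("k_y:b_y", "k_y:k_x", "k_y:b_x",
                                 "b_y:k_x", "b_y:b_x", "k_x:b_x"))

  expect_error(fit_pair_surface(samples[1:9, ], c("k_y", "b_x")),
               "at least 10")
  expect_error(fit_pair_surface(samples, c("k_y", "zz")), "parameter sets")
})

test_that("anteroposterior joint-frame shifts degrade tracking", {
  sp <- fx_specimen()
  data <- fx_data()
  sw <- sweep_joint_frame_positions(sp$model, data, sp$truth,
                                    d_x = c(-0.02, 0, 0.02))
  expect_equal(nrow(sw), 3)
  expect_lt(sw$rmse_mm[2], 1e-3)
  expect_true(all(sw$rmse_mm[-2] >= sw$rmse_mm[2]))
  sw9 <- sweep_joint_frame_positions(sp$model, data, sp$truth,
                                     d_x = seq(-0.02, 0.02,
                                               length.out = 9)[c(1, 5, 9)])
  expect_equal(range(sw9$d_x_m), c(-0.02, 0.02))
  expect_error(sweep_joint_frame_positions(sp$model, data, sp$truth,
                                           d_x = 0.03),
               "0.02")
})
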