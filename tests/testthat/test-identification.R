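mk_traj <- function(frames, names, fill = 0) {
  arr <- array(fill, c(frames, 3, length(names)),
               dimnames = list(NULL, NULL, names))
  marker_trajectories(arr, fs = 4000)
}

test_that("tracking RMSE pools squared marker distances over frames", {
  a <- mk_traj(4, c("A", "B"))
  expect_equal(tracking_rmse(a, a), 0)

  # constant 1 mm offset on every marker in every frame -> exactly 1 mm
  b <- a
  b$data[, 1, ] <- b$data[, 1, ] + 1e-3
  expect_equal(tracking_rmse(a, b), 1)

  # 2 markers x 2 frames with distances {0, 0, 3, 4} mm -> 2.5 mm
  m1 <- mk_traj(2, c("A", "B"))
  m2 <- mk_traj(2, c("A", "B"))
  m2$data[2, 1, "A"] <- 3e-3
  m2$data[2, 2, "B"] <- 4e-3
  expect_equal(tracking_rmse(m1, m2), sqrt((9 + 16) / 4))

  # marker order must not matter
  m3 <- m2
  m3$data <- m3$data[, , c("B", "A")]
  expect_equal(tracking_rmse(m1, m3), tracking_rmse(m1, m2))

  expect_error(tracking_rmse(m1, mk_traj(2, c("A", "C"))), "marker sets")
  expect_error(tracking_rmse(m1, mk_traj(3, c("A", "B"))), "frame counts")
})

test_that("the objective is exact at the generating parameters", {
  sp <- fx_specimen()
  tr <- fx_trial()
  o_truth <- evaluate_objective(sp$truth, sp$model, tr$force_window,
                                tr$markers_clean)
  expect_lt(o_truth, 1e-3)

  # halving every axial stiffness degrades tracking
  p_half <- sp$truth
  p_half[1:4] <- p_half[1:4] / 2
  o_half <- evaluate_objective(p_half, sp$model, tr$force_window,
                               tr$markers_clean)
  expect_gt(o_half, o_truth)

  # objective is invariant to marker ordering in the measurement
  shuffled <- tr$markers_clean
  ord <- rev(dimnames(shuffled$data)[[3]])
  shuffled$data <- shuffled$data[, , ord]
  expect_equal(evaluate_objective(sp$truth, sp$model, tr$force_window,
                                  shuffled),
               o_truth)

  # a degenerate (all-zero stiffness) candidate is penalised, not raised
  p_bad <- sp$truth
  p_bad[1:16] <- 0
  o_bad <- evaluate_objective(p_bad, sp$model, tr$force_window,
                              tr$markers_clean)
  expect_true(is.finite(o_bad))
})

test_that("the GA is deterministic, monotone, and never worse than the
           initialisation", {
  sp <- fx_specimen()
  tr <- fx_trial()
  ctrl <- ga_control(pop_size = 8, generations = 3, seed = 5)
  f1 <- fit_bushings(sp$model, tr$markers_clean, tr$force_window, ctrl)
  f2 <- fit_bushings(sp$model, tr$markers_clean, tr$force_window, ctrl)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$history, f2$history)

  # best-fitness history is monotone non-increasing
  expect_true(all(diff(f1$history) <= 0))

  # the literature-initialised individual is in generation 0, so the optimum
  # is never worse than the initialisation values
  o_init <- evaluate_objective(pack_parameters(sp$model$bushings), sp$model,
                               tr$force_window, tr$markers_clean)
  expect_lte(f1$rmse_opt, o_init)

  # the returned optimum respects the bounds
  b <- ctrl$bounds
  expect_true(all(coef(f1) >= b[, 1] & coef(f1) <= b[, 2]))
  expect_equal(f1$n_eval, 8 + 3 * (8 - ctrl$elite))

  # result object methods
  expect_s3_class(f1, "bushing_fit")
  expect_length(coef(f1), 16)
  r <- residuals(f1)
  expect_equal(dim(r), c(21, 15))
  expect_equal(sqrt(mean(r^2)), f1$rmse_opt, tolerance = 1e-9)
  s <- summary(f1)
  expect_equal(nrow(s$table), 16)
  expect_output(print(f1), "tracking RMSE")
})

test_that("bounds that exclude the truth pin the fit to a bound", {
  sp <- fx_specimen()
  tr <- fx_trial()
  # axial stiffness capped two decades below every drawn truth value
  b <- default_parameter_bounds()
  b[1:4, 2] <- 1e5 * 1.0001
  b[1:4, 1] <- 1e4
  ctrl <- ga_control(pop_size = 8, generations = 3, seed = 5, bounds = b)
  f_ex <- fit_bushings(sp$model, tr$markers_clean, tr$force_window, ctrl)
  ctrl0 <- ga_control(pop_size = 8, generations = 3, seed = 5)
  f_in <- fit_bushings(sp$model, tr$markers_clean, tr$force_window, ctrl0)
  expect_gt(f_ex$rmse_opt, f_in$rmse_opt)
  expect_error(ga_control(pop_size = 2), "at least 4")
  expect_error(fit_bushings(sp$model,
                            mk_traj(1, dimnames(tr$markers_clean$data)[[3]]),
                            tr$force_window, ctrl0),
               "degenerate")
})
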