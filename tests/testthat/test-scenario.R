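test_that("variant models install the documented parameter sources", {
  # impact-specific: aggregated C3-C4/C4-C5 medians at every joint
  bp <- impact_specific_bushing()
  expect_equal(bp$k_trans[2], median(c(26.3e6, 19.9e6)))
  expect_equal(bp$b_trans[2], median(c(6.1e3, 2.4e3)))
  expect_equal(bp$k_trans[1], median(c(76.4e3, 75.5e3)))
  expect_equal(bp$b_trans[1], median(c(1.4e3, 1.4e3)))

  m_is <- build_variant_model("impact_specific")
  for (b in m_is$bushings) expect_equal(b$k_trans[2], bp$k_trans[2])

  # quasi-static: literature axial stiffness 1.1e6 N/m at every joint
  m_qs <- build_variant_model("quasi_static")
  for (b in m_qs$bushings) expect_equal(b$k_trans[2], 1.1e6)

  # constrained: no translational joint DoF at all
  m_c <- build_variant_model("constrained")
  expect_s3_class(m_c, "constrained_variant")
})

test_that("scenario comparison reproduces the stiffness ordering", {
  sc <- memo("scenario", run_scenario_comparison())
  expect_s3_class(sc, "scenario_result")
  expect_equal(sc$failure_displacement_mm, 0.84)

  pk <- lapply(sc$variants, `[[`, "peaks")
  # constrained variant: displacements identically zero
  expect_true(all(pk$constrained$peak_axial_disp_mm == 0))
  expect_true(all(pk$constrained$peak_shear_disp_mm == 0))
  # rigid transmission: peak load = applied peak + weight above the joint
  expect_equal(pk$constrained$peak_compressive_N[1],
               max(sc$head_load$force) + 4.5 * 9.81)

  # quasi-static axial displacements exceed impact-specific at every joint
  expect_true(all(pk$quasi_static$peak_axial_disp_mm >
                    pk$impact_specific$peak_axial_disp_mm))
  # impact-specific joints stay near-rigid under the 2 kN pulse
  expect_true(all(pk$impact_specific$peak_axial_disp_mm < 0.15))
  expect_true(all(pk$quasi_static$peak_compressive_N >= 0))
})

test_that("the base reaction balances the applied impulse and momentum", {
  sc <- memo("scenario", run_scenario_comparison())
  for (v in c("impact_specific", "quasi_static")) {
    sim <- sc$variants[[v]]$simulation
    tms <- sim$times
    # impulse transmitted into the base through the C6Base bushing
    base_f <- sim$joints$C6Base[, "F_y"]
    react <- sum(diff(tms) * (head(base_f, -1) + tail(base_f, -1)) / 2)
    # applied load impulse over the window
    tf <- (seq_along(sc$head_load$force) - 1) / sc$head_load$fs
    keep <- tf <= sc$window_s + 1e-12
    fl <- sc$head_load$force[keep]
    applied <- sum(diff(tf[keep]) * (head(fl, -1) + tail(fl, -1)) / 2)
    # weight impulse of the suspended bodies
    cm <- neckdyn:::as_chain_model(sim$model, preload_on = FALSE)
    m_total <- sum(cm$mass[-length(cm$mass)])      # all but the fixed base
    weight <- m_total * 9.81 * sc$window_s
    # net downward momentum at the window end
    mom <- 0
    qidx <- cumsum(cm$free_mask)
    dim(qidx) <- dim(cm$free_mask)
    for (b in seq_along(cm$mass)) {
      if (cm$free_mask[2, b] == 1L) {
        mom <- mom - cm$mass[b] * sim$U[nrow(sim$U), qidx[2, b]]
      }
    }
    # base reaction impulse = applied + weight - final momentum deficit
    expect_lt(abs(react - (applied + weight - mom)),
              0.01 * (applied + weight))
  }
})

test_that("scenario rejects loads not covering the window", {
  short <- generate_load_pulse(peak_N = 2000, rise_s = 0.002,
                               duration_s = 0.005, baseline_N = 0)
  expect_error(run_scenario_comparison(variants = "quasi_static",
                                       head_load = short,
                                       window_s = 0.02),
               "cover")
})
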