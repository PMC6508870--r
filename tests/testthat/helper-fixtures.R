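# Shared fixtures, built once per test run and memoised. Everything is
# generated in code from fixed seeds; no data files.

.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fx)) assign(key, force(expr), envir = .fx)
  get(key, envir = .fx)
}

# The reference synthetic specimen and its noise-free trial.
fx_specimen <- function() memo("specimen", generate_specimen(42))

fx_trial <- function() {
  memo("trial", generate_trial(fx_specimen(), generate_load_pulse(),
                               marker_noise_sd_m = 0))
}

fx_data <- function() {
  tr <- fx_trial()
  list(force = tr$force_window, markers = tr$markers_clean)
}

# A single-DoF mass-on-bushing column: one body free in axial translation
# above a fixed base, coupled by one bushing. Closed-form reference system.
single_dof_model <- function(mass = 1, k = 1e4, b = 0, gravity = 0,
                             spring_force = 0) {
  segs <- list(
    B = list(name = "B", mass = mass, inertia = diag(3) * 1e-4,
             com = c(0, 0.1, 0),
             markers = list(B_M1 = c(0.02, 0, 0))),
    G = list(name = "G", mass = 1, inertia = diag(3) * 1e-3,
             com = c(0, 0, 0), markers = list())
  )
  joints <- list(J = list(name = "J", caudal = "G", cranial = "B",
                          origin = c(0, 0.05, 0), orientation = diag(3)))
  bush <- list(J = bushing_parameters(c(k, k, k), c(b, b, b),
                                      rep(10, 3), rep(0.1, 3)))
  structure(list(
    segments = segs, joints = joints, bushings = bush,
    constraints = c(B = "axial_translation_only", G = "fixed"),
    gravity = c(0, gravity, 0),
    preload = list(spring_force_N = spring_force, plate_weight_N = 0,
                   plate_mass_kg = 0),
    load = list(body = "B", dir = c(0, -1, 0))
  ), class = "specimen_model")
}

zero_load <- function(duration_s, fs = 1e6) {
  force_trace(rep(0, round(duration_s * fs) + 1), fs = fs)
}

expect_rigid_markers <- function(model, state, tol = 1e-12) {
  pos <- forward_kinematics_markers(model, state)
  tab <- neckdyn:::marker_table(model)
  for (seg in unique(tab$segment)) {
    mk <- tab$marker[tab$segment == seg]
    if (length(mk) < 2) next
    ref <- forward_kinematics_markers(model, list(q = numeric(length(state$q))))
    for (i in seq_along(mk)[-1]) {
      d0 <- sqrt(sum((ref[[mk[1]]] - ref[[mk[i]]])^2))
      d1 <- sqrt(sum((pos[[mk[1]]] - pos[[mk[i]]])^2))
      expect_lt(abs(d1 - d0), tol)
    }
  }
}
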