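# Forward dynamics: static preloaded equilibrium, RK4 time integration of the
# bushing chain, and extraction of marker and joint time series.

#' Wrench exerted by a Kelvin-Voigt bushing
#'
#' For each of the six DoF the bushing applies F_i = -k_i d_i - b_i ddot_i in
#' the caudal joint frame on the cranial body; the caudal body receives the
#' equal-and-opposite reaction at the joint origin.
#'
#' @param params a [bushing_parameters()] object.
#' @param d 6-vector of deflections (m, rad) in the joint frame.
#' @param d_rate 6-vector of deflection rates (m/s, rad/s).
#' @return list with `force` (N) and `torque` (Nm) on the cranial body, and
#'   `reaction_force`, `reaction_torque` on the caudal body.
#' @export
bushing_wrench <- function(params, d, d_rate) {
  stopifnot_finite(c(d, d_rate), "bushing deflection")
  k <- c(params$k_trans, params$k_rot)
  b <- c(params$b_trans, params$b_rot)
  w <- -(k * d + b * d_rate)
  list(force = w[1:3], torque = w[4:6],
       reaction_force = -w[1:3], reaction_torque = -w[4:6])
}

#' Generalized accelerations of the constrained chain
#'
#' Newton-Euler equations for every free body under gravity, the constant
#' preload forces, the bushing wrenches and an external load applied at the
#' load body's COM.
#'
#' @param model a `specimen_model`.
#' @param state list with `q` and `u` (free coordinates and velocities).
#' @param external_load scalar load magnitude, N, applied along the model's
#'   load direction (compressive positive, applied along -y by default).
#' @return list with `qdot` and `udot`.
#' @export
state_derivative <- function(model, state, external_load = 0) {
  cm <- as_chain_model(model)
  u <- state$u %||% numeric(length(state$q))
  udot <- chain_derivative_cpp(cm, state$q, u, external_load)
  list(qdot = u, udot = as.numeric(udot))
}

# DoF-wise generalized mass (translations: body mass; rotations: body-frame
# diagonal inertia — rest orientations are identity and equilibrium rotations
# are small, so the world inertia is diagonal to O(theta^2)).
dof_mass <- function(chain_model) {
  unlist(lapply(seq_along(chain_model$mass), function(b) {
    m6 <- c(rep(chain_model$mass[b], 3), diag(chain_model$inertia[, , b]))
    m6[chain_model$free_mask[, b] == 1L]
  }))
}

# Total potential energy of a configuration (elastic + gravitational + the
# potential of the constant preload forces), used by the equilibrium solve.
chain_potential <- function(chain_model, q) {
  poses <- body_poses_cpp(chain_model, q)
  pe <- 0
  for (b in seq_along(chain_model$mass)) {
    pe <- pe - chain_model$mass[b] *
      sum(chain_model$gravity * poses$pos[, b]) -
      sum(chain_model$const_force[, b] * poses$pos[, b])
  }
  js <- joint_states_cpp(chain_model, q, numeric(length(q)))$joint
  for (j in seq_len(nrow(js))) {
    pe <- pe + 0.5 * sum(chain_model$joints[[j]]$k * js[j, 1:6]^2)
  }
  pe
}

# Static preloaded equilibrium: find q with zero generalized accelerations at
# zero velocity. The preload puts the chain close to its rotational buckling
# load, so a plain Newton iteration from the build pose has a very small
# attraction basin; instead the total potential energy is minimised (L-BFGS
# with the generalized forces as gradient) and the result polished with a few
# damped Newton steps on the acceleration residual.
solve_equilibrium <- function(chain_model, n_free, tol = 1e-6,
                              max_iter = 30, q0 = NULL) {
  u <- numeric(n_free)
  md <- dof_mass(chain_model)
  residual <- function(q) as.numeric(chain_derivative_cpp(chain_model, q, u, 0))

  q <- q0 %||% numeric(n_free)
  opt <- stats::optim(q, fn = function(q) chain_potential(chain_model, q),
                      gr = function(q) -md * residual(q),
                      method = "L-BFGS-B",
                      control = list(maxit = 500, factr = 10))
  q <- opt$par
  r <- residual(q)

  for (iter in seq_len(max_iter)) {
    if (max(abs(r)) < tol) break
    J <- matrix(0, n_free, n_free)
    for (k in seq_len(n_free)) {
      eps <- 1e-9 * max(1, abs(q[k]))
      qk <- q
      qk[k] <- qk[k] + eps
      J[, k] <- (residual(qk) - r) / eps
    }
    step <- tryCatch(solve(J, -r), error = function(e) {
      qr.solve(J, -r, tol = 1e-14)
    })
    lambda <- 1
    q_new <- q + step
    r_new <- residual(q_new)
    while (max(abs(r_new)) > 0.9 * max(abs(r)) && lambda > 1e-4) {
      lambda <- lambda / 2
      q_new <- q + lambda * step
      r_new <- residual(q_new)
    }
    if (max(abs(r_new)) >= max(abs(r))) break
    q <- q_new
    r <- r_new
  }
  if (max(abs(r)) > 1e-2) {
    stop("equilibrium solve failed to converge")
  }
  list(q = q, residual = r, iter = NA_integer_)
}

#' Simulate the preloaded chain under an applied load
#'
#' Initialises the model at its preloaded static equilibrium (damped Newton
#' solve on the joint deflections), integrates the equations of motion with
#' fixed-step classical RK4, and returns marker trajectories resampled at the
#' marker rate together with per-joint deflection, rate and wrench series.
#'
#' @param model a `specimen_model`.
#' @param load a [force_trace()] holding the net external load over the
#'   window (compressive positive; the preload path is internal to the model
#'   and must not be included here). A plain numeric vector is accepted and
#'   interpreted at `load_fs`.
#' @param window_s simulation window, s (default 0.005).
#' @param h integrator step, s (default 1e-6).
#' @param record_every record state every this many steps (default 10).
#' @param marker_fs marker output rate, Hz (default 4000).
#' @param marker_times optional explicit marker sample times (s, relative to
#'   window start); overrides `marker_fs`.
#' @param load_fs sampling rate when `load` is a bare vector.
#' @param q0 optional initial coordinates (skips the equilibrium solve).
#' @return an object of class `simulation_result`.
#' @export
simulate_specimen <- function(model, load, window_s = 0.005, h = 1e-6,
                              record_every = 10L, marker_fs = 4000,
                              marker_times = NULL, load_fs = 1e6,
                              q0 = NULL) {
  if (inherits(load, "force_trace")) {
    force <- load$force
    load_fs <- load$fs
  } else {
    force <- as.numeric(load)
  }
  n_steps <- round(window_s / h)
  if (length(force) < 2 && n_steps > 0 && length(force) != 1) {
    stop("load is shorter than the simulation window")
  }
  if ((length(force) - 1) / load_fs < window_s - 1e-12 && length(force) > 1) {
    stop("load is shorter than the simulation window")
  }
  cm <- as_chain_model(model)
  nfree <- n_free_coordinates(model)
  if (is.null(q0)) {
    eq <- solve_equilibrium(cm, nfree)
    q0 <- eq$q
  }
  res <- chain_simulate_cpp(cm, q0, numeric(nfree), force, load_fs,
                            h, n_steps, as.integer(record_every))
  if (res$diverged) {
    out <- structure(list(diverged = TRUE, times = res$times, model = model),
                     class = "simulation_result")
    return(out)
  }
  times <- as.numeric(res$times)

  # marker forward kinematics at recorded states, then linear interpolation
  # onto the marker clock
  mt <- if (is.null(marker_times)) {
    seq(0, window_s + 1e-12, by = 1 / marker_fs)
  } else {
    marker_times
  }
  mt <- mt[mt <= window_s + 1e-9]
  tab <- marker_table(model)
  if (is.null(tab) || nrow(tab) == 0) {
    joints <- lapply(res$joints, function(J) {
      colnames(J) <- joint_series_cols()
      J
    })
    names(joints) <- names(model$joints)
    return(structure(list(times = times, Q = res$Q, U = res$U,
                          markers = NULL, joints = joints,
                          q_equilibrium = q0, h = h, window_s = window_s,
                          diverged = FALSE, model = model),
                     class = "simulation_result"))
  }
  seg_index <- match(tab$segment, names(model$segments))
  # Interpolate the generalized coordinates onto the marker clock, then do
  # rigid-body forward kinematics at the marker frames: segments stay exactly
  # rigid in the output (interpolating marker positions would not).
  Qm <- vapply(seq_len(ncol(res$Q)), function(k) {
    approx(times, res$Q[, k], xout = mt, rule = 2)$y
  }, numeric(length(mt)))
  if (length(mt) == 1L) Qm <- matrix(Qm, nrow = 1)
  marks <- array(NA_real_, c(length(mt), 3, nrow(tab)),
                 dimnames = list(NULL, c("x", "y", "z"), tab$marker))
  for (r in seq_along(mt)) {
    poses <- body_poses_cpp(cm, as.numeric(Qm[r, ]))
    for (m in seq_len(nrow(tab))) {
      i <- seg_index[m]
      loc <- model$segments[[i]]$markers[[tab$marker[m]]]
      marks[r, , m] <- poses$pos[, i] + poses$R[, , i] %*% loc
    }
  }

  joints <- lapply(res$joints, function(J) {
    colnames(J) <- joint_series_cols()
    J
  })
  names(joints) <- names(model$joints)

  structure(list(
    times = times,
    Q = res$Q, U = res$U,
    markers = marker_trajectories(marks, fs = if (is.null(marker_times))
      marker_fs else NA_real_, times = mt),
    joints = joints,
    q_equilibrium = q0,
    h = h, window_s = window_s,
    diverged = FALSE,
    model = model
  ), class = "simulation_result")
}

joint_series_cols <- function() {
  c(paste0("d_", c("x", "y", "z", "rx", "ry", "rz")),
    paste0("ddot_", c("x", "y", "z", "rx", "ry", "rz")),
    paste0("F_", c("x", "y", "z")),
    paste0("T_", c("x", "y", "z")))
}

#' @export
print.simulation_result <- function(x, ...) {
  if (isTRUE(x$diverged)) {
    cat("Chain simulation: DIVERGED (non-finite state)\n")
    return(invisible(x))
  }
  cat(sprintf("Chain simulation: %.1f ms window, %d recorded states, %d marker frames\n",
              1000 * x$window_s, length(x$times), dim(x$markers$data)[1]))
  invisible(x)
}

#' Extract a scalar joint time series from a simulation
#'
#' Displacement channels are reported relative to the preloaded equilibrium
#' configuration; force channels are the raw bushing force on the cranial
#' body in the joint frame (so at equilibrium the axial force equals that
#' joint's preload share).
#'
#' @param result a `simulation_result`.
#' @param joint joint name, e.g. `"C4C5"`.
#' @param channel one of `"axial_force"`, `"shear_force"`,
#'   `"axial_displacement"`, `"shear_displacement"`.
#' @return data.frame with `time` (s) and `value` (N or m).
#' @export
extract_joint_series <- function(result, joint,
                                 channel = c("axial_force", "shear_force",
                                             "axial_displacement",
                                             "shear_displacement")) {
  channel <- match.arg(channel)
  if (!joint %in% names(result$joints)) {
    stop(sprintf("unknown joint '%s'", joint))
  }
  J <- result$joints[[joint]]
  v <- switch(channel,
              axial_force = J[, "F_y"],
              shear_force = J[, "F_x"],
              axial_displacement = J[, "d_y"] - J[1, "d_y"],
              shear_displacement = J[, "d_x"] - J[1, "d_x"])
  data.frame(time = result$times, value = as.numeric(v))
}

#' Total mechanical energy along a simulated trajectory
#'
#' Kinetic plus elastic (bushing) plus gravitational potential energy,
#' including the potential of the constant preload forces. With zero external
#' load and non-negative damping this is non-increasing up to integrator
#' tolerance.
#'
#' @param result a `simulation_result`.
#' @return numeric vector, J, one value per recorded state.
#' @export
mechanical_energy <- function(result) {
  model <- result$model
  cm <- as_chain_model(model)
  nrec <- length(result$times)
  E <- numeric(nrec)
  qidx <- cumsum(cm$free_mask)          # map columns of Q to body DoF
  dim(qidx) <- dim(cm$free_mask)
  for (r in seq_len(nrec)) {
    q <- as.numeric(result$Q[r, ])
    u <- as.numeric(result$U[r, ])
    poses <- body_poses_cpp(cm, q)
    ke <- 0
    pe <- 0
    for (b in seq_along(cm$mass)) {
      vel <- numeric(3)
      omg <- numeric(3)
      for (d in 1:3) {
        if (cm$free_mask[d, b] == 1L) vel[d] <- u[qidx[d, b]]
        if (cm$free_mask[d + 3, b] == 1L) omg[d] <- u[qidx[d + 3, b]]
      }
      R <- poses$R[, , b]
      Iw <- R %*% cm$inertia[, , b] %*% t(R)
      ke <- ke + 0.5 * cm$mass[b] * sum(vel^2) +
        0.5 * sum(omg * (Iw %*% omg))
      pe <- pe - cm$mass[b] * sum(cm$gravity * poses$pos[, b]) -
        sum(cm$const_force[, b] * poses$pos[, b])
    }
    js <- joint_states_cpp(cm, q, u)$joint
    for (j in seq_len(nrow(js))) {
      kj <- cm$joints[[j]]$k
      pe <- pe + 0.5 * sum(kj * js[j, 1:6]^2)
    }
    E[r] <- ke + pe
  }
  E
}
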