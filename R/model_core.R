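# Model core: segments, joint frames, bushing parameterisation, constraints
# and the marker forward kinematics of the C2-C6 specimen chain.
#
# Coordinate convention: right-handed, x anterior, y superior, z = x cross y.
# Bushing deflections are expressed in the caudal joint frame.

#' Kelvin-Voigt bushing parameters for one joint
#'
#' A 6-DoF viscoelastic bushing couples two vertebrae with a linear spring and
#' damper in parallel on every degree of freedom. Translational components are
#' ordered (x anterior shear, y axial, z lateral); rotational components are
#' about the same axes.
#'
#' @param k_trans translational stiffness, N/m (length-3).
#' @param b_trans translational damping, Ns/m (length-3).
#' @param k_rot rotational stiffness, Nm/rad (length-3).
#' @param b_rot rotational damping, Nms/rad (length-3).
#' @return an object of class `bushing_parameters`.
#' @export
bushing_parameters <- function(k_trans, b_trans, k_rot, b_rot) {
  p <- list(k_trans = as.numeric(k_trans), b_trans = as.numeric(b_trans),
            k_rot = as.numeric(k_rot), b_rot = as.numeric(b_rot))
  if (any(lengths(p) != 3L)) stop("all bushing components must have length 3")
  v <- unlist(p)
  stopifnot_finite(v, "bushing parameters")
  if (any(v < 0)) stop("bushing parameters must be non-negative")
  structure(p, class = "bushing_parameters")
}

#' Literature initialisation values for the bushing elements
#'
#' Axial stiffness 1.1e6 N/m and shear stiffness 63e3 N/m with 1e3 Ns/m
#' damping on every translational DoF are the quasi-static automotive-model
#' values used to initialise the identification. The lateral translation
#' mirrors the shear DoF; rotational DoF (50 Nm/rad, 1 Nms/rad) are fixed
#' placeholders that the optimiser never touches, chosen large enough that
#' equilibrium rotations under the 152 N preload stay within the small-angle
#' regime of the bushing parameterisation.
#'
#' @param k_rot_Nm_rad,b_rot_Nms_rad rotational stiffness/damping overrides.
#' @return a `bushing_parameters` object.
#' @export
default_bushing_init <- function(k_rot_Nm_rad = 50, b_rot_Nms_rad = 1) {
  bushing_parameters(
    k_trans = c(63e3, 1.1e6, 63e3),
    b_trans = c(1e3, 1e3, 1e3),
    k_rot = rep(k_rot_Nm_rad, 3),
    b_rot = rep(b_rot_Nms_rad, 3)
  )
}

#' Construct a joint frame from the two intervertebral plane fits
#'
#' The joint frame sits at the centre of the intervertebral mid-plane: its
#' origin is the midpoint of the caudal superior and cranial inferior plane
#' centres, its y-axis is the caudal plane normal, its x-axis the anterior
#' reference projected into the caudal plane, and z completes the right-handed
#' triad.
#'
#' @param caudal_plane list with `centre` and `normal` (3-vectors).
#' @param cranial_plane list with `centre` and `normal`.
#' @param anterior anterior reference direction, default global +x.
#' @return list with `origin` (3-vector) and `orientation` (3x3 matrix whose
#'   columns are the joint x, y, z axes).
#' @export
compute_joint_frame <- function(caudal_plane, cranial_plane,
                                anterior = c(1, 0, 0)) {
  if (sqrt(sum(caudal_plane$normal^2)) == 0 ||
      sqrt(sum(cranial_plane$normal^2)) == 0) {
    stop("degenerate mid-plane: zero normal")
  }
  y <- unit(caudal_plane$normal)
  x_raw <- anterior - sum(anterior * y) * y
  if (sqrt(sum(x_raw^2)) < 1e-12) {
    stop("anterior reference is parallel to the plane normal; x-axis undefined")
  }
  x <- unit(x_raw)
  z <- c(x[2] * y[3] - x[3] * y[2],
         x[3] * y[1] - x[1] * y[3],
         x[1] * y[2] - x[2] * y[1])
  list(origin = (caudal_plane$centre + cranial_plane$centre) / 2,
       orientation = cbind(x, y, z, deparse.level = 0))
}

cylinder_inertia <- function(mass, radius, height) {
  ix <- mass * (3 * radius^2 + height^2) / 12
  iy <- mass * radius^2 / 2
  diag(c(ix, iy, ix))
}

#' Build a specimen model from geometry and inertial data
#'
#' Assembles the C2-C6 rigid-body chain: five vertebral segments, four joint
#' frames at the intervertebral mid-plane centres, per-joint Kelvin-Voigt
#' bushings, and the experimental constraint set (C6 fixed, C2 axial
#' translation only, C3-C5 free). The impact plate is modelled as added mass
#' on C2 and the constant-force springs as a constant compressive force, so
#' that the default preload path totals 152 N.
#'
#' @param geometry a [specimen_geometry()] object.
#' @param mass_kg total specimen mass, kg.
#' @param mass_split five weights summing to 1 distributing the mass over
#'   C2..C6; equal by default.
#' @param bushing_init a single `bushing_parameters` object or a list of four
#'   (per joint, cranial to caudal).
#' @param plate_mass_kg impact plate mass rigidly coupled to C2's axial DoF.
#' @param spring_force_N constant-force spring preload applied to C2.
#' @param gravity gravity vector, m/s^2.
#' @param inertia_radius,inertia_height solid-cylinder segment inertia
#'   approximation parameters, m.
#' @return an object of class `specimen_model`.
#' @export
build_specimen_model <- function(geometry,
                                 mass_kg = 0.390,
                                 mass_split = rep(1 / 5, 5),
                                 bushing_init = default_bushing_init(),
                                 plate_mass_kg = 5.10,
                                 spring_force_N = 102,
                                 gravity = c(0, -9.81, 0),
                                 inertia_radius = 0.015,
                                 inertia_height = 0.020) {
  if (!inherits(geometry, "specimen_geometry")) {
    stop("geometry must be a specimen_geometry object")
  }
  if (!is.finite(mass_kg) || mass_kg <= 0) stop("mass_kg must be positive")
  if (length(mass_split) != 5L || abs(sum(mass_split) - 1) > 1e-8) {
    stop("mass_split must be five weights summing to 1")
  }
  if (inherits(bushing_init, "bushing_parameters")) {
    bushing_init <- setNames(rep(list(bushing_init), 4), JOINT_NAMES)
  }
  if (length(bushing_init) != 4L) stop("need bushing parameters for 4 joints")
  names(bushing_init) <- JOINT_NAMES

  bh <- geometry$body_heights     # named C2..C6
  dh <- geometry$disc_heights     # named C2C3..C5C6
  tilts <- geometry$tilts         # rad, named C2C3..C5C6

  # Stack vertebral centres on the global vertical (caudal C6 at the base) so
  # the preload line of action passes through every joint origin; lordosis is
  # carried by wedge-shaped discs, i.e. tilted mid-planes.
  y_centre <- numeric(5)
  names(y_centre) <- SEGMENT_NAMES
  y_centre["C6"] <- bh["C6"] / 2
  y_joint <- numeric(4)
  names(y_joint) <- JOINT_NAMES
  for (j in 4:1) {                # C5C6 first going up
    jn <- JOINT_NAMES[j]
    caudal <- SEGMENT_NAMES[j + 1]
    cranial <- SEGMENT_NAMES[j]
    y_joint[jn] <- y_centre[caudal] + bh[caudal] / 2 + dh[jn] / 2
    y_centre[cranial] <- y_joint[jn] + dh[jn] / 2 + bh[cranial] / 2
  }

  masses <- setNames(mass_kg * mass_split, SEGMENT_NAMES)
  segments <- lapply(SEGMENT_NAMES, function(s) {
    list(name = s, mass = masses[[s]],
         inertia = cylinder_inertia(masses[[s]], inertia_radius,
                                    inertia_height),
         com = c(0, y_centre[[s]], 0),
         markers = geometry$markers[[s]] %||% list())
  })
  names(segments) <- SEGMENT_NAMES

  joints <- lapply(JOINT_NAMES, function(jn) {
    i <- match(jn, JOINT_NAMES)
    caudal <- SEGMENT_NAMES[i + 1]
    cranial <- SEGMENT_NAMES[i]
    normal <- rot_z(tilts[[jn]]) %*% c(0, 1, 0)
    fr <- compute_joint_frame(
      caudal_plane = list(centre = c(0, y_joint[[jn]], 0),
                          normal = as.numeric(normal)),
      cranial_plane = list(centre = c(0, y_joint[[jn]], 0),
                           normal = as.numeric(normal))
    )
    list(name = jn, caudal = caudal, cranial = cranial,
         origin = fr$origin, orientation = fr$orientation)
  })
  names(joints) <- JOINT_NAMES

  constraints <- c(C2 = "axial_translation_only", C3 = "free", C4 = "free",
                   C5 = "free", C6 = "fixed")

  model <- structure(list(
    segments = segments,
    joints = joints,
    bushings = bushing_init,
    constraints = constraints,
    gravity = gravity,
    preload = list(spring_force_N = spring_force_N,
                   plate_weight_N = 50,
                   plate_mass_kg = plate_mass_kg),
    geometry = geometry,
    load = list(body = "C2", dir = c(0, -1, 0))
  ), class = "specimen_model")
  model
}

#' @export
print.specimen_model <- function(x, ...) {
  nm <- sum(vapply(x$segments, function(s) length(s$markers), integer(1)))
  cat("Cervical spine specimen model\n")
  cat(sprintf("  segments: %s (total mass %.3f kg)\n",
              paste(names(x$segments), collapse = " "),
              sum(vapply(x$segments, `[[`, numeric(1), "mass"))))
  cat(sprintf("  joints:   %s (6-DoF Kelvin-Voigt bushings)\n",
              paste(names(x$joints), collapse = " ")))
  cat(sprintf("  markers:  %d\n", nm))
  cat(sprintf("  constraints: %s\n",
              paste(sprintf("%s=%s", names(x$constraints), x$constraints),
                    collapse = ", ")))
  pre <- x$preload
  cat(sprintf("  preload:  %.0f N springs + %.0f N plate = %.0f N\n",
              pre$spring_force_N, pre$plate_weight_N,
              pre$spring_force_N + pre$plate_weight_N))
  invisible(x)
}

free_mask_for <- function(constraint) {
  switch(constraint,
         fixed = rep(FALSE, 6),
         axial_translation_only = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
         free = rep(TRUE, 6),
         stop(sprintf("unknown constraint '%s'", constraint)))
}

# Lower the specimen model into the flat list consumed by the compiled core.
# `frame_shift_x` translates every joint origin along its own x-axis
# (anteroposterior joint-frame-position perturbation).
as_chain_model <- function(model, frame_shift_x = 0, preload_on = TRUE) {
  segs <- model$segments
  n <- length(segs)
  mass <- vapply(segs, `[[`, numeric(1), "mass")
  plate <- model$preload$plate_mass_kg %||% 0
  loaded <- model$load$body
  if (preload_on && loaded %in% names(segs)) {
    mass[[loaded]] <- mass[[loaded]] + plate
  }
  if (any(mass <= 0)) stop("singular mass matrix: non-positive segment mass")
  inertia <- array(0, c(3, 3, n))
  rest_pos <- matrix(0, 3, n)
  rest_rot <- array(0, c(3, 3, n))
  const_force <- matrix(0, 3, n)
  free_mask <- matrix(0L, 6, n)
  for (i in seq_len(n)) {
    inertia[, , i] <- segs[[i]]$inertia
    rest_pos[, i] <- segs[[i]]$com
    rest_rot[, , i] <- diag(3)
    free_mask[, i] <- as.integer(free_mask_for(model$constraints[[segs[[i]]$name]]))
  }
  if (preload_on && loaded %in% names(segs)) {
    const_force[, match(loaded, names(segs))] <-
      c(0, -model$preload$spring_force_N, 0)
  }
  joints <- lapply(names(model$joints), function(jn) {
    J <- model$joints[[jn]]
    bp <- model$bushings[[jn]]
    ica <- match(J$caudal, names(segs))
    icr <- match(J$cranial, names(segs))
    origin <- J$origin + J$orientation %*% c(frame_shift_x, 0, 0)
    # Rest orientations are identity, so body-frame quantities coincide with
    # world-frame quantities at build time.
    list(caudal = ica, cranial = icr,
         o1 = as.numeric(origin - segs[[ica]]$com),
         o2 = as.numeric(origin - segs[[icr]]$com),
         A1 = J$orientation, A2 = J$orientation,
         k = c(bp$k_trans, bp$k_rot),
         b = c(bp$b_trans, bp$b_rot))
  })
  list(mass = unname(mass), inertia = inertia, rest_pos = rest_pos,
       rest_rot = rest_rot, free_mask = free_mask,
       const_force = const_force, gravity = model$gravity,
       load_body = match(model$load$body, names(segs)),
       load_dir = model$load$dir, joints = joints)
}

n_free_coordinates <- function(model) {
  sum(vapply(model$segments, function(s) {
    sum(free_mask_for(model$constraints[[s$name]]))
  }, numeric(1)))
}

#' Marker positions for a given chain state
#'
#' Applies each segment's rigid-body pose to its locally attached markers.
#' The state's generalized coordinates are deviations from the build pose
#' (world translations of the COM plus an X-Y-Z Euler triplet per free body,
#' constrained DoF omitted).
#'
#' @param model a `specimen_model`.
#' @param state list with `q` (free generalized coordinates).
#' @return named list of marker world positions (3-vectors, m).
#' @export
forward_kinematics_markers <- function(model, state) {
  q <- state$q
  nfree <- n_free_coordinates(model)
  if (length(q) != nfree) {
    stop(sprintf("state has %d coordinates but model has %d free DoF",
                 length(q), nfree))
  }
  poses <- body_poses_cpp(as_chain_model(model), q)
  out <- list()
  for (i in seq_along(model$segments)) {
    seg <- model$segments[[i]]
    for (mn in names(seg$markers)) {
      out[[mn]] <- as.numeric(poses$pos[, i] +
                                poses$R[, , i] %*% seg$markers[[mn]])
    }
  }
  out
}

marker_table <- function(model) {
  rows <- list()
  for (seg in model$segments) {
    for (mn in names(seg$markers)) {
      rows[[mn]] <- data.frame(marker = mn, segment = seg$name,
                               stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Pack per-joint bushing parameters into the optimised 16-vector
#'
#' The identification optimises 16 parameters in the fixed order: axial
#' stiffness k_y over the four joints (C2C3..C5C6), then axial damping b_y,
#' shear stiffness k_x and shear damping b_x. The remaining four DoF per
#' bushing are never part of the vector.
#'
#' @param bushings named list of four `bushing_parameters` (C2C3..C5C6).
#' @return named numeric vector of length 16.
#' @export
pack_parameters <- function(bushings) {
  if (length(bushings) != 4L) stop("need bushing parameters for 4 joints")
  k_y <- vapply(bushings, function(b) b$k_trans[2], numeric(1))
  b_y <- vapply(bushings, function(b) b$b_trans[2], numeric(1))
  k_x <- vapply(bushings, function(b) b$k_trans[1], numeric(1))
  b_x <- vapply(bushings, function(b) b$b_trans[1], numeric(1))
  p <- c(k_y, b_y, k_x, b_x)
  names(p) <- paste(rep(PARAM_SETS, each = 4), rep(JOINT_NAMES, 4), sep = ".")
  p
}

#' Install a 16-parameter vector into a bushing template
#'
#' Inverse of [pack_parameters()]: writes the four axial/shear translational
#' entries of each joint and leaves every other DoF at the template's values.
#'
#' @param p numeric vector of length 16 (see [pack_parameters()] for order).
#' @param template named list of four `bushing_parameters` supplying the
#'   non-optimised DoF.
#' @return named list of four `bushing_parameters`.
#' @export
unpack_parameters <- function(p, template) {
  if (length(p) != 16L) stop("parameter vector must have length 16")
  stopifnot_finite(p, "parameter vector")
  if (any(p < 0)) stop("parameter vector entries must be non-negative")
  if (length(template) != 4L) stop("template must cover 4 joints")
  out <- template
  for (j in seq_len(4)) {
    b <- out[[j]]
    b$k_trans[2] <- p[j]
    b$b_trans[2] <- p[4 + j]
    b$k_trans[1] <- p[8 + j]
    b$b_trans[1] <- p[12 + j]
    out[[j]] <- bushing_parameters(b$k_trans, b$b_trans, b$k_rot, b$b_rot)
  }
  names(out) <- JOINT_NAMES
  out
}

set_model_parameters <- function(model, p) {
  model$bushings <- unpack_parameters(p, model$bushings)
  model
}

#' Group a 16-vector into its four functional parameter sets
#'
#' @param p parameter vector of length 16.
#' @return named list of four 4-vectors (`k_y`, `b_y`, `k_x`, `b_x`), each
#'   ordered C2C3..C5C6.
#' @export
parameter_sets <- function(p) {
  if (length(p) != 16L) stop("parameter vector must have length 16")
  out <- lapply(seq_len(4), function(s) {
    setNames(as.numeric(p[(s - 1) * 4 + 1:4]), JOINT_NAMES)
  })
  names(out) <- PARAM_SETS
  out
}

param_set_indices <- function(set) {
  s <- match(set, PARAM_SETS)
  if (is.na(s)) stop(sprintf("unknown parameter set '%s'", set))
  (s - 1) * 4 + 1:4
}
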