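# Sensitivity analyses around the identified optimum: individual parameter-set
# sweeps, simultaneous Monte Carlo perturbation of the four functional sets,
# cubic response surfaces over set pairs, and anteroposterior joint-frame
# position sweeps.

#' Perturb the four functional parameter sets
#'
#' Scales each member of set s (axial stiffness k_y, axial damping b_y,
#' shear stiffness k_x, shear damping b_x) by (1 + r_s): p_i = p + r p with
#' one scalar coefficient per set, r in [-0.5, 0.5] (50% to 150% of the
#' optimum).
#'
#' @param p parameter vector of length 16.
#' @param r 4-vector of perturbation coefficients in \[-0.5, 0.5\], ordered
#'   (k_y, b_y, k_x, b_x).
#' @return perturbed 16-vector.
#' @export
perturb_sets <- function(p, r) {
  if (length(p) != 16L) stop("parameter vector must have length 16")
  if (length(r) != 4L) stop("r must have one coefficient per parameter set")
  if (any(r < -0.5 - 1e-12) || any(r > 0.5 + 1e-12)) {
    stop("perturbation coefficients must lie in [-0.5, 0.5]")
  }
  p * (1 + rep(r, each = 4))
}

#' Sweep one parameter set between 50% and 150% of its optimum
#'
#' @param model a `specimen_model`.
#' @param data list with windowed `force` and `markers`.
#' @param p_opt identified optimum 16-vector.
#' @param set one of `"k_y"`, `"b_y"`, `"k_x"`, `"b_x"`.
#' @param scales grid of multiplicative scales (default 11 points in
#'   \[0.5, 1.5\]).
#' @return data.frame with `scale` and `rmse_mm`.
#' @export
sweep_parameter_set <- function(model, data, p_opt, set,
                                scales = seq(0.5, 1.5, length.out = 11)) {
  idx <- param_set_indices(set)
  rmse <- vapply(scales, function(s) {
    p <- p_opt
    p[idx] <- p[idx] * s
    evaluate_with_fixed_parameters(model, data, p)
  }, numeric(1))
  data.frame(scale = scales, rmse_mm = rmse)
}

#' Monte Carlo sensitivity analysis of the four parameter sets
#'
#' Draws `n` samples of r ~ Uniform(-0.5, 0.5)^4 (one coefficient per
#' functional set by default; `per_parameter = TRUE` draws one coefficient
#' per parameter instead), simulates each perturbed parameter vector and
#' records RMSE_per and the change DeltaRMSE = RMSE_per - RMSE_opt.
#'
#' @param model a `specimen_model`.
#' @param data list with windowed `force` and `markers`.
#' @param p_opt identified optimum 16-vector.
#' @param n number of samples (default 1000).
#' @param seed RNG seed; the sample list is reproducible given the seed.
#' @param per_parameter draw 16 independent coefficients instead of 4.
#' @return data.frame of class `mc_sensitivity` with columns `r_ky`, `r_by`,
#'   `r_kx`, `r_bx` (set-mean coefficients when `per_parameter`),
#'   `rmse_per_mm`, `delta_rmse_mm`; attributes `rmse_opt_mm` and `seed`.
#' @export
run_monte_carlo <- function(model, data, p_opt, n = 1000, seed = 1,
                            per_parameter = FALSE) {
  if (n <= 0) stop("n must be positive")
  rmse_opt <- evaluate_with_fixed_parameters(model, data, p_opt)
  draws <- mc_draws(n, seed, per_parameter)
  rmse_per <- vapply(seq_len(n), function(i) {
    p <- if (per_parameter) {
      p_opt * (1 + draws[i, ])
    } else {
      perturb_sets(p_opt, draws[i, ])
    }
    evaluate_with_fixed_parameters(model, data, p)
  }, numeric(1))
  rset <- if (per_parameter) {
    t(apply(draws, 1, function(d) vapply(1:4, function(s) {
      mean(d[(s - 1) * 4 + 1:4])
    }, numeric(1))))
  } else {
    draws
  }
  out <- data.frame(r_ky = rset[, 1], r_by = rset[, 2],
                    r_kx = rset[, 3], r_bx = rset[, 4],
                    rmse_per_mm = rmse_per,
                    delta_rmse_mm = rmse_per - rmse_opt)
  attr(out, "rmse_opt_mm") <- rmse_opt
  attr(out, "seed") <- seed
  class(out) <- c("mc_sensitivity", "data.frame")
  out
}

# Uniform(-0.5, 0.5) perturbation coefficients, one column per parameter set
# (or per parameter); the sampling path behind run_monte_carlo().
mc_draws <- function(n, seed, per_parameter = FALSE) {
  with_seed(seed, {
    if (per_parameter) {
      matrix(runif(n * 16, -0.5, 0.5), n, 16)
    } else {
      matrix(runif(n * 4, -0.5, 0.5), n, 4)
    }
  })
}

cubic_basis <- function(ra, rb) {
  cbind(1, ra, rb, ra^2, ra * rb, rb^2, ra^3, ra^2 * rb, ra * rb^2, rb^3)
}

surface_pairs <- function() {
  utils::combn(PARAM_SETS, 2, simplify = FALSE)
}

#' Fit a third-degree response surface over one parameter-set pair
#'
#' Ordinary least squares of DeltaRMSE on the complete bivariate cubic basis
#' (10 terms) in the pair's two perturbation coefficients, using all Monte
#' Carlo samples projected onto that pair.
#'
#' @param samples an `mc_sensitivity` data.frame.
#' @param pair character 2-vector, e.g. `c("k_y", "b_x")`.
#' @return object of class `surface_fit`: `pair`, `coefficients` (10),
#'   `residual_norm`, and a `predict`-ready basis description.
#' @export
fit_pair_surface <- function(samples, pair) {
  if (length(pair) != 2L || !all(pair %in% PARAM_SETS)) {
    stop("pair must name two of the four parameter sets")
  }
  cols <- c(k_y = "r_ky", b_y = "r_by", k_x = "r_kx", b_x = "r_bx")
  ra <- samples[[cols[pair[1]]]]
  rb <- samples[[cols[pair[2]]]]
  if (length(ra) < 10) stop("need at least 10 samples for the 10-term cubic")
  X <- cubic_basis(ra, rb)
  if (qr(X)$rank < 10) stop("rank-deficient design: fewer than 10 distinct points")
  y <- samples$delta_rmse_mm
  beta <- qr.solve(X, y)
  res <- y - X %*% beta
  names(beta) <- c("1", "ra", "rb", "ra2", "ra.rb", "rb2",
                   "ra3", "ra2.rb", "ra.rb2", "rb3")
  structure(list(pair = pair, coefficients = beta,
                 residual_norm = sqrt(sum(res^2)),
                 n = length(y)),
            class = "surface_fit")
}

#' @export
print.surface_fit <- function(x, ...) {
  cat(sprintf("Cubic response surface for (%s, %s): residual norm %.4g mm over %d samples\n",
              x$pair[1], x$pair[2], x$residual_norm, x$n))
  print(round(x$coefficients, 6))
  invisible(x)
}

#' Evaluate a fitted response surface
#'
#' @param object a `surface_fit`.
#' @param ra,rb perturbation coefficients for the pair's first and second set.
#' @param ... unused.
#' @return predicted DeltaRMSE, mm.
#' @export
predict.surface_fit <- function(object, ra, rb, ...) {
  as.numeric(cubic_basis(ra, rb) %*% object$coefficients)
}

#' Fit the response surfaces for all six parameter-set pairs
#'
#' @param samples an `mc_sensitivity` data.frame.
#' @return named list of six `surface_fit` objects.
#' @export
fit_all_pair_surfaces <- function(samples) {
  prs <- surface_pairs()
  out <- lapply(prs, function(p) fit_pair_surface(samples, p))
  names(out) <- vapply(prs, paste, character(1), collapse = ":")
  out
}

#' Sweep the anteroposterior joint-frame positions
#'
#' Shifts all four joint-frame origins simultaneously by d_x along their own
#' x-axes (JFP_i^x = JFP^x + d_x), re-simulates and reports the tracking
#' RMSE at each grid point.
#'
#' @param model a `specimen_model`.
#' @param data list with windowed `force` and `markers`.
#' @param p_opt identified optimum 16-vector.
#' @param d_x grid of shifts in m, each within \[-0.02, 0.02\] (default 9
#'   points spanning the range).
#' @return data.frame with `d_x_m` and `rmse_mm`.
#' @export
sweep_joint_frame_positions <- function(model, data, p_opt,
                                        d_x = seq(-0.02, 0.02,
                                                  length.out = 9)) {
  if (any(abs(d_x) > 0.02 + 1e-12)) {
    stop("joint frame shifts must lie within [-0.02, 0.02] m")
  }
  m0 <- set_model_parameters(model, p_opt)
  measured <- data$markers
  window_s <- measured$times[length(measured$times)]
  rmse <- vapply(d_x, function(dx) {
    simres <- tryCatch(
      simulate_specimen(shifted_model_with(m0, dx), data$force,
                        window_s = window_s, marker_times = measured$times),
      error = function(e) NULL)
    if (is.null(simres) || isTRUE(simres$diverged)) return(1e6)
    tracking_rmse(measured, simres$markers)
  }, numeric(1))
  data.frame(d_x_m = d_x, rmse_mm = rmse)
}

shifted_model_with <- function(model, dx) {
  model$joints <- lapply(model$joints, function(J) {
    J$origin <- as.numeric(J$origin + J$orientation %*% c(dx, 0, 0))
    J
  })
  model
}
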