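# S3 methods for the fitted identification object.

#' @export
print.bushing_fit <- function(x, ...) {
  cat("Impact-specific bushing parameter fit\n")
  cat(sprintf("  tracking RMSE at optimum: %.4f mm\n", x$rmse_opt))
  cat(sprintf("  GA: %d individuals x %d generations (%d evaluations, seed %s)\n",
              x$control$pop_size, x$control$generations, x$n_eval,
              format(x$seed)))
  if (x$n_penalised > 0) {
    cat(sprintf("  penalised (diverged) evaluations: %d\n", x$n_penalised))
  }
  cat("  coefficients: see summary() for the per-joint table\n")
  invisible(x)
}

#' @export
summary.bushing_fit <- function(object, ...) {
  sets <- parameter_sets(coef(object))
  tab <- do.call(rbind, lapply(names(sets), function(s) {
    data.frame(set = s, joint = names(sets[[s]]), value = unname(sets[[s]]),
               unit = if (grepl("^k", s)) "N/m" else "Ns/m",
               stringsAsFactors = FALSE)
  }))
  out <- list(table = tab, rmse_opt = object$rmse_opt,
              history = object$history, n_eval = object$n_eval)
  class(out) <- "summary.bushing_fit"
  out
}

#' @export
print.summary.bushing_fit <- function(x, ...) {
  cat("Identified axial/shear viscoelastic bushing parameters\n")
  for (s in unique(x$table$set)) {
    sub <- x$table[x$table$set == s, ]
    cat(sprintf("  %-4s [%s]: %s\n", s, sub$unit[1],
                paste(sprintf("%s=%.4g", sub$joint, sub$value),
                      collapse = "  ")))
  }
  cat(sprintf("Tracking RMSE at optimum: %.4f mm (%d objective evaluations)\n",
              x$rmse_opt, x$n_eval))
  invisible(x)
}

#' @export
coef.bushing_fit <- function(object, ...) object$coefficients

#' Simulate the fitted model
#'
#' Re-runs the forward dynamics with the fitted parameters (or any other
#' 16-vector) under the fitting window's force, returning the full
#' `simulation_result`.
#'
#' @param object a `bushing_fit`.
#' @param nsim unused (one deterministic simulation).
#' @param seed unused; the forward dynamics are deterministic.
#' @param parameters optional alternative parameter vector.
#' @param ... passed to [simulate_specimen()].
#' @export
simulate.bushing_fit <- function(object, nsim = 1, seed = NULL,
                                 parameters = NULL, ...) {
  p <- parameters %||% coef(object)
  m <- set_model_parameters(object$init_model, p)
  measured <- object$data$markers
  simulate_specimen(m, object$data$force,
                    window_s = measured$times[length(measured$times)],
                    marker_times = measured$times, ...)
}

#' @export
fitted.bushing_fit <- function(object, ...) {
  simulate(object)$markers
}

#' Per-frame, per-marker tracking residuals
#'
#' @param object a `bushing_fit`.
#' @param ... unused.
#' @return matrix (frames x markers) of Euclidean distances, mm.
#' @export
residuals.bushing_fit <- function(object, ...) {
  sim <- fitted(object)
  meas <- object$data$markers
  sim_data <- sim$data[, , marker_names(meas), drop = FALSE]
  d <- sqrt(apply((meas$data - sim_data)^2, c(1, 3), sum)) * 1000
  rownames(d) <- NULL
  d
}

#' Plot the GA convergence and tracking residuals
#'
#' Left panel: best tracking RMSE per generation. Right panel: per-marker
#' residual traces over the analysis window at the optimum.
#'
#' @param x a `bushing_fit`.
#' @param ... unused.
#' @export
plot.bushing_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(seq_along(x$history) - 1, x$history, type = "b", pch = 16,
                 xlab = "generation", ylab = "best tracking RMSE [mm]",
                 main = "GA convergence")
  r <- residuals(x)
  tms <- x$data$markers$times * 1000
  graphics::matplot(tms, r, type = "l", lty = 1,
                    xlab = "time after impact [ms]",
                    ylab = "marker residual [mm]", main = "tracking residuals")
  invisible(x)
}
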