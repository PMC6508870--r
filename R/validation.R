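# Validation: median aggregation across specimens, five-fold cross-validation
# of transferred parameters, and evaluation with fixed (literature) values.

#' Componentwise median of identified parameter vectors
#'
#' For an even number of specimens the median is the arithmetic midpoint of
#' the two central values (each cross-validation fold aggregates exactly
#' four).
#'
#' @param results list of 16-vectors (or `bushing_fit` objects).
#' @return named 16-vector.
#' @export
aggregate_median_parameters <- function(results) {
  if (length(results) == 0) stop("no parameter vectors to aggregate")
  vecs <- lapply(results, function(r) {
    if (inherits(r, "bushing_fit")) coef(r) else as.numeric(r)
  })
  if (any(lengths(vecs) != 16L)) stop("all parameter vectors must have length 16")
  m <- apply(do.call(rbind, vecs), 2, median)
  names(m) <- rownames(default_parameter_bounds())
  m
}

#' Tracking RMSE of a model with fixed parameters
#'
#' Installs `p`, runs the forward dynamics over the data window and returns
#' the tracking RMSE; no optimisation. Used for the literature-value
#' (RMSE_lit) and transferred-median (RMSE_val) evaluations.
#'
#' @param model a `specimen_model`.
#' @param data list with `force` (windowed net [force_trace()]) and
#'   `markers` (windowed measured [marker_trajectories()]).
#' @param p parameter vector of length 16.
#' @return RMSE in mm (the 1e6 mm penalty if the simulation diverges).
#' @export
evaluate_with_fixed_parameters <- function(model, data, p) {
  evaluate_objective(p, model, data$force, data$markers)
}

#' Five-fold leave-one-specimen-out cross-validation
#'
#' For each fold the componentwise median of the four remaining specimens'
#' identified parameters (all 16 transferred jointly) is installed in the
#' held-out specimen's model, the forward dynamics are re-run, and the
#' resulting tracking RMSE (RMSE_val) is compared with that specimen's own
#' optimum (RMSE_opt).
#'
#' @param specimens list of exactly 5 entries, each a list with `model`,
#'   `data` (as in [evaluate_with_fixed_parameters()]) and `fit` (a
#'   `bushing_fit` or a list with `coefficients` and `rmse_opt`).
#' @return data.frame of class `crossval_result` with one row per fold:
#'   `specimen`, `rmse_opt_mm`, `rmse_val_mm`, `pct_increase`.
#' @export
cross_validate_five_fold <- function(specimens) {
  if (length(specimens) != 5L) stop("five-fold cross-validation needs exactly 5 specimens")
  ok <- vapply(specimens, function(s) {
    !is.null(s$fit) && !is.null(s$model) && !is.null(s$data)
  }, logical(1))
  if (!all(ok)) stop("missing identification result for at least one specimen")
  coefs <- lapply(specimens, function(s) {
    if (inherits(s$fit, "bushing_fit")) coef(s$fit) else s$fit$coefficients
  })
  opt <- vapply(specimens, function(s) {
    if (inherits(s$fit, "bushing_fit")) s$fit$rmse_opt else s$fit$rmse_opt
  }, numeric(1))
  ids <- names(specimens) %||% paste0("S", seq_along(specimens))

  rows <- lapply(seq_along(specimens), function(i) {
    p_med <- aggregate_median_parameters(coefs[-i])
    rv <- evaluate_with_fixed_parameters(specimens[[i]]$model,
                                         specimens[[i]]$data, p_med)
    data.frame(specimen = ids[i],
               rmse_opt_mm = opt[i],
               rmse_val_mm = rv,
               pct_increase = 100 * (rv - opt[i]) / opt[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (anyNA(out$rmse_val_mm)) stop("cross-validation produced NaN fold errors")
  class(out) <- c("crossval_result", "data.frame")
  out
}

#' @export
print.crossval_result <- function(x, ...) {
  cat("Five-fold cross-validation of transferred median parameters\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  cat(sprintf("mean increase over optimum: %.2f%%\n", mean(x$pct_increase)))
  invisible(x)
}
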