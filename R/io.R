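# File formats and the end-to-end pipeline driver. TRC stores millimetres by
# convention; everything inside the package is SI (m, N, s) and conversion
# happens at the I/O boundary only.

#' Write marker trajectories to a TRC file
#'
#' Standard TRC layout: PathFileType line, header-name line, header-value
#' line (DataRate, NumFrames, NumMarkers, Units = mm), marker-name line,
#' coordinate-label line, then `Frame# Time X Y Z ...` rows. Positions are
#' converted from metres to millimetres.
#'
#' @param traj a [marker_trajectories()].
#' @param path output file path.
#' @export
write_marker_file <- function(traj, path) {
  nm <- marker_names(traj)
  n_frames <- dim(traj$data)[1]
  rate <- if (is.finite(traj$fs)) traj$fs else
    1 / mean(diff(traj$times))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("PathFileType\t4\t(X/Y/Z)\t%s", basename(path)), con)
  writeLines(paste("DataRate", "CameraRate", "NumFrames", "NumMarkers",
                   "Units", "OrigDataRate", "OrigDataStartFrame",
                   "OrigNumFrames", sep = "\t"), con)
  writeLines(sprintf("%g\t%g\t%d\t%d\tmm\t%g\t1\t%d",
                     rate, rate, n_frames, length(nm), rate, n_frames), con)
  writeLines(paste(c("Frame#", "Time",
                     unlist(lapply(nm, function(m) c(m, "", "")))),
                   collapse = "\t"), con)
  writeLines(paste(c("", "", unlist(lapply(seq_along(nm), function(i) {
    paste0(c("X", "Y", "Z"), i)
  }))), collapse = "\t"), con)
  for (f in seq_len(n_frames)) {
    row <- c(f, sprintf("%.9f", traj$times[f]),
             sprintf("%.9f", as.vector(traj$data[f, , ]) * 1000))
    writeLines(paste(row, collapse = "\t"), con)
  }
  invisible(path)
}

#' Read marker trajectories from a TRC file
#'
#' @param path TRC file path.
#' @return a [marker_trajectories()] with positions in metres.
#' @export
read_marker_file <- function(path) {
  if (!file.exists(path)) stop("marker file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 6 || !grepl("^PathFileType", lines[1])) {
    stop("malformed TRC header")
  }
  hd_names <- strsplit(lines[2], "\t")[[1]]
  hd_vals <- strsplit(lines[3], "\t")[[1]]
  hd <- setNames(as.list(hd_vals), hd_names)
  rate <- as.numeric(hd$DataRate)
  n_markers <- as.integer(hd$NumMarkers)
  units <- hd$Units
  scale <- switch(units, mm = 1e-3, m = 1, stop("unsupported TRC units"))
  nm <- strsplit(lines[4], "\t")[[1]]
  nm <- nm[-(1:2)]
  nm <- nm[nm != ""]
  if (length(nm) != n_markers) {
    stop("TRC header declares a different marker count than the name line")
  }
  data_lines <- lines[-(1:5)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  rows <- lapply(data_lines, function(l) as.numeric(strsplit(l, "\t")[[1]]))
  ncols <- 2 + 3 * n_markers
  if (any(vapply(rows, length, integer(1)) != ncols)) {
    stop("inconsistent column count in TRC data rows")
  }
  M <- do.call(rbind, rows)
  if (anyNA(M)) stop("NaN frames in TRC data")
  n_frames <- nrow(M)
  arr <- array(NA_real_, c(n_frames, 3, n_markers),
               dimnames = list(NULL, c("x", "y", "z"), nm))
  for (i in seq_len(n_markers)) {
    arr[, , i] <- M[, (2 + 3 * (i - 1) + 1):(2 + 3 * i), drop = FALSE] * scale
  }
  marker_trajectories(arr, fs = rate, times = M[, 2])
}

#' Write a force trace to CSV
#'
#' Dialect: header `time_s,force_N`, one row per sample.
#'
#' @param trace a [force_trace()].
#' @param path output path.
#' @export
write_force_file <- function(trace, path) {
  df <- data.frame(time_s = sprintf("%.9f", trace_times(trace)),
                   force_N = sprintf("%.9f", trace$force))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a force trace from CSV
#'
#' Requires the `time_s,force_N` header and a uniform time step (tolerance
#' 1 ppm of the step).
#'
#' @param path CSV path.
#' @param channel channel label to attach.
#' @return a [force_trace()].
#' @export
read_force_file <- function(path, channel = "cranial") {
  if (!file.exists(path)) stop("force file not found: ", path)
  df <- read.csv(path)
  if (!all(c("time_s", "force_N") %in% names(df))) {
    stop("missing time_s/force_N header in force CSV")
  }
  t <- df$time_s
  if (any(diff(t) <= 0)) stop("non-monotone time in force CSV")
  dt <- diff(t)
  if (max(abs(dt - mean(dt))) > 1e-6 * mean(dt)) {
    stop("non-uniform sampling in force CSV")
  }
  force_trace(df$force_N, fs = 1 / mean(dt), channel = channel)
}

#' Serialize a specimen model to JSON
#'
#' Sections: segments, joints, bushings, constraints, preload, gravity; all
#' units SI.
#'
#' @param model a `specimen_model`.
#' @param path output path.
#' @export
write_model_json <- function(model, path) {
  obj <- list(
    units = list(length = "m", force = "N", mass = "kg", time = "s"),
    segments = lapply(model$segments, function(s) {
      list(name = s$name, mass = s$mass, inertia = s$inertia,
           com = s$com, markers = s$markers)
    }),
    joints = lapply(model$joints, function(j) {
      list(name = j$name, caudal = j$caudal, cranial = j$cranial,
           origin = j$origin, orientation = j$orientation)
    }),
    bushings = lapply(model$bushings, unclass),
    constraints = as.list(model$constraints),
    gravity = model$gravity,
    preload = model$preload,
    load = model$load
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a specimen model from JSON
#'
#' @param path JSON path written by [write_model_json()].
#' @return a `specimen_model`.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyMatrix = TRUE)
  segments <- lapply(obj$segments, function(s) {
    list(name = s$name, mass = s$mass,
         inertia = matrix(unlist(s$inertia), 3, 3, byrow = FALSE),
         com = as.numeric(s$com),
         markers = lapply(s$markers, as.numeric))
  })
  joints <- lapply(obj$joints, function(j) {
    list(name = j$name, caudal = j$caudal, cranial = j$cranial,
         origin = as.numeric(j$origin),
         orientation = matrix(unlist(j$orientation), 3, 3))
  })
  bushings <- lapply(obj$bushings, function(b) {
    bushing_parameters(b$k_trans, b$b_trans, b$k_rot, b$b_rot)
  })
  structure(list(segments = segments, joints = joints, bushings = bushings,
                 constraints = unlist(obj$constraints),
                 gravity = as.numeric(obj$gravity),
                 preload = obj$preload,
                 load = list(body = obj$load$body,
                             dir = as.numeric(obj$load$dir))),
            class = "specimen_model")
}

#' Run the identification pipeline end to end
#'
#' filter -> onset detection -> windowing -> identification, optionally
#' followed by Monte Carlo sensitivity. Writes result artifacts and a
#' manifest (config hash, seed, stage log) to the output directory; any
#' stage error aborts with the stage name while preserving partial
#' artifacts.
#'
#' @param config list (or path to a JSON config) with entries: `model`
#'   (a `specimen_model` or path), `marker_file`, `force_file` (or in-memory
#'   `markers`/`force` objects), `force_cutoff_hz` (default 5000),
#'   `marker_cutoff_hz` (150), `filter_order` (4), `threshold_N` (200),
#'   `window_s` (0.005), `ga` (list passed to [ga_control()]), `seed`,
#'   `sensitivity_n` (0 to skip), `out_dir`.
#' @return list with `fit`, `window`, `manifest` (invisibly also written to
#'   `out_dir`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  out_dir <- config$out_dir %||% tempfile("neckdyn_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  t_start <- Sys.time()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    stages[[name]] <<- list(status = "complete",
                            seconds = as.numeric(Sys.time() - t0,
                                                 units = "secs"))
    res
  }

  model <- stage("load_model", {
    if (is.character(config[["model"]])) read_model_json(config[["model"]])
    else config[["model"]]
  })
  inputs <- stage("load_inputs", {
    force <- if (!is.null(config[["force"]])) config[["force"]]
    else read_force_file(config[["force_file"]])
    markers <- if (!is.null(config[["markers"]])) config[["markers"]]
    else read_marker_file(config[["marker_file"]])
    list(force = force, markers = markers)
  })
  windowed <- stage("signal_processing", {
    fo <- config$filter_order %||% 4
    force_f <- zero_lag_lowpass(inputs$force,
                                cutoff = config$force_cutoff_hz %||% 5000,
                                order = fo)
    markers_f <- inputs$markers
    mc <- config$marker_cutoff_hz %||% 150
    if (is.finite(markers_f$fs) && mc < markers_f$fs / 2 &&
        dim(markers_f$data)[1] > 3 * fo + 1) {
      for (m in seq_len(dim(markers_f$data)[3])) {
        for (d in 1:3) {
          markers_f$data[, d, m] <- zero_lag_lowpass(
            markers_f$data[, d, m], markers_f$fs, mc, fo)
        }
      }
    }
    onset <- detect_impact_onset(force_f,
                                 threshold_N = config$threshold_N %||% 200)
    align_and_window(force_f, markers_f, onset,
                     window_s = config$window_s %||% 0.005)
  })
  fit <- stage("identification", {
    ga_args <- config$ga %||% list()
    control <- do.call(ga_control, ga_args)
    fit_bushings(model, windowed$markers, windowed$force, control = control,
                 seed = config$seed %||% control$seed)
  })
  result_path <- file.path(out_dir, "result.json")
  stage("write_result", {
    jsonlite::write_json(list(
      parameters = as.list(coef(fit)),
      units = list(stiffness = "N/m", damping = "Ns/m"),
      rmse_opt_mm = fit$rmse_opt,
      history_mm = fit$history,
      n_eval = fit$n_eval,
      seed = fit$seed
    ), result_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  mc <- NULL
  n_mc <- config$sensitivity_n %||% 0
  if (n_mc > 0) {
    mc <- stage("sensitivity", {
      samples <- run_monte_carlo(model, windowed[c("force", "markers")],
                                 coef(fit), n = n_mc,
                                 seed = config$seed %||% 1)
      write.csv(samples, file.path(out_dir, "mc.csv"), row.names = FALSE)
      samples
    })
  }
  cfg_path <- file.path(out_dir, "config.json")
  cfg_ser <- config
  cfg_ser$model <- NULL
  cfg_ser$force <- NULL
  cfg_ser$markers <- NULL
  jsonlite::write_json(cfg_ser, cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("neckdyn")),
    config_hash = unname(tools::md5sum(cfg_path)),
    seed = config$seed %||% NULL,
    units = "SI",
    stages = stages,
    total_seconds = as.numeric(Sys.time() - t_start, units = "secs")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(fit = fit, window = windowed, sensitivity = mc,
                 manifest = manifest, out_dir = out_dir))
}
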