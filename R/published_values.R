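# Published reference values from the in vitro porcine C2-C6 impact study
# the synthetic generator emulates: per-specimen identified bushing
# parameters and cohort descriptives. Shipped as plain CSV under extdata.

#' Per-specimen identified bushing parameters (published values)
#'
#' Axial and shear stiffness and damping identified for five porcine C2-C6
#' specimens (S1-S5) under impulsive axial loading, plus the quasi-static
#' literature values used to initialise the optimisation. Units: N/m for
#' stiffness, Ns/m for damping.
#'
#' @return data.frame with columns `specimen` (`Initialised`, `S1`..`S5`),
#'   `joint` (`C2C3`..`C5C6`), `parameter` (`k_y`, `b_y`, `k_x`, `b_x`) and
#'   `value`.
#' @export
published_bushing_parameters <- function() {
  path <- system.file("extdata", "published_bushing_parameters.csv",
                      package = "neckdyn", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Specimen mass and height descriptives (published values)
#'
#' Mass and height of the six dissected porcine cervical spine segments;
#' specimen S6 fractured during testing and is excluded from cohort
#' statistics (`included = FALSE`).
#'
#' @return data.frame with `specimen`, `mass_kg`, `height_m`, `included`.
#' @export
specimen_descriptives <- function() {
  path <- system.file("extdata", "specimen_descriptives.csv",
                      package = "neckdyn", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Identified parameter vectors per published specimen
#'
#' @param specimens which specimens to extract (default S1..S5).
#' @return named list of 16-vectors in [pack_parameters()] order.
#' @export
published_parameter_vectors <- function(specimens = paste0("S", 1:5)) {
  pub <- published_bushing_parameters()
  lapply(setNames(specimens, specimens), function(s) {
    sub <- pub[pub$specimen == s, ]
    p <- unlist(lapply(PARAM_SETS, function(prm) {
      vapply(JOINT_NAMES, function(j) {
        sub$value[sub$parameter == prm & sub$joint == j]
      }, numeric(1))
    }))
    names(p) <- rownames(default_parameter_bounds())
    p
  })
}
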