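# Small internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

rot_x <- function(a) {
  matrix(c(1, 0, 0,
           0, cos(a), sin(a),
           0, -sin(a), cos(a)), 3, 3)
}
rot_y <- function(a) {
  matrix(c(cos(a), 0, -sin(a),
           0, 1, 0,
           sin(a), 0, cos(a)), 3, 3)
}
rot_z <- function(a) {
  matrix(c(cos(a), sin(a), 0,
           -sin(a), cos(a), 0,
           0, 0, 1), 3, 3)
}

# Body X-Y-Z Euler composition, matching the compiled core.
rot_xyz <- function(ang) rot_x(ang[1]) %*% rot_y(ang[2]) %*% rot_z(ang[3])

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalise a zero vector")
  v / n
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so fits do not disturb user-level randomness.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(sprintf("non-finite values in %s", what))
  invisible(x)
}
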