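# small internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

vnorm <- function(v) sqrt(sum(v * v))

unit_vec <- function(v) {
  n <- vnorm(v)
  if (n < 1e-300) stop("cannot normalize a zero vector", call. = FALSE)
  v / n
}

# 90 degree counter-clockwise rotation in the x-right / y-down image frame
rot90ccw <- function(v) c(-v[2], v[1])

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# 2D cross product z-component
cross2 <- function(a, b) a[1] * b[2] - a[2] * b[1]

# run body with a private RNG stream seeded at `seed`, restoring global state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
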