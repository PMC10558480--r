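# internal helpers shared across modules

assert_scalar_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x))) {
    abort(paste0("`", name, "` must be a single finite number"))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  assert_scalar_number(x, name)
  if (x < min || x != as.integer(x)) {
    abort(paste0("`", name, "` must be an integer >= ", min))
  }
  invisible(as.integer(x))
}

# wrap an angle into (-pi, pi]
wrap_angle <- function(theta) {
  out <- (theta + pi) %% (2 * pi) - pi
  ifelse(out <= -pi, out + 2 * pi, out)
}

# circular absolute difference between two angles, in [0, pi]
angle_distance <- function(a, b) {
  abs(wrap_angle(a - b))
}

# derive a stream of child seeds from a master seed, all < 2^31
derive_seeds <- function(seed, n) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  sample.int(.Machine$integer.max - 1L, n)
}

# evaluate expr with a local RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}
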