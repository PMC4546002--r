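# Internal helpers shared across modules.

DEG2RAD <- pi / 180
RAD2DEG <- 180 / pi

#' Wrap angles to (-180, 180]
#' @param x angles in degrees.
#' @return wrapped angles in degrees.
#' @keywords internal
#' @noRd
wrap_deg <- function(x) {
  w <- (x + 180) %% 360 - 180
  # map -180 to +180 so the interval is (-180, 180]
  w[w == -180] <- 180
  w
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic child seeds below 2^31, derived from a master seed.
derive_seeds <- function(master_seed, n) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(master_seed %% .Machine$integer.max))
  sample.int(.Machine$integer.max - 1L, n)
}

# Evaluate an expression under a local RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
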