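# Internal helpers: seeded RNG scoping and derived child seeds.

# Seed the RNG for the remainder of the calling function, restoring the
# caller-visible RNG state when that function exits.
local_rng <- function(seed, env = parent.frame()) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    restore <- if (is.null(old)) {
      quote(if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()))
    } else {
      bquote(assign(".Random.seed", .(old), envir = globalenv()))
    }
    do.call(on.exit, list(restore, add = TRUE), envir = env)
    set.seed(as.integer(seed))
  }
  invisible(seed)
}

# Deterministic child seed from a master seed and one or two indices; stays
# below 2^31 (R integers are 32-bit).
child_seed <- function(master, i, j = 0L) {
  m <- 2147483647
  s <- (as.double(master) %% m) * 48271 %% m
  s <- (s + as.double(i) * 1299709 + as.double(j) * 15485863) %% m
  as.integer(s) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
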