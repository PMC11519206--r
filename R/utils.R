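#' @keywords internal
"_PACKAGE"

# Classed conditions: every package error carries class "cbma_error" plus a
# specific subclass so callers (and tests) can discriminate failure modes.
cbma_abort <- function(message, class) {
  stop(errorCondition(message, class = c(class, "cbma_error")))
}

cbma_warn <- function(message, class = "cbma_warning") {
  warning(warningCondition(message, class = c(class, "cbma_warning")))
}

# Run `code` with the RNG seeded to `seed`, restoring the caller's RNG state
# afterwards so library calls never perturb a user's random stream.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# When no seed is supplied a fresh one is drawn (and reported by the caller)
# so that any unseeded run can still be replayed.
resolve_seed <- function(seed) {
  if (is.null(seed)) {
    seed <- sample.int(.Machine$integer.max, 1L)
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != trunc(seed)) {
    cbma_abort("`seed` must be a single integer", "cbma_bad_arguments")
  }
  as.integer(seed)
}

# Round half away from zero (mm -> voxel tie rule; documented, deterministic).
round_half_away <- function(x) {
  trunc(x + 0.5 * sign(x))
}

# Uniform draw of one element that is safe for length-1 vectors.
sample_one <- function(x) {
  x[sample.int(length(x), 1L)]
}

# Uniform integer in [lo, hi], safe when lo == hi.
sample_int_range <- function(lo, hi) {
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

# Shortest fixed-notation decimal representation that parses back to exactly
# the same double. Keeps written foci files human-readable while making the
# write -> parse round trip lossless.
format_coord <- function(x) {
  vapply(x, function(v) {
    if (!is.finite(v)) {
      cbma_abort("coordinates must be finite", "cbma_bad_coordinate")
    }
    for (d in 1:17) {
      s <- format(v, digits = d, scientific = FALSE, trim = TRUE)
      if (as.numeric(s) == v) return(s)
    }
    format(v, digits = 17, scientific = FALSE, trim = TRUE)
  }, character(1))
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)
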