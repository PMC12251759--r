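## Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
# All stochastic operations in the package go through this so outputs are pure
# functions of (config, seed).
with_rng_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic fan-out of one global seed into per-task seeds. `parts` is a
# character/numeric vector identifying the task; the result stays inside the
# 32-bit integer range R requires of set.seed().
derive_seed <- function(seed, ...) {
  parts <- paste(c(...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(parts)) h <- (h * 131 + ch) %% 1977326743
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_scalar_num <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max)
    stop("`", name, "` must be a single finite number in [", min, ", ", max, "]",
         call. = FALSE)
  invisible(x)
}
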