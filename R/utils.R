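# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All generators route through this so
# that identical specs give bit-identical output without disturbing the
# session RNG.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic sub-stream seed for object `index` under a root seed,
# kept inside 32-bit integer range.
substream_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 7919) %% 2147483647L)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE, closed_lower = TRUE,
                         closed_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  lo_ok <- if (closed_lower) x >= lower else x > lower
  hi_ok <- if (closed_upper) x <= upper else x < upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf(
      "`%s` must be in %s%s, %s%s (got %s).", name,
      if (closed_lower) "[" else "(", format(lower),
      format(upper), if (closed_upper) "]" else ")", format(x)
    ))
  }
  if (integer && x != round(x)) {
    abort(sprintf("`%s` must be a whole number (got %s).", name, format(x)))
  }
  invisible(x)
}

# Round half away from zero, the convention used for reported percentages.
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Integer (row, col) offsets of a disc of radius r around the origin,
# membership by Euclidean distance from pixel centre to centre <= r.
disc_offsets <- function(r) {
  k <- ceiling(r)
  g <- expand.grid(dr = -k:k, dc = -k:k)
  g <- g[g$dr^2 + g$dc^2 <= r^2, , drop = FALSE]
  as.matrix(g)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
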