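# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort("`seed` must be a single integer.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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
  force(code)
}

# Derive a child seed from a base seed and a stream index, staying in 32-bit
# signed range.
child_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 7919 + stream * 104729) %% .Machine$integer.max)
}

# Centred moving-average smoother with window w, renormalised at the edges
# over the in-range part of the window. O(n) via cumulative sums.
moving_average <- function(x, w) {
  w <- max(1L, as.integer(w))
  n <- length(x)
  if (w == 1L || n == 1L) return(x)
  hl <- (w - 1L) %/% 2L            # left half-window
  hr <- w - 1L - hl                # right half-window
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - hl, 1L)
  hi <- pmin(seq_len(n) + hr, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Apply moving_average to every row of a matrix.
row_moving_average <- function(m, w) {
  t(apply(m, 1, moving_average, w = w))
}
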