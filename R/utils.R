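# Internal helpers shared across modules.

# Snap a time (ms) to the sample grid, rounding half-up. Half-up rather than
# banker's rounding keeps fractional-GC arithmetic deterministic on the grid.
round_grid <- function(x, step_ms) {
  floor(x / step_ms + 0.5) * step_ms
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Indices of strict local maxima; a plateau contributes its first sample.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  # collapse plateaus so runs of equal values count once, at their first sample
  r <- rle(x)
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mid <- 2:(k - 1L)
  is_max <- r$values[mid] > r$values[mid - 1L] & r$values[mid] > r$values[mid + 1L]
  starts[mid][is_max]
}

local_minima <- function(x) local_maxima(-x)

# Topographic prominence of the peaks at `peaks` (indices into x).
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    # walk left until a strictly higher sample (or the edge), track the minimum
    left <- x[seq_len(p - 1L)]
    higher_l <- which(left > h)
    lmin <- if (length(higher_l)) min(left[(max(higher_l) + 1L):(p - 1L)]) else min(c(left, h))
    right <- x[seq.int(p + 1L, length(x))]
    if (p == length(x)) right <- numeric(0)
    higher_r <- which(right > h)
    rmin <- if (length(higher_r)) min(right[seq_len(min(higher_r) - 1L)]) else min(c(right, h))
    h - max(lmin, rmin)
  }, numeric(1))
}

# Prominent local maxima of x: prominence at least `prom_frac` of the range of x.
prominent_maxima <- function(x, prom_frac) {
  p <- local_maxima(x)
  if (!length(p)) return(integer(0))
  rng <- diff(range(x))
  if (rng == 0) return(integer(0))
  p[peak_prominence(x, p) >= prom_frac * rng]
}

prominent_minima <- function(x, prom_frac) prominent_maxima(-x, prom_frac)

# Centered moving average with partial windows at the edges.
moving_average <- function(x, window) {
  if (window <= 1L) return(x)
  half <- (window - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
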