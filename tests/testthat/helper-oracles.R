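# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Point-to-chord distance via the cross-product formulation (different
# algebra from the slope-based implementation under test).
oracle_chord_distance <- function(t, q, t1, u1, t2, u2) {
  abs((u2 - u1) * (t - t1) - (t2 - t1) * (q - u1)) /
    sqrt((t2 - t1)^2 + (u2 - u1)^2)
}

# Exhaustive gradient-turning-point search: evaluate the distance at every
# sample and take the earliest argmax.
oracle_gtp <- function(t, q, t1, u1, t2, u2) {
  keep <- t >= min(t1, t2) & t <= max(t1, t2)
  d <- oracle_chord_distance(t[keep], q[keep], t1, u1, t2, u2)
  t[keep][which.max(d)]
}

# A random monotone curve segment on a uniform grid.
random_monotone_segment <- function(n = 50L) {
  t <- seq(0, by = 10, length.out = n)
  q <- cumsum(abs(rnorm(n)))
  if (runif(1) < 0.5) q <- -q     # decreasing half the time
  q <- q * runif(1, 0.1, 10)      # random scale
  list(t = t, q = q)
}

# Pinball loss of a candidate quantile line.
oracle_pinball <- function(x, y, c0, c1, tau) {
  r <- y - (c0 + c1 * x)
  sum(r * (tau - (r < 0)))
}

# Exhaustive grid search for the best linear quantile fit.
oracle_quantile_line <- function(x, y, tau, c0_grid, c1_grid) {
  best <- c(NA, NA); best_loss <- Inf
  for (c1 in c1_grid) for (c0 in c0_grid) {
    l <- oracle_pinball(x, y, c0, c1, tau)
    if (l < best_loss) {
      best_loss <- l
      best <- c(c0, c1)
    }
  }
  list(coef = best, loss = best_loss)
}

# Deterministic-timing spec used wherever tests need exact event recovery.
exact_spec <- function(...) {
  gait_spec(gc_sd_ms = 0, noise_sd = 0, ...)
}

# Truth columns aligned with the detection output.
event_cols <- c("T_HS", "T_footflat", "T_OTO", "T_OHS", "T_TO")
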