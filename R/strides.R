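#' Segment a trial into strides at heel strikes
#'
#' A stride (one gait cycle) spans the half-open interval between two
#' successive heel strikes of the instrumented foot, so `n` heel strikes yield
#' `n - 1` strides that partition `[first HS, last HS)` with no gaps or
#' overlaps.
#'
#' @param signal A [foot_motion_signal()].
#' @param hs_times Sorted heel-strike timestamps in ms, each within the
#'   signal's time range.
#' @return A data frame with one row per stride: `index`, `start_ms`,
#'   `end_ms`, `gc_ms` (gait-cycle duration) and `effective` (initialised
#'   `TRUE`; see [filter_effective_strides()]).
#' @export
segment_strides <- function(signal, hs_times) {
  empty <- data.frame(index = integer(0), start_ms = numeric(0),
                      end_ms = numeric(0), gc_ms = numeric(0),
                      effective = logical(0))
  if (length(hs_times) < 2L) {
    warning("fewer than 2 heel strikes: no strides to segment")
    return(empty)
  }
  if (is.unsorted(hs_times, strictly = TRUE))
    stop("hs_times must be strictly increasing")
  rng <- range(signal$t)
  if (any(hs_times < rng[1] | hs_times > rng[2]))
    stop("heel-strike times outside the signal time range")
  n <- length(hs_times) - 1L
  data.frame(index = seq_len(n),
             start_ms = hs_times[-(n + 1L)],
             end_ms = hs_times[-1L],
             gc_ms = diff(hs_times),
             effective = rep(TRUE, n))
}

#' Flag effective strides
#'
#' Marks the first two and last two strides of a trial non-effective
#' (gait initiation/termination), then screens the remaining strides for
#' waveform outliers: each stride's `G_x` waveform is resampled onto a common
#' phase axis and correlated against the pointwise median stride template;
#' strides whose correlation falls below `template_corr_min` are flagged
#' non-effective. The rule is a transparent, pluggable stand-in for outlier
#' removal (pass a different `predicate` to replace it).
#'
#' All strides are returned with updated `effective` flags (none are dropped),
#' so the operation is idempotent and boundary strides are never re-admitted.
#'
#' @param strides Stride table from [segment_strides()].
#' @param signal The [foot_motion_signal()] the strides index into.
#' @param template_corr_min Minimum Pearson correlation against the median
#'   template (default 0.8).
#' @param n_points Number of phase samples for the resampled waveforms.
#' @param predicate Optional function `(stride_matrix, template) -> logical`
#'   returning a keep flag per stride, replacing the correlation rule.
#' @return The stride table with `effective` updated.
#' @export
filter_effective_strides <- function(strides, signal, template_corr_min = 0.8,
                                     n_points = 101L, predicate = NULL) {
  n <- nrow(strides)
  if (n == 0L) return(strides)
  eff <- rep(FALSE, n)
  if (n >= 5L) eff[3:(n - 2L)] <- TRUE
  if (!any(eff)) {
    strides$effective <- eff
    return(strides)
  }
  gx <- get_channel(signal, "G_x")
  phase <- seq(0, 1, length.out = n_points)
  mat <- t(vapply(seq_len(n), function(i) {
    i0 <- time_to_index(signal, strides$start_ms[i])
    i1 <- time_to_index(signal, strides$end_ms[i])
    seg <- gx[i0:i1]
    stats::approx(seq(0, 1, length.out = length(seg)), seg, xout = phase)$y
  }, numeric(n_points)))
  template <- apply(mat[eff, , drop = FALSE], 2, stats::median)
  keep <- if (is.null(predicate)) {
    vapply(seq_len(n), function(i) {
      r <- suppressWarnings(stats::cor(mat[i, ], template))
      isTRUE(r >= template_corr_min)
    }, logical(1))
  } else {
    predicate(mat, template)
  }
  strides$effective <- eff & keep
  strides
}
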