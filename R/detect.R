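#' Detection configuration
#'
#' Tunable parameters of the rule-based gait-event detector. The amplitude
#' thresholds gate the opposite-heel-strike (OHS) search: after the foot-flat
#' state the first sample whose amplitude exceeds the channel's threshold
#' anchors the triangle-thresholding chord. Defaults follow the values used
#' with a 100 Hz in-shoe sensor: 0.15 g for `A_y` (deviation from the
#' foot-flat baseline), 1.15 g for `A_z` (absolute amplitude, gravity
#' included, i.e. ~0.15 g above the 1 g baseline) and 30 deg/s for `G_x`.
#'
#' @param channel Detection channel for foot-flat and OHS: `"Gx"` (default,
#'   the best-agreeing candidate), `"Ay"` or `"Az"`.
#' @param thr_Ay,thr_Az,thr_Gx Positive amplitude thresholds (g, g, deg/s).
#' @param oto_anchor_frac Fraction of the gait cycle after heel strike where
#'   the foot-flat chord is anchored (default 0.20; most subjects are
#'   foot-flat there).
#' @param oto_offset_frac Offset from foot-flat to opposite toe off as a
#'   fraction of the gait cycle (default 0.02).
#' @param ohs_window_start_frac Fraction of the gait cycle after which the
#'   OHS signature is expected (default 0.40).
#' @param prominence_frac Minimum topographic prominence of a usable peak,
#'   as a fraction of the local signal range (default 0.10). This is the
#'   package's explicit sharpness criterion for peak/valley selection.
#' @param hs_height_frac Heel-strike pre-impact peaks must reach this fraction
#'   of the trial's `A_y` maximum (default 0.5).
#' @param hs_valley_window_ms Window after an accepted `A_y` maximum searched
#'   for the adjacent heel-strike valley (default 150 ms).
#' @param hs_min_drop_frac Minimum drop from peak to valley, as a fraction of
#'   the trial's `A_y` range, for the valley to count as sharp (default 0.25).
#' @param to_window_frac Two fractions of the gait cycle bounding the toe-off
#'   search window after heel strike (default `c(0.30, 0.90)`).
#' @param to_depth_frac A toe-off valley must be at least this fraction as
#'   deep as the deepest sample in the search window (default 0.5).
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(channel = c("Gx", "Ay", "Az"),
                             thr_Ay = 0.15, thr_Az = 1.15, thr_Gx = 30,
                             oto_anchor_frac = 0.20, oto_offset_frac = 0.02,
                             ohs_window_start_frac = 0.40,
                             prominence_frac = 0.10,
                             hs_height_frac = 0.5,
                             hs_valley_window_ms = 150,
                             hs_min_drop_frac = 0.25,
                             to_window_frac = c(0.30, 0.90),
                             to_depth_frac = 0.5) {
  channel <- match.arg(channel)
  stopifnot(thr_Ay > 0, thr_Az > 0, thr_Gx > 0,
            oto_anchor_frac > 0,
            oto_anchor_frac < ohs_window_start_frac,
            ohs_window_start_frac < 1,
            oto_offset_frac > 0, oto_offset_frac < 1,
            prominence_frac > 0,
            length(to_window_frac) == 2L,
            to_window_frac[1] < to_window_frac[2])
  structure(list(channel = channel, thr_Ay = thr_Ay, thr_Az = thr_Az,
                 thr_Gx = thr_Gx, oto_anchor_frac = oto_anchor_frac,
                 oto_offset_frac = oto_offset_frac,
                 ohs_window_start_frac = ohs_window_start_frac,
                 prominence_frac = prominence_frac,
                 hs_height_frac = hs_height_frac,
                 hs_valley_window_ms = hs_valley_window_ms,
                 hs_min_drop_frac = hs_min_drop_frac,
                 to_window_frac = to_window_frac,
                 to_depth_frac = to_depth_frac),
            class = "detection_config")
}

#' Detect heel strikes from the anterior-posterior acceleration
#'
#' Heel strike leaves a characteristic signature in `A_y`: a sharp valley
#' immediately after the cycle's pre-impact maximum. The detector finds
#' prominent `A_y` maxima reaching `hs_height_frac` of the trial maximum and,
#' for each, takes the minimum within the following `hs_valley_window_ms` as
#' the heel-strike instant; maxima without a sufficiently deep valley are
#' skipped with a warning.
#'
#' @param signal A [foot_motion_signal()] with `A_y` present.
#' @param cfg A [detection_config()].
#' @return Sorted heel-strike timestamps in ms (possibly empty).
#' @export
detect_hs <- function(signal, cfg = detection_config()) {
  ay <- get_channel(signal, "A_y")
  n <- length(ay)
  rng <- diff(range(ay))
  if (n < 5L || rng == 0) return(numeric(0))
  peaks <- prominent_maxima(ay, cfg$prominence_frac)
  peaks <- peaks[ay[peaks] >= cfg$hs_height_frac * max(ay)]
  if (!length(peaks)) return(numeric(0))
  # one impact peak per cycle: within half the median inter-peak interval,
  # keep only the highest peak
  if (length(peaks) > 2L) {
    min_gap <- 0.5 * stats::median(diff(peaks))
    ord <- peaks[order(ay[peaks], decreasing = TRUE)]
    kept <- integer(0)
    for (p in ord) {
      if (!length(kept) || min(abs(kept - p)) >= min_gap) kept <- c(kept, p)
    }
    peaks <- sort(kept)
  }
  win <- max(2L, round(cfg$hs_valley_window_ms / sample_step(signal)))
  hs <- vapply(peaks, function(p) {
    hi <- min(n, p + win)
    if (hi <= p) return(NA_real_)
    seg <- ay[(p + 1L):hi]
    v <- p + which.min(seg)
    if (ay[p] - ay[v] < cfg$hs_min_drop_frac * rng) return(NA_real_)
    signal$t[v]
  }, numeric(1))
  if (anyNA(hs))
    warning(sprintf("%d cycle(s) without a qualifying heel-strike valley skipped",
                    sum(is.na(hs))))
  sort(unique(hs[!is.na(hs)]))
}

#' Detect toe off from the W-shaped acceleration pattern
#'
#' Toe off is the first valley of the W-shaped `A_y` pattern that follows the
#' foot-flat state. Per stride, the detector searches the window
#' `to_window_frac` of the gait cycle after heel strike for the first local
#' minimum at least `to_depth_frac` as deep as the window minimum; strides
#' without such a pattern yield `NA`.
#'
#' @param signal A [foot_motion_signal()] with `A_y` present.
#' @param hs_times Sorted heel-strike timestamps (ms).
#' @param cfg A [detection_config()].
#' @return Toe-off timestamps in ms, one per stride (`NA` when absent).
#' @export
detect_to <- function(signal, hs_times, cfg = detection_config()) {
  ay <- get_channel(signal, "A_y")
  if (length(hs_times) < 2L) return(numeric(0))
  n_str <- length(hs_times) - 1L
  vapply(seq_len(n_str), function(i) {
    gc <- hs_times[i + 1L] - hs_times[i]
    lo <- time_to_index(signal, hs_times[i] + cfg$to_window_frac[1] * gc)
    hi <- time_to_index(signal, hs_times[i] + cfg$to_window_frac[2] * gc)
    if (hi - lo < 2L) return(NA_real_)
    seg <- ay[lo:hi]
    cand <- prominent_minima(seg, cfg$prominence_frac)
    floor_val <- min(seg)
    if (floor_val >= 0) return(NA_real_)
    cand <- cand[seg[cand] <= cfg$to_depth_frac * floor_val]
    if (!length(cand)) return(NA_real_)
    signal$t[lo + cand[1L] - 1L]
  }, numeric(1))
}

#' Detect foot-flat and opposite toe off in one stride
#'
#' The foot-flat instant is the gradient turning point at which the detection
#' channel settles to its baseline after heel strike. The chord is anchored at
#' `P_A`, `oto_anchor_frac` of the gait cycle after heel strike, and at `P_B`,
#' the prominent local maximum of the channel nearest in time to `P_A`
#' (searching both directions; ties take the earlier). Opposite toe off is
#' reported at exactly `oto_offset_frac` of the gait cycle after foot-flat,
#' snapped to the sample grid.
#'
#' @param signal A [foot_motion_signal()].
#' @param stride_start_ms Heel-strike time (ms) opening the stride.
#' @param gc_ms Gait-cycle duration in ms (from the preceding heel-strike
#'   pair, so detection stays causal).
#' @param cfg A [detection_config()].
#' @return A list with `T_footflat` and `T_OTO` in ms (`NA` when detection
#'   fails).
#' @export
detect_footflat_and_oto <- function(signal, stride_start_ms, gc_ms,
                                    cfg = detection_config()) {
  failed <- list(T_footflat = NA_real_, T_OTO = NA_real_)
  x <- get_channel(signal, cfg$channel)
  step <- sample_step(signal)
  t_pa <- stride_start_ms + round_grid(cfg$oto_anchor_frac * gc_ms, step)
  i0 <- time_to_index(signal, stride_start_ms)
  i1 <- time_to_index(signal, min(stride_start_ms + gc_ms, max(signal$t)))
  if (i1 - i0 < 4L) return(failed)
  seg <- x[i0:i1]
  cand <- prominent_maxima(seg, cfg$prominence_frac)
  if (!length(cand)) {
    warning("no local maximum in the stride: foot-flat/OTO absent")
    return(failed)
  }
  t_cand <- signal$t[i0 + cand - 1L]
  t_pb <- t_cand[which.min(abs(t_cand - t_pa))]  # earlier wins ties (sorted)
  if (t_pb == t_pa) {
    warning("foot-flat chord degenerate (P_A coincides with P_B)")
    return(failed)
  }
  q <- tryCatch(tta_query(signal$t, x, t_pb, t_pa), error = function(e) NULL)
  if (is.null(q)) {
    warning("foot-flat chord segment too short")
    return(failed)
  }
  t_ff <- tta_gtp(q)$T_GTP
  list(T_footflat = t_ff,
       T_OTO = t_ff + round_grid(cfg$oto_offset_frac * gc_ms, step))
}

#' Detect opposite heel strike in one stride
#'
#' After the foot-flat state the detection channel's amplitude stays near its
#' baseline until heel rise, then grows; at opposite heel strike (OHS) the
#' slope breaks upward as the foot shifts to high-rotation motion. The chord
#' is anchored at `P_A`, the first sample after foot-flat whose amplitude
#' exceeds the channel threshold for two consecutive samples (a debounce
#' against noise), and at `P_B`, the channel's extreme value (maximum, or
#' minimum for `A_y`) before toe off. The OHS is the gradient turning point
#' between them.
#'
#' @param signal A [foot_motion_signal()].
#' @param T_footflat,T_TO Foot-flat and toe-off times (ms) of the stride.
#' @param cfg A [detection_config()].
#' @return The OHS timestamp in ms, or `NA` when the threshold is never
#'   crossed before toe off.
#' @export
detect_ohs <- function(signal, T_footflat, T_TO, cfg = detection_config()) {
  x <- get_channel(signal, cfg$channel)
  i_ff <- time_to_index(signal, T_footflat)
  i_to <- time_to_index(signal, T_TO)
  if (i_to - i_ff < 4L) return(NA_real_)
  idx <- (i_ff + 1L):i_to
  amp <- switch(cfg$channel,
    Gx = abs(x[idx]),
    Az = abs(x[idx]),
    Ay = {
      base_end <- min(i_ff + max(3L, round((i_to - i_ff) / 5)), i_to)
      baseline <- mean(x[i_ff:base_end])
      abs(x[idx] - baseline)
    })
  thr <- switch(cfg$channel, Gx = cfg$thr_Gx, Az = cfg$thr_Az, Ay = cfg$thr_Ay)
  over <- amp >= thr
  sustained <- which(over & c(over[-1L], FALSE))
  if (!length(sustained)) {
    warning("amplitude never exceeded the threshold before toe off: OHS absent")
    return(NA_real_)
  }
  i_pa <- idx[sustained[1L]]
  rest <- idx[idx > i_pa]
  if (length(rest) < 2L) return(NA_real_)
  i_pb <- if (cfg$channel == "Ay") rest[which.min(x[rest])] else rest[which.max(x[rest])]
  q <- tryCatch(tta_query(signal$t, x, signal$t[i_pa], signal$t[i_pb]),
                error = function(e) NULL)
  if (is.null(q)) return(NA_real_)
  tta_gtp(q)$T_GTP
}

#' Detect all gait events in a trial
#'
#' Chains the per-event detectors over a whole trial: heel strikes establish
#' strides; each stride's gait-cycle duration (taken causally from the
#' preceding heel-strike pair) anchors foot-flat and opposite toe off; toe off
#' comes from the W-pattern; opposite heel strike from the amplitude-threshold
#' chord. The first stride has no preceding cycle and reports only its heel
#' strikes. One corrupted stride never aborts the trial: its events are `NA`
#' and the remaining strides are unaffected.
#'
#' @param signal A [foot_motion_signal()].
#' @param cfg A [detection_config()].
#' @return A data frame of class `gait_events`, one row per stride, with
#'   columns `stride_index`, `T_HS`, `T_footflat`, `T_OTO`, `T_OHS`, `T_TO`,
#'   `T_HS_next`, `T_OHS_next`, `T_OTO_next` (ms; `NA` when absent).
#' @export
detect_all_events <- function(signal, cfg = detection_config()) {
  empty <- data.frame(stride_index = integer(0), T_HS = numeric(0),
                      T_footflat = numeric(0), T_OTO = numeric(0),
                      T_OHS = numeric(0), T_TO = numeric(0),
                      T_HS_next = numeric(0), T_OHS_next = numeric(0),
                      T_OTO_next = numeric(0))
  class(empty) <- c("gait_events", "data.frame")
  hs <- detect_hs(signal, cfg)
  if (length(hs) < 2L) return(empty)
  strides <- suppressWarnings(segment_strides(signal, hs))
  to <- detect_to(signal, hs, cfg)
  n <- nrow(strides)
  ff <- oto <- ohs <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i == 1L) next  # no preceding cycle to establish gc_ms
    res <- tryCatch(
      detect_footflat_and_oto(signal, strides$start_ms[i],
                              strides$gc_ms[i - 1L], cfg),
      error = function(e) list(T_footflat = NA_real_, T_OTO = NA_real_))
    ff[i] <- res$T_footflat
    oto[i] <- res$T_OTO
    if (!is.na(ff[i]) && !is.na(to[i])) {
      ohs[i] <- tryCatch(detect_ohs(signal, ff[i], to[i], cfg),
                         error = function(e) NA_real_)
    }
  }
  out <- data.frame(stride_index = strides$index,
                    T_HS = strides$start_ms,
                    T_footflat = ff, T_OTO = oto, T_OHS = ohs, T_TO = to,
                    T_HS_next = strides$end_ms,
                    T_OHS_next = c(ohs[-1L], NA_real_),
                    T_OTO_next = c(oto[-1L], NA_real_))
  class(out) <- c("gait_events", "data.frame")
  out
}
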