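#' Specify a synthetic gait trial
#'
#' Parameters of the seedable gait simulator. The waveforms are
#' piecewise-linear templates that guarantee exactly the morphological
#' features the detectors rely on — a sharp `A_y` valley beside the pre-impact
#' maximum at heel strike, a W-shaped `A_y` pattern whose first valley marks
#' toe off, `G_x` settling to baseline with a concave gradient corner at
#' foot-flat, and a `G_x` slope break (low- to high-rotation motion) at
#' opposite heel strike — and nothing more; they are not a biomechanical
#' simulation.
#'
#' Timing defaults encode canonical healthy gait: stance occupies 60% of the
#' gait cycle, foot-flat ~8%, opposite toe off ~10% (foot-flat + 2%), opposite
#' heel strike ~50%, a median cycle of 1070 ms with 30 ms stride-to-stride
#' variability. All event times are snapped to the sample grid.
#'
#' Asymmetry: `asym_ta` shifts the opposite-heel-strike phase by a constant
#' solved from the stance-time symmetry index; `asym_tr` adds a per-stride
#' linear drift of that phase (delta = `s * gc / (1 - s/2)` per stride), which
#' makes every left stride time exceed the right by exactly `delta`, so the
#' programmed stride-time symmetry index holds stride by stride. The phase
#' path is auto-centred in its admissible band; a path that cannot fit raises
#' an error.
#'
#' @param n_strides Number of strides (the trial carries `n_strides + 1` heel
#'   strikes).
#' @param gc_ms Mean gait-cycle duration in ms.
#' @param gc_sd_ms Stride-to-stride SD of the cycle duration in ms (0 gives
#'   deterministic timing).
#' @param sample_rate Sampling frequency in Hz.
#' @param stance_frac,footflat_frac,ohs_frac Event phases as fractions of the
#'   gait cycle.
#' @param oto_offset_frac Opposite toe off trails foot-flat by this fraction.
#' @param hr_lead_frac Heel-rise onset precedes opposite heel strike by this
#'   fraction (the start of the low-rotation `G_x` ramp).
#' @param asym_tr,asym_ta Programmed symmetry indexes of stride time and
#'   stance time (signed fractions; 0 = symmetric).
#' @param slope_low,slope_high `G_x` slopes (deg/s per ms) before and after
#'   opposite heel strike; the upward break requires
#'   `slope_high > slope_low >= 0`.
#' @param noise_sd Additive Gaussian noise per channel, as a fraction of the
#'   channel's peak amplitude (0 = noise-free template).
#' @param smooth_window Moving-average window (samples) applied after noise
#'   injection; noise-free templates are already piecewise smooth and are not
#'   filtered.
#' @param lead_ms,tail_ms Signal padding before the first and after the last
#'   heel strike.
#' @param amplitudes Optional named list overriding template amplitudes:
#'   `gx_hs` (100 deg/s), `gx_swing_min` (-250), `ay_valley` (-1 g),
#'   `ay_peak` (1.5), `ay_to_valley` (-0.8), `az_hs_peak` (2.2 g),
#'   `az_to_peak` (2).
#' @param seed Integer seed; every random draw in the generator flows from it.
#' @return A list of class `gait_spec`.
#' @export
gait_spec <- function(n_strides = 10L, gc_ms = 1070, gc_sd_ms = 30,
                      sample_rate = 100,
                      stance_frac = 0.60, footflat_frac = 0.08,
                      oto_offset_frac = 0.02, ohs_frac = 0.50,
                      hr_lead_frac = 0.10,
                      asym_tr = 0, asym_ta = 0,
                      slope_low = 0.6, slope_high = 3.0,
                      noise_sd = 0, smooth_window = 3L,
                      lead_ms = 200, tail_ms = 200,
                      amplitudes = list(), seed = 1L) {
  amp <- utils::modifyList(
    list(gx_hs = 100, gx_swing_min = -250, ay_valley = -1, ay_peak = 1.5,
         ay_to_valley = -0.8, az_hs_peak = 2.2, az_to_peak = 2),
    amplitudes)
  stopifnot(n_strides >= 1L, gc_ms >= 700, gc_sd_ms >= 0, sample_rate > 0,
            noise_sd >= 0, smooth_window >= 1L,
            lead_ms >= 100, tail_ms >= 100,
            abs(asym_tr) < 0.5, abs(asym_ta) < 0.5)
  if (!(0 < footflat_frac && footflat_frac < footflat_frac + oto_offset_frac &&
        footflat_frac + oto_offset_frac < ohs_frac &&
        ohs_frac < stance_frac && stance_frac < 1))
    stop("event phases must satisfy 0 < footflat < oto < ohs < stance < 1")
  if (!(slope_high > slope_low && slope_low >= 0))
    stop("slopes must satisfy slope_high > slope_low >= 0")
  structure(list(n_strides = as.integer(n_strides), gc_ms = gc_ms,
                 gc_sd_ms = gc_sd_ms, sample_rate = sample_rate,
                 stance_frac = stance_frac, footflat_frac = footflat_frac,
                 oto_offset_frac = oto_offset_frac, ohs_frac = ohs_frac,
                 hr_lead_frac = hr_lead_frac,
                 asym_tr = asym_tr, asym_ta = asym_ta,
                 slope_low = slope_low, slope_high = slope_high,
                 noise_sd = noise_sd, smooth_window = as.integer(smooth_window),
                 lead_ms = lead_ms, tail_ms = tail_ms,
                 amplitudes = amp, seed = as.integer(seed)),
            class = "gait_spec")
}

# The admissible band for the OHS phase: heel rise must start after opposite
# toe off, and the slope break must sit clear of the toe-off peak.
ohs_phase_band <- function(spec) {
  c(lo = spec$footflat_frac + spec$oto_offset_frac + spec$hr_lead_frac + 0.01,
    hi = spec$stance_frac - 0.04)
}

# Per-stride OHS phase path implementing the programmed asymmetry. The base
# phase is solved from the stance-time symmetry index on grid-snapped
# quantities (the opposite foot's stance runs from this stride's OHS to the
# next stride's OTO), so the programmed index survives the sample grid.
ohs_phase_path <- function(spec) {
  n <- spec$n_strides
  s_ta <- spec$asym_ta
  step <- 1000 / spec$sample_rate
  gc0 <- round_grid(spec$gc_ms, step)
  oto_rel0 <- round_grid(spec$footflat_frac * gc0, step) +
    round_grid(spec$oto_offset_frac * gc0, step)
  sta_r0 <- round_grid(spec$stance_frac * gc0, step)
  sta_l_target <- sta_r0 * (1 + s_ta / 2) / (1 - s_ta / 2)
  f_base <- (gc0 + oto_rel0 - sta_l_target) / gc0
  delta <- spec$asym_tr / (1 - spec$asym_tr / 2)
  f <- f_base + (seq_len(n) - (n + 1) / 2) * delta
  band <- ohs_phase_band(spec)
  span <- diff(range(f))
  if (span > band["hi"] - band["lo"])
    stop("programmed asymmetry drift does not fit the gait cycle: ",
         "reduce n_strides or |asym_tr|")
  if (max(f) > band["hi"]) f <- f - (max(f) - band["hi"])
  if (min(f) < band["lo"]) f <- f + (band["lo"] - min(f))
  unname(f)
}

# Ground-truth event timetable (ms, on the sample grid). Called inside
# with_seed(): draws the per-stride cycle durations.
build_ground_truth <- function(spec) {
  step <- 1000 / spec$sample_rate
  rg <- function(x) round_grid(x, step)
  n <- spec$n_strides
  gc <- if (spec$gc_sd_ms > 0) {
    pmax(rg(stats::rnorm(n, spec$gc_ms, spec$gc_sd_ms)), rg(0.7 * spec$gc_ms))
  } else {
    rep(rg(spec$gc_ms), n)
  }
  f <- ohs_phase_path(spec)
  hs <- rg(spec$lead_ms) + c(0, cumsum(gc))
  t_ff <- hs[-(n + 1)] + rg(spec$footflat_frac * gc)
  t_oto <- t_ff + rg(spec$oto_offset_frac * gc)
  t_ohs <- hs[-(n + 1)] + rg(f * gc)
  t_hr <- t_ohs - rg(spec$hr_lead_frac * gc)
  t_to <- hs[-(n + 1)] + rg(spec$stance_frac * gc)
  out <- data.frame(stride_index = seq_len(n), gc_ms = gc,
                    T_HS = hs[-(n + 1)], T_footflat = t_ff, T_OTO = t_oto,
                    T_OHS = t_ohs, T_TO = t_to, T_heelrise = t_hr,
                    T_HS_next = hs[-1L],
                    T_OHS_next = c(t_ohs[-1L], NA_real_),
                    T_OTO_next = c(t_oto[-1L], NA_real_))
  stopifnot(all(out$T_HS < out$T_footflat),
            all(out$T_footflat < out$T_OTO),
            all(out$T_OTO < out$T_heelrise),
            all(out$T_heelrise < out$T_OHS),
            all(out$T_OHS < out$T_TO),
            all(out$T_TO < out$T_HS_next))
  out
}

# Append breakpoints, keeping t strictly increasing (later conflicting points
# are dropped; breakpoints are listed in intended temporal order).
add_points <- function(pts, t, v) {
  keep <- rep(TRUE, length(t))
  last <- if (nrow(pts)) pts$t[nrow(pts)] else -Inf
  for (j in seq_along(t)) {
    if (t[j] > last) last <- t[j] else keep[j] <- FALSE
  }
  rbind(pts, data.frame(t = t[keep], v = v[keep]))
}

#' Generate a synthetic gait trial with ground truth
#'
#' Builds the foot-motion waveforms for the timetable implied by the spec and
#' returns them together with the exact programmed event times. Two calls
#' with the same spec produce bit-identical output.
#'
#' @param spec A [gait_spec()].
#' @return A list of class `gait_trial`: `signal` (a [foot_motion_signal()]),
#'   `truth` (the ground-truth event table, one row per stride, same columns
#'   as [detect_all_events()] output plus `gc_ms` and `T_heelrise`) and
#'   `gpbll` (the true parameter table from [compute_gpbll_table()]).
#' @export
generate_trial <- function(spec) {
  stopifnot(inherits(spec, "gait_spec"))
  with_seed(spec$seed, {
    gt <- build_ground_truth(spec)
    step <- 1000 / spec$sample_rate
    rg <- function(x) round_grid(x, step)
    amp <- spec$amplitudes
    n <- spec$n_strides
    total <- gt$T_HS_next[n] + rg(spec$tail_ms)
    grid <- seq(0, total, by = step)

    ay <- data.frame(t = numeric(0), v = numeric(0))
    az <- ay; gx <- ay
    r1 <- gt$T_HS[1]
    # lead-in: quiet signal ending in the pre-impact A_y spike
    ay <- add_points(ay, c(0, r1 - 60, r1 - 30), c(0, 0, amp$ay_peak))
    az <- add_points(az, c(0, r1 - 30), c(1, 1))
    gx <- add_points(gx, c(0, r1 - 30), c(0, 0))

    for (i in seq_len(n)) {
      hs <- gt$T_HS[i]; gc <- gt$gc_ms[i]
      ff <- gt$T_footflat[i]; hr <- gt$T_heelrise[i]
      ohs <- gt$T_OHS[i]; to <- gt$T_TO[i]; nxt <- gt$T_HS_next[i]
      # A_y: HS valley, recovery, quiet stance, OHS ramp, W pattern at TO,
      # quiet swing, pre-impact spike for the next HS
      ay <- add_points(ay,
        c(hs, hs + 20, hs + 50, ff, hr, ohs, to - 40, to, to + 40, to + 80,
          to + 130, nxt - 60, nxt - 30),
        c(amp$ay_valley, 0.6, 0.2, 0, 0, -0.2, -0.2, amp$ay_to_valley, -0.2,
          -0.6, 0, 0, amp$ay_peak))
      # G_x: post-HS plantarflexion pulse settling at foot-flat (concave
      # corner), baseline, low-rotation ramp from heel rise, slope break at
      # OHS, peak at TO, swing dip, return to baseline at the next HS
      v1 <- spec$slope_low * (ohs - hr)
      v2 <- v1 + spec$slope_high * (to - ohs)
      gx <- add_points(gx,
        c(hs, hs + max(step, rg(0.02 * gc)), ff, hr, ohs, to,
          to + rg(0.2 * gc), nxt),
        c(0, amp$gx_hs, 0, 0, v1, v2, amp$gx_swing_min, 0))
      # A_z: impact spike over the 1 g baseline, settle at foot-flat,
      # push-off rise breaking at OHS, peak at TO, swing dip
      az <- add_points(az,
        c(hs, hs + 10, ff, hr, ohs, to, to + 60, to + 140),
        c(1, amp$az_hs_peak, 1, 1, 1.3, amp$az_to_peak, 0.4, 1))
    }
    last <- gt$T_HS_next[n]
    ay <- add_points(ay, c(last, last + 20, last + 50, last + 80, total),
                     c(amp$ay_valley, 0.6, 0.2, 0, 0))
    gx <- add_points(gx, c(last, last + 20, last + 90, total),
                     c(0, amp$gx_hs, 0, 0))
    az <- add_points(az, c(last, last + 10, last + 90, total),
                     c(1, amp$az_hs_peak, 1, 1))

    interp <- function(pts) stats::approx(pts$t, pts$v, xout = grid, rule = 2)$y
    ch <- list(A_y = interp(ay), A_z = interp(az), G_x = interp(gx))
    ch$A_x <- rep(0, length(grid))
    ch$G_y <- rep(0, length(grid))
    ch$G_z <- rep(0, length(grid))
    if (spec$noise_sd > 0) {
      for (nm in names(ch)) {
        peak <- max(abs(ch[[nm]]), 1e-9)
        ref_peak <- if (peak > 1e-9) peak else 1
        ch[[nm]] <- ch[[nm]] + stats::rnorm(length(grid), 0,
                                            spec$noise_sd * ref_peak)
        ch[[nm]] <- moving_average(ch[[nm]], spec$smooth_window)
      }
    }
    signal <- foot_motion_signal(t = grid, sample_rate = spec$sample_rate,
                                 A_x = ch$A_x, A_y = ch$A_y, A_z = ch$A_z,
                                 G_x = ch$G_x, G_y = ch$G_y, G_z = ch$G_z,
                                 side = "right")
    structure(list(signal = signal, truth = gt,
                   gpbll = compute_gpbll_table(gt), spec = spec),
              class = "gait_trial")
  })
}

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf("<gait_trial> %d strides, gc ~ %g ms, noise %g, seed %d\n",
              x$spec$n_strides, x$spec$gc_ms, x$spec$noise_sd, x$spec$seed))
  print(x$signal)
  invisible(x)
}

#' Generate paired two-system measurements from ground truth
#'
#' Emulates a method comparison: the programmed ground-truth values of one
#' parameter act as the reference system, and a jittered copy (seeded
#' Gaussian measurement error, optionally proportional to the value, snapped
#' to the sample grid for time-valued parameters) acts as the test system.
#' The result is realistically tied, discrete paired data for the agreement
#' pipeline.
#'
#' @param spec A [gait_spec()]; `n_strides` sets the number of pairs (one
#'   fewer for parameters that span into the next stride).
#' @param jitter_sd_ms SD of the measurement error (ms for time parameters,
#'   index units for symmetry indexes).
#' @param parameter `"T_OHS_0"`, `"T_OTO_0"` (relative event times) or any
#'   column of the gait-parameter table (`"DSTt"`, `"SIS_tr"`, ...).
#' @param jitter_prop Proportional error: the test value is scaled by
#'   `1 + jitter_prop` before noise, inducing a proportional bias.
#' @return A [paired_measurements()].
#' @export
generate_paired_measurements <- function(spec, jitter_sd_ms = 0,
                                         parameter = "T_OHS_0",
                                         jitter_prop = 0) {
  stopifnot(inherits(spec, "gait_spec"))
  step <- 1000 / spec$sample_rate
  with_seed(spec$seed, {
    gt <- build_ground_truth(spec)
    is_time <- parameter %in% c("T_OHS_0", "T_OTO_0", "DST1", "DST2", "DSTt",
                                "T_str_L", "T_str_R", "T_sta_L", "T_sta_R")
    ref <- switch(parameter,
      T_OHS_0 = gt$T_OHS - gt$T_HS,
      T_OTO_0 = gt$T_OTO - gt$T_HS,
      {
        tab <- compute_gpbll_table(gt)
        if (!parameter %in% names(tab))
          stop("unknown parameter: ", parameter)
        tab[[parameter]]
      })
    test <- ref * (1 + jitter_prop) +
      stats::rnorm(length(ref), 0, jitter_sd_ms)
    if (is_time) test <- round_grid(test, step)
    paired_measurements(ref, test, label = parameter)
  })
}
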