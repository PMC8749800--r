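# A tiny hand-built signal with heel-strike signatures only: spike-and-valley
# pairs in A_y at the given times, flat elsewhere (no W pattern, no G_x ramp).
flat_swing_signal <- function(hs_times, rate = 100) {
  total <- max(hs_times) + 300
  t <- seq(0, total, by = 1000 / rate)
  ay <- rep(0, length(t))
  gx <- rep(0, length(t))
  for (h in hs_times) {
    ay[t == h - 30] <- 1.5
    ay[t == h - 20] <- 0.7
    ay[t == h - 10] <- -0.2
    ay[t == h] <- -1
    ay[t == h + 10] <- -0.3
    ay[t == h + 20] <- 0.2
  }
  foot_motion_signal(t = t, sample_rate = rate, A_y = ay, G_x = gx)
}

test_that("noise-free detection reproduces every programmed event exactly", {
  tr <- generate_trial(exact_spec(n_strides = 10, seed = 1))
  ev <- detect_all_events(tr$signal)
  expect_equal(nrow(ev), 10L)
  i <- 2:9
  for (col in event_cols) {
    expect_equal(ev[[col]][i], tr$truth[[col]][i], info = col)
  }
  # ordering invariant on every complete stride
  cmp <- ev[i, ]
  expect_true(all(cmp$T_HS < cmp$T_footflat))
  expect_true(all(cmp$T_footflat <= cmp$T_OTO))
  expect_true(all(cmp$T_OTO < cmp$T_OHS))
  expect_true(all(cmp$T_OHS < cmp$T_TO))
  expect_true(all(cmp$T_TO < cmp$T_HS_next))
})

test_that("opposite toe off trails foot-flat by exactly 2% of the cycle", {
  tr <- generate_trial(gait_spec(n_strides = 10, seed = 4))  # variable timing
  ev <- detect_all_events(tr$signal)
  st <- segment_strides(tr$signal, detect_hs(tr$signal))
  for (i in 2:nrow(ev)) {
    if (is.na(ev$T_OTO[i])) next
    expect_equal(ev$T_OTO[i] - ev$T_footflat[i],
                 round(0.02 * st$gc_ms[i - 1] / 10) * 10)
  }
})

test_that("degenerate signals yield empty or absent events, not errors", {
  # constant-zero A_y: no heel strikes at all
  z <- foot_motion_signal(A_y = rep(0, 500), G_x = rep(0, 500))
  expect_length(detect_hs(z), 0)
  expect_equal(nrow(detect_all_events(z)), 0L)
  # heel strikes present but flat swing: no W pattern, so no toe off
  s <- flat_swing_signal(c(500, 1500, 2500))
  hs <- detect_hs(s)
  expect_equal(hs, c(500, 1500, 2500))
  expect_true(all(is.na(detect_to(s, hs))))
})

test_that("a rotation ramp that never crosses the threshold yields no OHS", {
  spec <- exact_spec(n_strides = 6, slope_low = 0, slope_high = 0.25, seed = 5)
  tr <- generate_trial(spec)
  ev <- suppressWarnings(detect_all_events(tr$signal))
  expect_true(all(is.na(ev$T_OHS)))
  # the earlier events are still produced
  expect_false(anyNA(ev$T_footflat[2:5]))
})

test_that("one corrupted stride leaves the remaining strides untouched", {
  tr <- generate_trial(exact_spec(n_strides = 10, seed = 6))
  clean <- detect_all_events(tr$signal)
  sig <- tr$signal
  i0 <- which(sig$t == tr$truth$T_HS[5]) + 3
  i1 <- which(sig$t == tr$truth$T_HS_next[5]) - 3
  sig$G_x[i0:i1] <- 0   # no foot-flat corner, no ramp in stride 5
  ev <- suppressWarnings(detect_all_events(sig))
  others <- c(2:4, 7:9)
  for (col in c("T_footflat", "T_OTO", "T_OHS")) {
    expect_equal(ev[[col]][others], clean[[col]][others], info = col)
  }
})

test_that("detection stays accurate under measurement noise (Monte-Carlo)", {
  tr <- generate_trial(gait_spec(n_strides = 200, noise_sd = 0.05, seed = 7))
  ev <- suppressWarnings(detect_all_events(tr$signal))
  expect_equal(nrow(ev), 200L)
  med_err <- function(col) {
    median(abs(ev[[col]] - tr$truth[[col]]), na.rm = TRUE)
  }
  expect_lte(med_err("T_HS"), 10)
  expect_lte(med_err("T_TO"), 10)
  expect_lte(med_err("T_OTO"), 10)
  expect_lte(med_err("T_OHS"), 15)
  # the vast majority of strides still produce every event
  expect_gte(sum(complete.cases(ev[2:199, event_cols])), 180)
})

test_that("the A_z channel also recovers foot-flat and OHS on clean signals", {
  tr <- generate_trial(exact_spec(n_strides = 8, seed = 8))
  ev <- detect_all_events(tr$signal, detection_config(channel = "Az"))
  i <- 2:7
  expect_equal(ev$T_footflat[i], tr$truth$T_footflat[i])
  expect_equal(ev$T_OHS[i], tr$truth$T_OHS[i])
})
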