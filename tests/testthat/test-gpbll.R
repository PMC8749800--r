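test_that("relative event times are simple offsets from the reference heel strike", {
  expect_equal(relative_times(list(T_OHS = 1560, T_OTO = 1120), 1000),
               list(T_OHS_0 = 560, T_OTO_0 = 120))
  expect_equal(relative_times(list(T_OHS = 1000, T_OTO = NA_real_), 1000)$T_OHS_0, 0)
  expect_true(is.na(relative_times(list(T_OTO = 5), 0)$T_OHS_0))
})

test_that("the nine parameters come out right on a hand-built stride", {
  ev <- list(T_HS = 0, T_OTO = 100, T_OHS = 500, T_TO = 665,
             T_HS_next = 1070, T_OHS_next = 1570, T_OTO_next = 1150)
  rec <- compute_gpbll(ev)
  expect_equal(rec$DST1, 100)          # T_OTO - T_HS
  expect_equal(rec$DST2, 165)          # T_TO - T_OHS
  expect_equal(rec$DSTt, 265)
  expect_equal(rec$T_sta_L, 650)       # next OTO - OHS
  expect_equal(rec$T_sta_R, 665)       # T_TO - T_HS
  expect_equal(rec$T_str_L, 1070)
  expect_equal(rec$T_str_R, 1070)
  expect_equal(rec$SIS_ta, (650 - 665) / (0.5 * (650 + 665)))
  expect_equal(rec$SIS_ta, -0.02281369, tolerance = 1e-6)
  expect_equal(rec$SIS_tr, 0)
  # a missing event voids the record with a reason
  ev$T_OHS_next <- NA_real_
  expect_warning(expect_null(compute_gpbll(ev)), "T_OHS_next")
})

test_that("swapping the limbs negates the symmetry indexes", {
  ev <- list(T_HS = 0, T_OTO = 100, T_OHS = 480, T_TO = 665,
             T_HS_next = 1070, T_OHS_next = 1590, T_OTO_next = 1150)
  rec <- compute_gpbll(ev)
  # exchange the left/right stance and stride durations directly
  sis <- function(l, r) (l - r) / (0.5 * (l + r))
  expect_equal(sis(rec$T_sta_R, rec$T_sta_L), -rec$SIS_ta)
  expect_equal(sis(rec$T_str_R, rec$T_str_L), -rec$SIS_tr)
  # generator-level: negating the programmed asymmetry negates the truth index
  a <- generate_trial(exact_spec(n_strides = 6, asym_tr = 0.04, seed = 9))
  b <- generate_trial(exact_spec(n_strides = 6, asym_tr = -0.04, seed = 9))
  expect_lt(abs(mean(a$gpbll$SIS_tr) + mean(b$gpbll$SIS_tr)), 0.002)
})

test_that("total double support is conserved as the sum of its phases", {
  tr <- generate_trial(gait_spec(n_strides = 30, noise_sd = 0.03, seed = 10))
  tab <- compute_gpbll_table(suppressWarnings(detect_all_events(tr$signal)))
  expect_gt(nrow(tab), 10)
  expect_equal(tab$DSTt, tab$DST1 + tab$DST2)
  # symmetric programming keeps the indexes centred on zero; per-stride
  # values fluctuate with the natural stride-time variability
  expect_lt(abs(mean(tr$gpbll$SIS_tr)), 0.01)
  expect_lt(max(abs(tr$gpbll$SIS_tr)), 0.06)
  # with deterministic timing the per-stride index is within two samples
  det <- generate_trial(exact_spec(n_strides = 8, seed = 10))
  expect_lt(max(abs(det$gpbll$SIS_tr)), 2 * 10 / 1000)
})

test_that("averaging runs of consecutive strides behaves like a mean", {
  rec <- data.frame(stride_index = 1:5, DSTt = c(200, 210, 220, 230, 240),
                    SIS_tr = rep(0.02, 5))
  out <- average_records(rec, k = 5)
  expect_equal(nrow(out), 1L)
  expect_equal(out$DSTt, 220)
  expect_equal(out$SIS_tr, 0.02)
  # five identical records average to themselves
  same <- data.frame(stride_index = 1:5, DSTt = rep(250, 5))
  expect_equal(average_records(same, k = 5)$DSTt, 250)
  # k = 1 is the identity on the parameter columns
  expect_equal(average_records(rec, k = 1)$DSTt, rec$DSTt)
  # fewer than k records yields an empty table
  expect_equal(nrow(average_records(rec[1:3, ], k = 5)), 0L)
  # a gap in stride_index breaks the run
  gap <- rec; gap$stride_index <- c(1, 2, 3, 7, 8)
  expect_equal(nrow(average_records(gap, k = 5)), 0L)
  # averaging commutes with the DSTt = DST1 + DST2 identity
  tab <- data.frame(stride_index = 1:10, DST1 = 100 + 1:10,
                    DST2 = 120 - 1:10)
  tab$DSTt <- tab$DST1 + tab$DST2
  avg <- average_records(tab, k = 5)
  expect_equal(avg$DSTt, avg$DST1 + avg$DST2)
})
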