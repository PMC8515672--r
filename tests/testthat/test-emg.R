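test_that("preprocessing rejects bad cutoffs and produces non-negative envelopes", {
  rec <- emg_record(matrix(0, 1000, 1, dimnames = list(NULL, "ch")), 1000)
  expect_error(preprocess_emg(rec, highpass_hz = 600), "Nyquist")
  env <- preprocess_emg(rec)
  expect_true(all(env$signals == 0))
  set.seed(3)
  rec2 <- emg_record(matrix(rnorm(2000), 2000, 1,
                            dimnames = list(NULL, "ch")), 1000)
  env2 <- preprocess_emg(rec2)
  expect_true(all(env2$signals >= 0))
})

test_that("the 100-Hz high-pass suppresses a 50-Hz tone by more than 90%", {
  t <- seq(0, 0.999, by = 1e-3)
  tone <- sin(2 * pi * 50 * t) * 100
  rec <- emg_record(matrix(tone, ncol = 1, dimnames = list(NULL, "m")), 1000)
  raw_rms <- sqrt(mean(tone^2))
  env <- preprocess_emg(rec, highpass_hz = 100)
  # compare steady-state envelope (clip filter edge transients)
  mid <- 200:800
  expect_lt(mean(env$signals[mid, 1]), 0.1 * raw_rms)
})

test_that("burst detection recovers generated windows within 5 ms", {
  truth <- simulate_jaw_motion(motion_spec(n_cycles = 3))
  emg <- synth_emg(truth, seed = 21)
  env <- preprocess_emg(emg)
  bursts <- detect_bursts(env)
  win <- attr(emg, "burst_windows_emg_ms")
  for (ch in unique(win$channel)) {
    det <- bursts$bursts[bursts$bursts$channel == ch, ]
    tw <- win[win$channel == ch, ]
    expect_identical(nrow(det), nrow(tw))
    expect_true(all(abs(det$onset_ms - tw$onset_ms) <= 5))
    expect_true(all(abs(det$offset_ms - tw$offset_ms) <= 5))
  }
})

test_that("close bursts merge and flat baselines fall back with a flag", {
  # hand-built envelope: two 20-ms bursts separated by 5 ms
  v <- numeric(600)
  v[101:120] <- 10
  v[126:145] <- 10
  env <- emg_record(matrix(v + 0.01 * sin(seq_len(600)), ncol = 1,
                           dimnames = list(NULL, "m")), 1000)
  class(env) <- c("emg_envelope", class(env))
  b <- detect_bursts(env, baseline_window_ms = 80, k_sd = 3,
                     min_duration_ms = 10)
  expect_identical(nrow(b$bursts), 1L)
  expect_lt(b$bursts$onset_ms, 105)
  expect_gt(b$bursts$offset_ms, 140)
  # exactly-zero baseline triggers the global-SD fallback
  env0 <- emg_record(matrix(v, ncol = 1, dimnames = list(NULL, "m")), 1000)
  class(env0) <- c("emg_envelope", class(env0))
  b0 <- detect_bursts(env0, baseline_window_ms = 80)
  expect_true(b0$baseline_flagged[["m"]])
  expect_identical(nrow(b0$bursts), 1L)
})

test_that("frame alignment arithmetic and synchronization offsets", {
  bs <- structure(list(
    bursts = data.frame(channel = "m", onset_ms = 25, offset_ms = 100),
    parameters = list(), baseline_flagged = c(m = FALSE),
    sync_offset_ms = 0), class = "burst_set")
  al <- align_to_frames(bs, 200)
  # 0-based frames 5 and 20 (1-based indices 6 and 21)
  expect_identical(al$onset_frame, 6L)
  expect_identical(al$offset_frame, 21L)
  al5 <- align_to_frames(bs, 200, sync_offset_ms = 5)
  expect_identical(al5$onset_frame, al$onset_frame - 1L)
  expect_identical(al5$offset_frame, al$offset_frame - 1L)
  # negative aligned time clips to the first frame and flags
  alneg <- align_to_frames(bs, 200, sync_offset_ms = 50)
  expect_identical(alneg$onset_frame, 1L)
  expect_true(alneg$clipped)
})

test_that("masseter onset ordering and contact coincidence on synthetic data", {
  b <- synth_bundle(motion_spec(n_cycles = 3))
  emg <- synth_emg(b$truth, seed = 31)
  env <- preprocess_emg(emg)
  al <- align_to_frames(detect_bursts(env), 200)
  occl <- contact_series(b$pose_series, b$maxilla_pose, b$model)
  tb <- b$truth$phase_boundaries
  on_w <- al$onset_frame[al$channel == "masseter_working"]
  on_b <- al$onset_frame[al$channel == "masseter_balancing"]
  expect_identical(length(on_w), 3L)
  expect_true(all(on_w < on_b))
  # balancing-side onset coincides with contact onset to within a frame
  expect_true(all(abs(on_b - tb$contact_onset) <= 1))
})

test_that("digastric bursts overlap the opening phase (Jaccard >= 0.8)", {
  truth <- simulate_jaw_motion(motion_spec(n_cycles = 3))
  emg <- synth_emg(truth, seed = 41)
  al <- align_to_frames(detect_bursts(preprocess_emg(emg)), 200)
  dig <- al[al$channel == "digastric", ]
  tb <- truth$phase_boundaries
  jacc <- vapply(seq_len(nrow(tb)), function(k) {
    a <- seq(tb$max_closing[k], tb$max_opening[k])
    d <- seq(dig$onset_frame[k], dig$offset_frame[k])
    length(intersect(a, d)) / length(union(a, d))
  }, numeric(1))
  expect_true(all(jacc >= 0.8))
})
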