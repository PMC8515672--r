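test_that("degenerate motion spec yields a constant identity pose", {
  spec <- motion_spec(n_cycles = 2, gape_mm = 0, ap_excursion_mm = 0,
                      lateral_mm = 0)
  truth <- simulate_jaw_motion(spec)
  for (i in seq_len(n_frames(truth$pose_series))) {
    p <- pose_at(truth$pose_series, i)
    expect_lt(max(abs(p$rotation - diag(3))), 1e-12)
    expect_lt(max(abs(p$translation)), 1e-12)
  }
  expect_null(truth$phase_boundaries)
})

test_that("one 150-ms cycle at 200 Hz spans 30 frames, 5 ms apart", {
  truth <- simulate_jaw_motion(motion_spec(n_cycles = 1, cycle_ms = 150,
                                           frame_rate = 200))
  expect_identical(n_frames(truth$pose_series), 30L)
  expect_equal(unique(diff(truth$t_ms)), 5)
})

test_that("recorded phase boundaries equal an extrema scan of the generated molar path", {
  truth <- simulate_jaw_motion(motion_spec())
  mol <- truth$landmark_paths$molar_cusp
  F <- 30L
  for (k in seq_len(truth$spec$n_cycles)) {
    idx <- ((k - 1L) * F + 1L):(k * F)
    b <- truth$phase_boundaries[k, ]
    expect_identical(b$max_closing, idx[which.max(mol[idx, 3])])
    expect_identical(b$most_anterior, idx[which.max(mol[idx, 1])])
    expect_identical(b$max_opening, idx[which.min(mol[idx, 3])])
    post <- idx[idx >= b$max_opening]
    expect_identical(b$most_posterior, post[which.min(mol[post, 1])])
    # cyclic order of the four key timepoints
    expect_true(b$max_closing < b$most_anterior &&
                b$most_anterior < b$max_opening &&
                b$max_opening < b$most_posterior)
  }
})

test_that("condylar asymmetry: working side reverses mid-opening, balancing advances", {
  truth <- simulate_jaw_motion(motion_spec(working_side = "left"))
  open_end <- truth$phase_boundaries$max_opening[1]
  work <- truth$landmark_paths$condyle_left[1:open_end, 1]
  bal <- truth$landmark_paths$condyle_right[1:open_end, 1]
  # balancing condyle advances anteriorly through the whole opening phase
  expect_true(all(diff(bal) > -1e-9))
  # working condyle advances, then reverses before maximum opening
  peak <- which.max(work)
  expect_lt(peak, open_end)
  expect_gt(peak, 2)
  expect_lt(work[open_end], work[peak])
})

test_that("noiseless capture round-trips ground truth through pose estimation", {
  truth <- simulate_jaw_motion(motion_spec(n_cycles = 2))
  cap <- synth_capture(truth, noise_sigma_mm = 0, seed = 1)
  ps <- estimate_pose_series(cap, default_marker_geometry())
  mount <- attr(cap, "mount")
  for (i in seq_len(n_frames(ps))) {
    est <- pose_compose(pose_invert(mount), pose_at(ps, i))
    tru <- pose_at(truth$pose_series, i)
    expect_lt(max(abs(est$rotation - tru$rotation)), 1e-9)
    expect_lt(max(abs(est$translation - tru$translation)), 1e-9)
  }
})

test_that("capture generation is deterministic under a fixed seed", {
  truth <- simulate_jaw_motion(motion_spec(n_cycles = 1))
  a <- synth_capture(truth, noise_sigma_mm = 0.02, seed = 9)
  b <- synth_capture(truth, noise_sigma_mm = 0.02, seed = 9)
  expect_identical(a$coords, b$coords)
  c3 <- synth_capture(truth, noise_sigma_mm = 0.02, seed = 10)
  expect_false(identical(a$coords, c3$coords))
  expect_error(synth_capture(truth, labeled_points(
    rbind(a = c(0, 0, 0), b = c(1, 0, 0), c = c(2, 0, 0)))), "degenerate")
})

test_that("per-frame fit RMSD under noise matches the Monte-Carlo expectation", {
  truth <- simulate_jaw_motion(motion_spec(n_cycles = 5))  # 150 frames
  sigma <- 0.01
  cap <- synth_capture(truth, noise_sigma_mm = sigma, seed = 3)
  ps <- estimate_pose_series(cap, default_marker_geometry())
  # independent Monte-Carlo replicates of a single noisy 4-marker fit
  ref <- default_marker_geometry()
  set.seed(99)
  mc <- replicate(1000, {
    obs <- ref$points + matrix(stats::rnorm(12, 0, sigma), 4, 3)
    attr(fit_rigid(ref, labeled_points(obs, ref$labels)), "residual_rmsd")
  })
  expect_lt(abs(mean(ps$residual_rmsd) - mean(mc)) / mean(mc), 0.15)
})

test_that("toy dentition interdigitates with zero clearance at intercuspal pose", {
  dent <- synth_dentition(resolution_mm = 0.1)
  r <- min_clearance(dent$mandible, dent$maxilla)
  expect_lt(r$clearance_mm, 0.05)
  # lowering the mandible by 1 mm opens 1 mm of clearance
  down <- rigid_pose(diag(3), c(0, 0, -1))
  r1 <- min_clearance(dent$mandible, dent$maxilla, down)
  expect_equal(r1$clearance_mm, 1, tolerance = 0.05)
  expect_identical(sort(dent$landmarks$labels),
                   sort(c("incisor_edge", "molar_cusp", "condyle_left",
                          "condyle_right")))
  expect_identical(nrow(dent$landmarks$points), 4L)
})

test_that("synthetic EMG is silent outside bursts and locks to frame arithmetic", {
  truth <- simulate_jaw_motion(motion_spec(n_cycles = 2))
  emg <- synth_emg(truth, noise_amplitude_uv = 0, seed = 4)
  win <- attr(emg, "burst_windows_emg_ms")
  outside <- rep(TRUE, nrow(emg$signals))
  for (j in seq_len(nrow(win))) {
    ch <- win$channel[j]
    inw <- emg$t_ms >= win$onset_ms[j] & emg$t_ms <= win$offset_ms[j]
    expect_gt(max(abs(emg$signals[inw, ch])), 0)
  }
  for (ch in colnames(emg$signals)) {
    w <- win[win$channel == ch, ]
    inw <- Reduce(`|`, lapply(seq_len(nrow(w)), function(j)
      emg$t_ms >= w$onset_ms[j] & emg$t_ms <= w$offset_ms[j]))
    expect_true(all(emg$signals[!inw, ch] == 0))
  }
  # 1000 Hz sampling against 200 frames/s: exactly 5 samples per frame
  expect_equal(emg$sampling_rate / truth$pose_series$frame_rate, 5)
  # working-side onset precedes balancing-side onset in every cycle
  on_w <- win$onset_ms[win$channel == "masseter_working"]
  on_b <- win$onset_ms[win$channel == "masseter_balancing"]
  expect_true(all(on_w < on_b))
  # determinism
  e2 <- synth_emg(truth, noise_amplitude_uv = 0, seed = 4)
  expect_identical(emg$signals, e2$signals)
})

test_that("truth contact is self-consistent with generated mesh clearance", {
  b <- synth_bundle(motion_spec(n_cycles = 2))
  occl <- contact_series(b$pose_series, b$maxilla_pose, b$model,
                         threshold_mm = b$truth$contact_threshold)
  sel <- b$truth$gap_mm <= 0.06
  expect_lt(max(abs(occl$clearance_mm[sel] - b$truth$gap_mm[sel])), 1e-9)
  expect_identical(occl$contact, b$truth$contact)
  # every occlusal portion (contact onset to cycle end) is in contact
  for (k in seq_len(nrow(b$truth$phase_boundaries))) {
    on <- b$truth$phase_boundaries$contact_onset[k]
    end <- k * 30L
    expect_true(all(b$truth$contact[on:end]))
  }
})
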