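truth_occlusion <- function(truth) {
  occlusion_series(truth$gap_mm, truth$contact_threshold,
                   truth$spec$frame_rate)
}

truth_molar <- function(truth) {
  trajectory(truth$landmark_paths$molar_cusp, "molar_cusp",
             truth$spec$frame_rate)
}

test_that("key timepoints recover generator truth across a parameter sweep", {
  for (gape in c(1, 2, 3))
    for (ap in c(0.8, 1.5, 2.2))
      for (cyc in c(100, 150, 250)) {
        spec <- motion_spec(n_cycles = 3, cycle_ms = cyc, gape_mm = gape,
                            ap_excursion_mm = ap, seed = 1L)
        truth <- simulate_jaw_motion(spec)
        seg <- detect_key_timepoints(truth_molar(truth),
                                     truth_occlusion(truth))
        tb <- truth$phase_boundaries
        expect_identical(nrow(seg$timepoints), nrow(tb))
        for (col in c("max_closing", "most_anterior", "max_opening",
                      "most_posterior"))
          expect_true(all(abs(seg$timepoints[[col]] - tb[[col]]) <= 1),
                      label = sprintf("%s (gape %g ap %g cyc %g)", col,
                                      gape, ap, cyc))
        # phases partition each cycle without gap or overlap
        for (k in seq_len(nrow(seg$timepoints))) {
          ph <- seg$phases[seg$phases$cycle == k, ]
          expect_identical(ph$start_frame[-1], ph$end_frame[-3])
          expect_identical(ph$start_frame[1], seg$cycle_delimiters[k])
          expect_identical(ph$end_frame[3], seg$cycle_delimiters[k + 1])
        }
      }
})

test_that("occlusal phase starts at contact onset and is flagged consistent", {
  truth <- simulate_jaw_motion(motion_spec())
  seg <- detect_key_timepoints(truth_molar(truth), truth_occlusion(truth))
  occl_rows <- seg$phases[seg$phases$phase == "occlusal", ]
  expect_identical(occl_rows$start_frame, truth$phase_boundaries$contact_onset)
  expect_true(all(seg$timepoints$consistent))
})

test_that("pure vertical motion is segmented but flagged degenerate", {
  # hand-built open-close with no antero-posterior component at all
  n <- 61
  z <- cos(2 * pi * (seq_len(n) - 1) / 30)
  tr <- trajectory(cbind(0, 0, z), "molar_cusp", 200)
  occl <- occlusion_series(max(z) - z, 0.05, 200)
  seg <- detect_key_timepoints(tr, occl)
  expect_true(seg$degenerate_ap)
  # ties broken to the earliest frame: most_anterior collapses to cycle start
  expect_identical(seg$timepoints$most_anterior, seg$timepoints$max_closing)
})

test_that("a cycle without contact yields an empty occlusal phase", {
  truth <- simulate_jaw_motion(motion_spec(n_cycles = 2))
  occl <- occlusion_series(truth$gap_mm + 1, 0.05, truth$spec$frame_rate)
  seg <- detect_key_timepoints(truth_molar(truth), occl)
  expect_true(all(is.na(seg$timepoints$contact_onset)))
  occl_rows <- seg$phases[seg$phases$phase == "occlusal", ]
  expect_identical(occl_rows$start_frame, occl_rows$end_frame)
  expect_false(any(seg$timepoints$consistent))
})

test_that("no complete cycle raises an error", {
  truth <- simulate_jaw_motion(motion_spec(n_cycles = 1))
  half <- trajectory(truth$landmark_paths$molar_cusp[2:14, ], "molar_cusp",
                     200)
  occl <- occlusion_series(truth$gap_mm[2:14], 0.05, 200)
  expect_error(detect_key_timepoints(half, occl), "cycle")
})

test_that("phase statistics convert frames to durations", {
  truth <- simulate_jaw_motion(motion_spec(n_cycles = 4))
  seg <- detect_key_timepoints(truth_molar(truth), truth_occlusion(truth))
  st <- phase_statistics(seg)
  # 30-frame cycles at 200 Hz span 150 ms
  expect_equal(st$per_cycle$cycle_ms[1], 150)
  expect_equal(st$per_cycle$opening_ms + st$per_cycle$closing_ms +
                 st$per_cycle$occlusal_ms, st$per_cycle$cycle_ms)
  # single cycle: SD reported as absent
  one <- simulate_jaw_motion(motion_spec(n_cycles = 2))
  seg1 <- detect_key_timepoints(truth_molar(one), truth_occlusion(one))
  seg1$phases <- seg1$phases[seg1$phases$cycle == 1, ]
  st1 <- phase_statistics(seg1)
  expect_true(all(is.na(st1$summary$sd_ms)))
  # determinism
  seg2 <- detect_key_timepoints(truth_molar(truth), truth_occlusion(truth))
  expect_identical(seg$timepoints, seg2$timepoints)
})
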