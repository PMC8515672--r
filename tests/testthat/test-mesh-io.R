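test_that("STL round trips preserve geometry in ASCII and binary", {
  dent <- synth_dentition(resolution_mm = 0.2)
  m <- dent$mandible
  fa <- tempfile(fileext = ".stl")
  fb <- tempfile(fileext = ".stl")
  write_mesh(m, fa)
  write_mesh(m, fb, binary = TRUE)
  ra <- read_mesh(fa)
  rb <- read_mesh(fb)
  expect_identical(nrow(ra$faces), nrow(m$faces))
  expect_identical(nrow(rb$faces), nrow(m$faces))
  # STL stores a soup; compare per-face corner coordinates
  corners <- function(x) {
    tc <- cbind(x$vertices[x$faces[, 1], ], x$vertices[x$faces[, 2], ],
                x$vertices[x$faces[, 3], ])
    tc[order(tc[, 1], tc[, 2], tc[, 3]), ]
  }
  expect_lt(max(abs(corners(ra) - corners(m))), 1e-7)
  expect_lt(max(abs(corners(rb) - corners(m))), 1e-6)  # float32 storage
})

test_that("PLY round trips are exact in ASCII and binary", {
  dent <- synth_dentition(resolution_mm = 0.25)
  m <- dent$maxilla
  fa <- tempfile(fileext = ".ply")
  fb <- tempfile(fileext = ".ply")
  write_mesh(m, fa)
  write_mesh(m, fb, binary = TRUE)
  ra <- read_mesh(fa)
  rb <- read_mesh(fb)
  expect_equal(ra$vertices, m$vertices, ignore_attr = TRUE)
  expect_identical(ra$faces, m$faces)
  expect_equal(rb$vertices, m$vertices, ignore_attr = TRUE)
  expect_identical(rb$faces, m$faces)
})

test_that("mesh constructor and readers reject empty or corrupt input", {
  expect_error(tri_mesh(matrix(0, 0, 3), matrix(1L, 0, 3)), "empty")
  expect_error(tri_mesh(diag(3), matrix(c(1L, 2L, 4L), 1)), "out of range")
  f <- tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "garbage"), f)
  expect_error(read_mesh(f), "corrupt|header")
  f2 <- tempfile(fileext = ".stl")
  con <- file(f2, "wb")
  writeBin(raw(90), con)   # truncated binary STL
  close(con)
  expect_error(read_mesh(f2), "corrupt")
  expect_error(read_mesh(tempfile(fileext = ".obj")), "extension|such file")
})

test_that("marker CSV round trips losslessly and validates its schema", {
  truth <- simulate_jaw_motion(motion_spec(n_cycles = 1, cycle_ms = 50))
  cap <- synth_capture(truth, noise_sigma_mm = 0.01, seed = 2)
  f <- tempfile(fileext = ".csv")
  write_markers(cap, f)
  d <- utils::read.csv(f)
  expect_identical(nrow(d), n_frames(cap) * 4L)
  back <- read_markers(f)
  expect_equal(back$frame_rate, cap$frame_rate, tolerance = 1e-9)
  expect_lt(max(abs(back$coords - cap$coords)), 1e-9)

  # missing coordinate column is named in the error
  d2 <- d[setdiff(names(d), "z_mm")]
  f2 <- tempfile(fileext = ".csv")
  utils::write.csv(d2, f2, row.names = FALSE)
  expect_error(read_markers(f2), "z_mm")

  # non-numeric coordinate reported with its line
  d3 <- d
  d3$x_mm[3] <- "oops"
  f3 <- tempfile(fileext = ".csv")
  utils::write.csv(d3, f3, row.names = FALSE)
  expect_error(read_markers(f3), "line 3")

  # duplicated (frame, label)
  d4 <- rbind(d, d[1, ])
  f4 <- tempfile(fileext = ".csv")
  utils::write.csv(d4, f4, row.names = FALSE)
  expect_error(read_markers(f4), "duplicate")
})

test_that("points, EMG, trajectory and pose-series files round trip", {
  pts <- default_marker_geometry()
  f <- tempfile(fileext = ".csv")
  write_points(pts, f)
  back <- read_points(f)
  expect_equal(back$points, pts$points, tolerance = 1e-12)

  truth <- simulate_jaw_motion(motion_spec(n_cycles = 1))
  emg <- synth_emg(truth, seed = 5)
  fe <- tempfile(fileext = ".csv")
  write_emg(emg, fe)
  back <- read_emg(fe)
  expect_equal(back$sync_offset_ms, emg$sync_offset_ms)
  expect_equal(back$sampling_rate, emg$sampling_rate, tolerance = 1e-9)
  expect_lt(max(abs(back$signals - emg$signals)), 1e-9)

  tr <- trajectory(truth$landmark_paths$molar_cusp, "molar_cusp", 200)
  ft <- tempfile(fileext = ".csv")
  write_trajectory(tr, ft)
  back <- read_trajectory(ft)
  expect_lt(max(abs(back$coords - tr$coords)), 1e-9)

  fp <- tempfile(fileext = ".csv")
  write_pose_series(truth$pose_series, fp)
  back <- read_pose_series(fp)
  expect_lt(max(abs(back$rotations - truth$pose_series$rotations)), 1e-9)
  expect_lt(max(abs(back$translations - truth$pose_series$translations)), 1e-9)
})
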