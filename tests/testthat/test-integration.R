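test_that("static registration recovers the mounting pose exactly", {
  dent <- synth_dentition(resolution_mm = 0.2)
  ref <- default_marker_geometry()
  model <- anatomical_model(dent$mandible, dent$maxilla, ref, dent$landmarks)
  # static frame equal to the reference -> identity
  p0 <- register_maxilla_static(ref, model)
  expect_lt(max(abs(p0$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(p0$translation)), 1e-9)
  # known mounting pose round-trips
  set.seed(2)
  mount <- rigid_pose(random_rotation(), stats::rnorm(3, 0, 10))
  p1 <- register_maxilla_static(apply_pose(mount, ref), model)
  expect_lt(max(abs(p1$rotation - mount$rotation)), 1e-9)
  expect_lt(max(abs(p1$translation - mount$translation)), 1e-9)
})

test_that("static registration residual under noise matches Monte-Carlo expectation", {
  dent <- synth_dentition(resolution_mm = 0.2)
  ref <- default_marker_geometry()
  model <- anatomical_model(dent$mandible, dent$maxilla, ref, dent$landmarks)
  sigma <- 0.01
  set.seed(33)
  obs_rmsd <- replicate(300, {
    noisy <- labeled_points(ref$points + matrix(rnorm(12, 0, sigma), 4, 3),
                            ref$labels)
    attr(register_maxilla_static(noisy, model), "residual_rmsd")
  })
  set.seed(44)
  mc <- replicate(1000, {
    noisy <- labeled_points(ref$points + matrix(rnorm(12, 0, sigma), 4, 3),
                            ref$labels)
    attr(fit_rigid(ref, noisy), "residual_rmsd")
  })
  expect_lt(abs(mean(obs_rmsd) - mean(mc)) / mean(mc), 0.15)
})

test_that("landmark trajectories express motion relative to the maxilla", {
  b <- synth_bundle(motion_spec(n_cycles = 2))
  # static pose series at the intercuspal position -> constant CT coordinates
  n <- 10
  rot <- array(rep(diag(3), n), c(3, 3, n))
  static_ps <- pose_series(rot, matrix(0, n, 3), 200)
  mount <- attr(b$capture, "mount")
  static_capture_ps <- pose_series(
    array(rep(mount$rotation, n), c(3, 3, n)),
    matrix(mount$translation, n, 3, byrow = TRUE), 200)
  tr <- landmark_trajectory(static_capture_ps, b$maxilla_pose, b$model,
                            "molar_cusp")
  target <- b$model$landmarks$points["molar_cusp", ]
  expect_lt(max(abs(sweep(tr$coords, 2, target))), 1e-9)

  # full synthetic motion reproduces the generator's landmark paths
  for (nm in c("molar_cusp", "incisor_edge", "condyle_left")) {
    tr <- landmark_trajectory(b$pose_series, b$maxilla_pose, b$model, nm)
    expect_lt(max(abs(tr$coords - b$truth$landmark_paths[[nm]])), 1e-9)
  }
  expect_error(landmark_trajectory(b$pose_series, b$maxilla_pose, b$model,
                                   "nonexistent"), "unknown landmark")
})

test_that("hinge rotation about the intercondylar axis leaves condyles stationary", {
  dent <- synth_dentition(resolution_mm = 0.2)
  ref <- default_marker_geometry()
  model <- anatomical_model(dent$mandible, dent$maxilla, ref, dent$landmarks)
  c0 <- colMeans(dent$landmarks$points[c("condyle_left", "condyle_right"), ])
  n <- 25
  rot <- array(NA_real_, c(3, 3, n))
  tra <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    th <- 0.3 * sin(2 * pi * (i - 1) / n)
    R <- rot_y(th)                       # the intercondylar axis runs along y
    rot[, , i] <- R
    tra[i, ] <- c0 - as.numeric(R %*% c0)
  }
  hinge <- pose_series(rot, tra, 200)
  for (nm in c("condyle_left", "condyle_right")) {
    tr <- landmark_trajectory(hinge, identity_pose(), model, nm)
    disp <- sweep(tr$coords, 2, tr$coords[1, ])
    expect_lt(max(abs(disp)), 1e-9)
  }
  inc <- landmark_trajectory(hinge, identity_pose(), model, "incisor_edge")
  expect_gt(max(abs(sweep(inc$coords, 2, inc$coords[1, ]))), 1)
})

test_that("maxilla-relative trajectories are invariant to the capture frame", {
  spec <- motion_spec(n_cycles = 1)
  truth <- simulate_jaw_motion(spec)
  ref <- default_marker_geometry()
  dent <- synth_dentition(resolution_mm = 0.2)
  model <- anatomical_model(dent$mandible, dent$maxilla, ref, dent$landmarks)
  run_with_mount <- function(mount) {
    cap <- synth_capture(truth, mount = mount)
    ps <- estimate_pose_series(cap, ref)
    maxpose <- register_maxilla_static(attr(cap, "static_frame"), model)
    landmark_trajectory(ps, maxpose, model, "molar_cusp")$coords
  }
  set.seed(8)
  a <- run_with_mount(identity_pose())
  b <- run_with_mount(rigid_pose(random_rotation(), stats::rnorm(3, 0, 20)))
  expect_lt(max(abs(a - b)), 1e-9)
})

test_that("plane projections drop the orthogonal coordinate and keep gaps", {
  tr <- trajectory(rbind(c(1, 2, 3), c(4, 5, 6), c(NA, NA, NA)), "molar_cusp",
                   200)
  sag <- project_plane(tr, "sagittal")
  expect_equal(unname(sag$coords[1, ]), c(1, 3))
  fro <- project_plane(tr, "frontal")
  expect_equal(unname(fro$coords[1, ]), c(2, 3))
  occ <- project_plane(tr, "occlusal")
  expect_equal(unname(occ$coords[2, ]), c(4, 5))
  for (p in list(sag, fro, occ)) {
    expect_identical(nrow(p$coords), 3L)
    expect_true(all(is.na(p$coords[3, ])))
  }
})

test_that("posed-mandible export and trajectory smoothing behave", {
  b <- synth_bundle(motion_spec(n_cycles = 1), resolution_mm = 0.25)
  f <- tempfile(fileext = ".ply")
  export_posed_mandible(b$pose_series, b$maxilla_pose, b$model, 15, f)
  posed <- read_mesh(f)
  expect_identical(nrow(posed$vertices), nrow(b$model$mandible_mesh$vertices))
  tr <- landmark_trajectory(b$pose_series, b$maxilla_pose, b$model,
                            "molar_cusp")
  expect_identical(smooth_trajectory(tr, 1)$coords, tr$coords)
  sm <- smooth_trajectory(tr, 3)
  expect_identical(dim(sm$coords), dim(tr$coords))
  tr$coords[5, ] <- NA
  sm2 <- smooth_trajectory(tr, 3)
  expect_true(all(is.na(sm2$coords[5, ])))
  expect_false(anyNA(sm2$coords[4, ]))
})
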