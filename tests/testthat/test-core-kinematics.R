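test_that("rigid fit recovers exact poses and reports residuals", {
  ref <- labeled_points(rbind(m1 = c(1, 0, 0), m2 = c(0, 1, 0),
                              m3 = c(0, 0, 1), m4 = c(1, 1, 1)))
  # identical point sets
  fit <- fit_rigid(ref, ref)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-12)
  expect_equal(fit$translation, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(attr(fit, "residual_rmsd"), 0, tolerance = 1e-12)

  # 90 degrees about z plus a shift
  R90 <- rot_z(pi / 2)
  obs <- labeled_points(ref$points %*% t(R90) +
                          matrix(c(1, 2, 3), 4, 3, byrow = TRUE), ref$labels)
  fit <- fit_rigid(ref, obs)
  expect_lt(max(abs(fit$rotation - R90)), 1e-9)
  expect_lt(max(abs(fit$translation - c(1, 2, 3))), 1e-9)
  expect_lt(attr(fit, "residual_rmsd"), 1e-9)
})

test_that("rigid fit errors on insufficient or degenerate correspondence", {
  ref <- labeled_points(rbind(a = c(0, 0, 0), b = c(1, 0, 0),
                              c = c(0, 1, 0)))
  two <- labeled_points(rbind(a = c(0, 0, 0), b = c(1, 0, 0)))
  expect_error(fit_rigid(ref, two), "insufficient")
  line <- labeled_points(rbind(a = c(0, 0, 0), b = c(1, 0, 0),
                               c = c(2, 0, 0)))
  expect_error(fit_rigid(line, line), "degenerate|collinear")
})

test_that("rigid fit matches a brute-force optimisation oracle and never reflects", {
  set.seed(41)
  for (rep in 1:12) {
    n <- sample(3:5, 1)
    A <- random_points(n)
    R <- random_rotation()
    t <- stats::rnorm(3, 0, 3)
    noise <- matrix(stats::rnorm(n * 3, 0, 0.01), n, 3)
    B <- labeled_points(A$points %*% t(R) +
                          matrix(t, n, 3, byrow = TRUE) + noise, A$labels)
    fit <- fit_rigid(A, B)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
    expect_lt(rotation_angle(fit$rotation, R), 0.05)
    # residual equals the global minimum of the same objective
    expect_equal(attr(fit, "residual_rmsd"),
                 oracle_fit_residual(A$points, B$points), tolerance = 1e-6)
  }
})

test_that("apply_pose is rigid and preserves labels", {
  p <- rigid_pose(diag(3), c(0, 0, 1))
  expect_equal(apply_pose(identity_pose(), c(1, 2, 3)), c(1, 2, 3))
  expect_equal(apply_pose(p, c(0, 0, 0)), c(0, 0, 1))
  set.seed(7)
  pts <- random_points(6)
  pose <- rigid_pose(random_rotation(), stats::rnorm(3))
  out <- apply_pose(pose, pts)
  expect_identical(out$labels, pts$labels)
  expect_lt(max(abs(dist(out$points) - dist(pts$points))), 1e-9)
  expect_error(apply_pose(pose, c(1, NA, 3)), "finite")
})

test_that("pose composition and inversion follow group structure", {
  set.seed(11)
  a <- rigid_pose(random_rotation(), stats::rnorm(3))
  b <- rigid_pose(random_rotation(), stats::rnorm(3))
  ai <- compose_invert(a)
  aa <- compose_invert(a, ai)
  expect_lt(max(abs(aa$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(aa$translation)), 1e-9)
  ib <- compose_invert(identity_pose(), b)
  expect_equal(ib$rotation, b$rotation, tolerance = 1e-12)
  expect_equal(ib$translation, b$translation, tolerance = 1e-12)
  for (rep in 1:5) {
    p <- stats::rnorm(3)
    expect_equal(apply_pose(pose_compose(a, b), p),
                 apply_pose(a, apply_pose(b, p)), tolerance = 1e-9)
  }
})

test_that("pose series estimation round-trips known motion exactly", {
  ref <- default_marker_geometry()
  # static capture -> identity every frame
  coords <- array(NA_real_, c(5, 4, 3), dimnames = list(NULL, ref$labels, NULL))
  for (i in 1:5) coords[i, , ] <- ref$points
  ps <- estimate_pose_series(capture_sequence(coords, 200), ref)
  for (i in 1:5) {
    expect_lt(max(abs(ps$rotations[, , i] - diag(3))), 1e-9)
    expect_lt(max(abs(ps$translations[i, ])), 1e-9)
  }
  # known pose sequence, no noise
  set.seed(5)
  n <- 20
  poses <- lapply(seq_len(n), function(i)
    rigid_pose(random_rotation(), stats::rnorm(3, 0, 4)))
  coords <- array(NA_real_, c(n, 4, 3), dimnames = list(NULL, ref$labels, NULL))
  for (i in seq_len(n)) coords[i, , ] <- apply_pose(poses[[i]], ref$points)
  ps <- estimate_pose_series(capture_sequence(coords, 200), ref)
  for (i in seq_len(n)) {
    expect_lt(max(abs(ps$rotations[, , i] - poses[[i]]$rotation)), 1e-9)
    expect_lt(max(abs(ps$translations[i, ] - poses[[i]]$translation)), 1e-9)
  }
})

test_that("missing markers fall back to subsets, gaps are flagged, interpolation fills", {
  ref <- default_marker_geometry()
  n <- 6
  coords <- array(NA_real_, c(n, 4, 3), dimnames = list(NULL, ref$labels, NULL))
  shift <- cbind(seq_len(n), 0, 0)
  for (i in seq_len(n))
    coords[i, , ] <- ref$points + matrix(shift[i, ], 4, 3, byrow = TRUE)
  coords[2, 4, ] <- NA          # one marker lost: 3 remain, still fits
  coords[4, 2:4, ] <- NA        # only 1 marker: frame invalid
  ps <- estimate_pose_series(capture_sequence(coords, 200), ref)
  expect_true(ps$valid[2])
  expect_false(ps$valid[4])
  expect_lt(max(abs(ps$translations[2, ] - c(2, 0, 0))), 1e-9)
  expect_true(is.na(ps$translations[4, 1]))
  filled <- interpolate_pose_series(ps)
  expect_lt(max(abs(filled$translations[4, ] - c(4, 0, 0))), 1e-9)
  expect_identical(attr(filled, "interpolated"), 4L)
  # all frames invalid -> fatal
  coords[] <- NA
  expect_error(estimate_pose_series(capture_sequence(coords, 200), ref),
               "usable")
})

test_that("noisy pose estimation error matches an independent Monte-Carlo prediction", {
  ref <- default_marker_geometry()
  sigma <- 0.005
  run_errors <- function(n, seed) {
    set.seed(seed)
    rot_err <- tra_err <- rmsd <- numeric(n)
    for (i in seq_len(n)) {
      pose <- rigid_pose(random_rotation(), stats::rnorm(3, 0, 2))
      obs <- apply_pose(pose, ref$points) +
        matrix(stats::rnorm(12, 0, sigma), 4, 3)
      fit <- fit_rigid(ref, labeled_points(obs, ref$labels))
      rot_err[i] <- rotation_angle(fit$rotation, pose$rotation)
      tra_err[i] <- sqrt(sum((fit$translation - pose$translation)^2))
      rmsd[i] <- attr(fit, "residual_rmsd")
    }
    c(rot = mean(rot_err), tra = mean(tra_err), rmsd = mean(rmsd))
  }
  mc <- run_errors(1000, 101)      # independent Monte-Carlo prediction
  obs <- run_errors(300, 202)      # the path under test, fresh draws
  expect_lt(abs(obs["rot"] - mc["rot"]) / mc["rot"], 0.15)
  expect_lt(abs(obs["tra"] - mc["tra"]) / mc["tra"], 0.15)
  expect_lt(abs(obs["rmsd"] - mc["rmsd"]) / mc["rmsd"], 0.15)
})
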