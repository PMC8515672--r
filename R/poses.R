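#' Rigid-body pose
#'
#' A pose is the rigid map \eqn{p \mapsto R p + t} taking points expressed in
#' one coordinate system (typically the anatomical / CT frame) into another
#' (typically the motion-capture frame). The rotation must be a proper
#' orthonormal matrix: reflections are never valid jaw poses.
#'
#' @param rotation 3x3 rotation matrix (dimensionless).
#' @param translation length-3 translation vector (mm).
#' @return An object of class `rigid_pose` with elements `rotation` and
#'   `translation`.
#' @examples
#' p <- rigid_pose(diag(3), c(1, 2, 3))
#' apply_pose(p, c(0, 0, 0))
#' @export
rigid_pose <- function(rotation, translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)) || length(translation) != 3L)
    stop("rigid_pose: rotation must be 3x3 and translation length 3")
  if (!all(is.finite(rotation)) || !all(is.finite(translation)))
    stop("rigid_pose: non-finite entries")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rigid_pose: rotation is not orthonormal (R'R != I within 1e-9)")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rigid_pose: det(rotation) != +1; reflections are not rigid poses")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_pose")
}

#' @export
print.rigid_pose <- function(x, ...) {
  cat("Rigid pose (rotation | translation mm):\n")
  m <- cbind(x$rotation, x$translation)
  colnames(m) <- c("r1", "r2", "r3", "t")
  print(round(m, 6))
  invisible(x)
}

#' @rdname rigid_pose
#' @export
identity_pose <- function() rigid_pose(diag(3), c(0, 0, 0))

#' @rdname rigid_pose
#' @param x object to test.
#' @export
is_rigid_pose <- function(x) inherits(x, "rigid_pose")

#' Labeled 3D point set
#'
#' Marker or landmark coordinates with unique identifiers, the common currency
#' between capture data and the anatomical model. Stored as an n x 3 matrix in
#' mm with labels as rownames.
#'
#' @param points n x 3 numeric matrix (mm), or a data.frame with columns
#'   x, y, z.
#' @param labels character vector of unique marker identifiers.
#' @param frame_id optional integer frame number.
#' @return Object of class `labeled_points`.
#' @export
labeled_points <- function(points, labels = rownames(points), frame_id = NULL) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L) stop("labeled_points: points must have 3 columns")
  if (nrow(points) < 1L) stop("labeled_points: need at least one point")
  if (is.null(labels)) labels <- paste0("m", seq_len(nrow(points)))
  labels <- as.character(labels)
  if (length(labels) != nrow(points)) stop("labeled_points: one label per point")
  if (anyDuplicated(labels)) stop("labeled_points: labels must be unique")
  if (!all(is.finite(points))) stop("labeled_points: coordinates must be finite")
  rownames(points) <- labels
  colnames(points) <- c("x", "y", "z")
  structure(list(points = points, labels = labels, frame_id = frame_id),
            class = "labeled_points")
}

#' @export
print.labeled_points <- function(x, ...) {
  cat(sprintf("Labeled point set (%d points%s)\n", nrow(x$points),
              if (is.null(x$frame_id)) "" else paste0(", frame ", x$frame_id)))
  print(round(x$points, 4))
  invisible(x)
}

# internal: coerce matrix / labeled_points to bare coordinate matrix
.coords <- function(p) {
  if (inherits(p, "labeled_points")) return(p$points)
  if (is.numeric(p) && is.null(dim(p)) && length(p) == 3L)
    return(matrix(p, 1, 3, dimnames = list(NULL, c("x", "y", "z"))))
  as.matrix(p)
}

#' Least-squares rigid fit between corresponding labeled point sets
#'
#' Finds the rigid pose minimizing the sum of squared distances between
#' transformed reference points and observed points over their common labels
#' (Kabsch / orthogonal Procrustes): centroids are aligned, the rotation is the
#' SVD polar factor of the cross-covariance with the determinant sign
#' corrected so that only proper rotations are returned.
#'
#' @param reference,observed `labeled_points` sharing at least 3 labels; the
#'   common points must not be collinear in the reference configuration.
#' @return `rigid_pose` with attribute `residual_rmsd` (mm), the root mean
#'   square residual of the fit.
#' @export
fit_rigid <- function(reference, observed) {
  if (!inherits(reference, "labeled_points") ||
      !inherits(observed, "labeled_points"))
    stop("fit_rigid: inputs must be labeled_points")
  common <- intersect(reference$labels, observed$labels)
  if (length(common) < 3L)
    stop(sprintf(
      "fit_rigid: insufficient correspondence - %d common label(s), need >= 3",
      length(common)))
  A <- reference$points[common, , drop = FALSE]
  B <- observed$points[common, , drop = FALSE]
  if (!all(is.finite(B))) stop("fit_rigid: observed coordinates must be finite")
  ca <- colMeans(A)
  cb <- colMeans(B)
  A0 <- sweep(A, 2, ca)
  B0 <- sweep(B, 2, cb)
  # degeneracy: collinear reference markers leave a free rotation axis
  sv_ref <- svd(A0, nu = 0, nv = 0)$d
  if (sv_ref[2] < 1e-6)
    stop("fit_rigid: degenerate geometry - reference markers are collinear")
  H <- crossprod(A0, B0)            # 3x3 cross-covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- cb - as.numeric(R %*% ca)
  fitted <- A %*% t(R) + matrix(t, nrow(A), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  pose <- rigid_pose(R, t)
  attr(pose, "residual_rmsd") <- rmsd
  attr(pose, "n_markers") <- length(common)
  pose
}

#' Apply a rigid pose to points
#'
#' Maps every point as `rotation %*% p + translation`. Labels (and the
#' `frame_id`) are preserved when a `labeled_points` object is supplied.
#'
#' @param pose a `rigid_pose`.
#' @param points a `labeled_points`, an n x 3 matrix, or a length-3 vector.
#' @return Same container kind as `points`.
#' @export
apply_pose <- function(pose, points) {
  stopifnot(is_rigid_pose(pose))
  m <- .coords(points)
  if (!all(is.finite(m))) stop("apply_pose: non-finite coordinates")
  out <- m %*% t(pose$rotation) +
    matrix(pose$translation, nrow(m), 3, byrow = TRUE)
  if (inherits(points, "labeled_points"))
    return(labeled_points(out, points$labels, points$frame_id))
  if (is.numeric(points) && is.null(dim(points))) return(as.numeric(out))
  rownames(out) <- rownames(m)
  out
}

#' Compose or invert rigid poses
#'
#' `compose_invert(a, b)` returns the pose "apply `b`, then `a`";
#' `compose_invert(a)` returns the inverse of `a`. `pose_compose` and
#' `pose_invert` are the idiomatic aliases.
#'
#' @param a,b `rigid_pose` objects; `b` may be omitted to invert `a`.
#' @return A `rigid_pose`.
#' @export
compose_invert <- function(a, b = NULL) {
  stopifnot(is_rigid_pose(a))
  if (is.null(b)) {
    Rt <- t(a$rotation)
    return(rigid_pose(Rt, -as.numeric(Rt %*% a$translation)))
  }
  stopifnot(is_rigid_pose(b))
  rigid_pose(.orthonormalize(a$rotation %*% b$rotation),
             as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' @rdname compose_invert
#' @export
pose_compose <- function(a, b) compose_invert(a, b)

#' @rdname compose_invert
#' @export
pose_invert <- function(a) compose_invert(a)

# re-project a near-orthonormal matrix onto SO(3); keeps long compositions
# from drifting past the 1e-9 validity tolerance
.orthonormalize <- function(R) {
  s <- svd(R)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Rotation angle between two poses (radians)
#'
#' Geodesic distance on SO(3): the angle of the relative rotation
#' `a$rotation' %*% b$rotation`.
#' @param a,b `rigid_pose` objects (or bare 3x3 rotation matrices).
#' @return angle in radians, in `[0, pi]`.
#' @export
rotation_angle <- function(a, b = NULL) {
  Ra <- if (is_rigid_pose(a)) a$rotation else a
  Rb <- if (is.null(b)) diag(3) else if (is_rigid_pose(b)) b$rotation else b
  tr <- sum(diag(crossprod(Ra, Rb)))
  acos(max(-1, min(1, (tr - 1) / 2)))
}

# ---- quaternion helpers (used for pose interpolation) ----

.rot_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    if (i == 1) {
      s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
      q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
             (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
    } else if (i == 2) {
      s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
      q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
             0.25 * s, (R[2, 3] + R[3, 2]) / s)
    } else {
      s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
      q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
             (R[2, 3] + R[3, 2]) / s, 0.25 * s)
    }
  }
  q / sqrt(sum(q^2))
}

.quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
}

.quat_slerp <- function(q1, q2, u) {
  if (sum(q1 * q2) < 0) q2 <- -q2
  d <- max(-1, min(1, sum(q1 * q2)))
  th <- acos(d)
  if (th < 1e-12) return(q1)
  (sin((1 - u) * th) * q1 + sin(u * th) * q2) / sin(th)
}

#' Elementary rotations about anatomical axes
#'
#' Right-handed rotations: `rot_x` = roll about the anterior axis, `rot_y` =
#' pitch about the transverse (left-right) axis, `rot_z` = yaw about the
#' vertical axis.
#'
#' @param theta angle in radians.
#' @return 3x3 rotation matrix.
#' @export
rot_x <- function(theta)
  matrix(c(1, 0, 0, 0, cos(theta), -sin(theta), 0, sin(theta), cos(theta)),
         3, 3, byrow = TRUE)

#' @rdname rot_x
#' @export
rot_y <- function(theta)
  matrix(c(cos(theta), 0, sin(theta), 0, 1, 0, -sin(theta), 0, cos(theta)),
         3, 3, byrow = TRUE)

#' @rdname rot_x
#' @export
rot_z <- function(theta)
  matrix(c(cos(theta), -sin(theta), 0, sin(theta), cos(theta), 0, 0, 0, 1),
         3, 3, byrow = TRUE)
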