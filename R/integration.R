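#' Anatomical model from segmented micro-CT
#'
#' Bundles the two surface meshes, the marker reference coordinates and the
#' named anatomical landmarks, all expressed in the CT frame (mm). The CT
#' frame is anatomical: +X anterior, +Y animal-left, +Z superior, with the
#' mandible at its intercuspal position.
#'
#' @param mandible_mesh,maxilla_mesh `tri_mesh` objects (mm, CT frame).
#' @param marker_reference `labeled_points`: the four (at least three,
#'   non-collinear) mandibular markers in the CT frame.
#' @param landmarks `labeled_points` of named analysis points (typically
#'   `incisor_edge`, `molar_cusp`, `condyle_left`, `condyle_right`).
#' @return Object of class `anatomical_model`.
#' @export
anatomical_model <- function(mandible_mesh, maxilla_mesh, marker_reference,
                             landmarks) {
  stopifnot(inherits(mandible_mesh, "tri_mesh"),
            inherits(maxilla_mesh, "tri_mesh"),
            inherits(marker_reference, "labeled_points"),
            inherits(landmarks, "labeled_points"))
  sv <- svd(scale(marker_reference$points, scale = FALSE), nu = 0, nv = 0)$d
  if (nrow(marker_reference$points) < 3L || sv[2] < 1e-6)
    stop("anatomical_model: marker reference needs >= 3 non-collinear points")
  structure(list(mandible_mesh = mandible_mesh, maxilla_mesh = maxilla_mesh,
                 marker_reference = marker_reference, landmarks = landmarks),
            class = "anatomical_model")
}

#' @export
print.anatomical_model <- function(x, ...) {
  cat(sprintf(
    "Anatomical model: mandible %d faces, maxilla %d faces, %d markers, %d landmarks\n",
    nrow(x$mandible_mesh$faces), nrow(x$maxilla_mesh$faces),
    nrow(x$marker_reference$points), nrow(x$landmarks$points)))
  invisible(x)
}

#' Register the maxilla into capture coordinates from the static acquisition
#'
#' At the consolidated acquisition the mandible is closed into the intercuspal
#' position and fixed to the cranium, so mandible and maxilla form one rigid
#' unit. Fitting the marker reference onto the static capture frame therefore
#' yields the single CT-to-capture pose that places the maxilla (and the whole
#' cranium) in capture coordinates for every frame.
#'
#' @param static_capture_frame `labeled_points`: the markers as captured at
#'   the static intercuspal acquisition.
#' @param model an [anatomical_model()].
#' @return `rigid_pose` (CT to capture) with attribute `residual_rmsd` (mm).
#' @export
register_maxilla_static <- function(static_capture_frame, model) {
  stopifnot(inherits(model, "anatomical_model"))
  fit_rigid(model$marker_reference, static_capture_frame)
}

#' Landmark trajectory in the maxilla-fixed frame
#'
#' Maps a mandibular landmark through each frame's estimated CT-to-capture
#' pose, then back through the inverse of the static maxilla registration.
#' The result expresses mandibular motion relative to the (head-fixed)
#' maxilla, in CT-aligned anatomical axes, independent of how the capture
#' system was oriented. Invalid pose frames propagate as `NA` gaps.
#'
#' @param pose_series per-frame mandible poses from [estimate_pose_series()].
#' @param maxilla_pose the static registration from
#'   [register_maxilla_static()].
#' @param model an [anatomical_model()].
#' @param landmark_name a landmark name present in `model$landmarks`.
#' @return Object of class `trajectory`: `coords` (n x 3 matrix, mm),
#'   `landmark`, `frame_rate`, `t_ms`.
#' @export
landmark_trajectory <- function(pose_series, maxilla_pose, model,
                                landmark_name) {
  stopifnot(inherits(pose_series, "pose_series"),
            is_rigid_pose(maxilla_pose), inherits(model, "anatomical_model"))
  if (!landmark_name %in% model$landmarks$labels)
    stop("landmark_trajectory: unknown landmark '", landmark_name,
         "'; model has: ", paste(model$landmarks$labels, collapse = ", "))
  p <- model$landmarks$points[landmark_name, ]
  inv <- pose_invert(maxilla_pose)
  n <- n_frames(pose_series)
  out <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("x", "y", "z")))
  for (i in seq_len(n)) {
    if (!pose_series$valid[i]) next
    q <- apply_pose(pose_at(pose_series, i), p)
    out[i, ] <- apply_pose(inv, q)
  }
  trajectory(out, landmark_name, pose_series$frame_rate)
}

#' @rdname landmark_trajectory
#' @param coords n x 3 matrix of maxilla-frame positions (mm); `NA` rows are
#'   gaps at invalid frames.
#' @param landmark landmark name.
#' @param frame_rate Hz.
#' @export
trajectory <- function(coords, landmark, frame_rate) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3, frame_rate > 0)
  colnames(coords) <- c("x", "y", "z")
  structure(list(coords = coords, landmark = landmark,
                 frame_rate = frame_rate,
                 t_ms = (seq_len(nrow(coords)) - 1) / frame_rate * 1000),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory of '%s': %d frames at %g Hz (%d gaps)\n",
              x$landmark, nrow(x$coords), x$frame_rate,
              sum(!stats::complete.cases(x$coords))))
  invisible(x)
}

#' Orthographic plane projection of a trajectory
#'
#' Projects a maxilla-frame trajectory onto one of the three anatomical
#' planes by dropping the orthogonal coordinate: sagittal keeps (X anterior,
#' Z superior), frontal keeps (Y lateral, Z superior), occlusal keeps (X, Y).
#'
#' @param traj a [trajectory()].
#' @param plane `"sagittal"`, `"frontal"` or `"occlusal"`.
#' @return Object of class `trajectory2d`: `coords` (n x 2), axis labels,
#'   plane name, `frame_rate`.
#' @export
project_plane <- function(traj, plane = c("sagittal", "frontal", "occlusal")) {
  stopifnot(inherits(traj, "trajectory"))
  plane <- match.arg(plane)
  sel <- switch(plane,
                sagittal = c(1L, 3L),
                frontal = c(2L, 3L),
                occlusal = c(1L, 2L))
  axes <- switch(plane,
                 sagittal = c("anterior x (mm)", "superior z (mm)"),
                 frontal = c("lateral y (mm)", "superior z (mm)"),
                 occlusal = c("anterior x (mm)", "lateral y (mm)"))
  structure(list(coords = traj$coords[, sel, drop = FALSE], plane = plane,
                 axes = axes, landmark = traj$landmark,
                 frame_rate = traj$frame_rate, t_ms = traj$t_ms),
            class = "trajectory2d")
}

#' @export
print.trajectory2d <- function(x, ...) {
  cat(sprintf("%s-plane projection of '%s': %d frames\n", x$plane,
              x$landmark, nrow(x$coords)))
  invisible(x)
}

#' @export
plot.trajectory2d <- function(x, ...) {
  graphics::plot(x$coords[, 1], x$coords[, 2], type = "l", asp = 1,
                 xlab = x$axes[1], ylab = x$axes[2],
                 main = sprintf("%s (%s plane)", x$landmark, x$plane), ...)
  invisible(x)
}

#' Export a posed mandible mesh for a selected frame
#'
#' Writes the mandible surface, posed into the maxilla-fixed frame at frame
#' `i`, for rendering alongside the static maxilla in external viewers.
#'
#' @param pose_series mandible pose series (CT to capture).
#' @param maxilla_pose static maxilla registration (CT to capture).
#' @param model an [anatomical_model()].
#' @param i frame index.
#' @param path output `.stl` or `.ply` path.
#' @param binary write binary mesh format.
#' @return `path`, invisibly.
#' @export
export_posed_mandible <- function(pose_series, maxilla_pose, model, i, path,
                                  binary = FALSE) {
  p <- pose_at(pose_series, i)
  if (is.null(p)) stop("export_posed_mandible: frame ", i, " is invalid")
  rel <- pose_compose(pose_invert(maxilla_pose), p)
  write_mesh(transform_mesh(model$mandible_mesh, rel), path, binary)
}

#' Moving-average trajectory smoothing
#'
#' Optional centered moving average over an odd window; gaps (NA frames) stay
#' gaps and do not bleed into neighbours.
#' @param traj a [trajectory()].
#' @param window odd window length in frames.
#' @return smoothed [trajectory()].
#' @export
smooth_trajectory <- function(traj, window = 3) {
  stopifnot(inherits(traj, "trajectory"), window >= 1, window %% 2 == 1)
  if (window == 1) return(traj)
  half <- (window - 1) / 2
  n <- nrow(traj$coords)
  out <- traj$coords
  for (i in seq_len(n)) {
    if (anyNA(traj$coords[i, ])) next
    idx <- max(1, i - half):min(n, i + half)
    idx <- idx[stats::complete.cases(traj$coords[idx, , drop = FALSE])]
    out[i, ] <- colMeans(traj$coords[idx, , drop = FALSE])
  }
  trajectory(out, traj$landmark, traj$frame_rate)
}
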