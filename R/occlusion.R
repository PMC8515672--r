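#' Minimum clearance between posed mandible and maxilla
#'
#' Symmetric minimum vertex-to-surface distance between the mandible mesh,
#' posed by `pose`, and the (static) maxilla mesh: posed-mandible vertices are
#' measured against maxilla triangles and maxilla vertices against posed-
#' mandible triangles, taking the smaller. Queries run against a uniform-grid
#' spatial index; the returned distance is exact. If the two surfaces cross
#' (interpenetration), the clearance is reported as 0 rather than a signed
#' depth.
#'
#' @param mandible_mesh,maxilla_mesh `tri_mesh` objects in a common frame
#'   (before posing).
#' @param pose `rigid_pose` applied to the mandible (default identity).
#' @param region restrict the mandible to faces near a landmark: `"all"`,
#'   `"molar"` or `"incisor"`.
#' @param landmarks `labeled_points` with `molar_cusp` / `incisor_edge`
#'   entries (mandible frame); required when `region != "all"`.
#' @param region_radius_mm inclusion radius of the region mask (mm).
#' @return List with `clearance_mm`, `crossing` (logical), and the closest
#'   point pair `point_mandible`, `point_maxilla` (posed frame, mm).
#' @export
min_clearance <- function(mandible_mesh, maxilla_mesh, pose = identity_pose(),
                          region = c("all", "molar", "incisor"),
                          landmarks = NULL, region_radius_mm = 1.5) {
  region <- match.arg(region)
  stopifnot(inherits(mandible_mesh, "tri_mesh"),
            inherits(maxilla_mesh, "tri_mesh"))
  mesh <- .mask_region(mandible_mesh, region, landmarks, region_radius_mm)
  posed <- transform_mesh(mesh, pose)
  r <- cpp_mesh_clearance(posed$vertices, posed$faces,
                          maxilla_mesh$vertices, maxilla_mesh$faces)
  list(clearance_mm = r$dist, crossing = r$crossing,
       point_mandible = as.numeric(r$point_a),
       point_maxilla = as.numeric(r$point_b))
}

.mask_region <- function(mesh, region, landmarks, radius) {
  if (region == "all") return(mesh)
  if (is.null(landmarks))
    stop("min_clearance: landmarks required for region '", region, "'")
  nm <- switch(region, molar = "molar_cusp", incisor = "incisor_edge")
  if (!nm %in% landmarks$labels)
    stop("min_clearance: landmark '", nm, "' not found")
  mesh_region(mesh, landmarks$points[nm, ], radius)
}

#' Per-frame occlusal clearance and contact series
#'
#' Computes the minimum mandible-maxilla clearance for every valid frame of a
#' pose series, in the maxilla-fixed frame (mandible pose composed with the
#' inverse static maxilla registration), and flags frames with clearance at
#' or below the contact threshold. Invalid pose frames propagate as gaps.
#'
#' @param pose_series mandible pose series (CT to capture frame).
#' @param maxilla_pose static maxilla registration (CT to capture).
#' @param model an [anatomical_model()].
#' @param threshold_mm contact threshold (mm); the default 0.05 mm is the
#'   mesh-resolution scale of the toy dentition.
#' @param region optional mandible region mask as in [min_clearance()].
#' @param region_radius_mm region mask radius (mm).
#' @return Object of class `occlusion_series`: per-frame `clearance_mm`,
#'   logical `contact`, `crossing`, `threshold_mm`, `frame_rate`, `t_ms`.
#' @export
contact_series <- function(pose_series, maxilla_pose, model,
                           threshold_mm = 0.05,
                           region = c("all", "molar", "incisor"),
                           region_radius_mm = 1.5) {
  region <- match.arg(region)
  stopifnot(inherits(pose_series, "pose_series"),
            is_rigid_pose(maxilla_pose), inherits(model, "anatomical_model"),
            threshold_mm > 0)
  mesh <- .mask_region(model$mandible_mesh, region, model$landmarks,
                       region_radius_mm)
  inv <- pose_invert(maxilla_pose)
  n <- n_frames(pose_series)
  rot <- array(NA_real_, c(3, 3, n))
  tra <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    if (!pose_series$valid[i]) next
    rel <- pose_compose(inv, pose_at(pose_series, i))
    rot[, , i] <- rel$rotation
    tra[i, ] <- rel$translation
  }
  rot[is.na(rot)] <- 0
  r <- cpp_contact_series(mesh$vertices, mesh$faces,
                          model$maxilla_mesh$vertices,
                          model$maxilla_mesh$faces,
                          rot, tra, pose_series$valid,
                          cross_check_below = 4 * threshold_mm)
  occlusion_series(r$dist, threshold_mm, pose_series$frame_rate,
                   crossing = r$crossing,
                   closest_mandible = r$point_a, closest_maxilla = r$point_b)
}

#' @rdname contact_series
#' @param clearance_mm per-frame minimum clearance (mm), `NA` at gaps.
#' @param frame_rate Hz.
#' @param crossing optional per-frame interpenetration flags.
#' @param closest_mandible,closest_maxilla optional n x 3 closest-point
#'   matrices.
#' @export
occlusion_series <- function(clearance_mm, threshold_mm, frame_rate,
                             crossing = NULL, closest_mandible = NULL,
                             closest_maxilla = NULL) {
  stopifnot(threshold_mm >= 0, frame_rate > 0)
  clearance_mm <- as.numeric(clearance_mm)
  if (any(clearance_mm < 0, na.rm = TRUE))
    stop("occlusion_series: clearance must be non-negative")
  structure(list(clearance_mm = clearance_mm,
                 contact = clearance_mm <= threshold_mm,
                 crossing = crossing, threshold_mm = threshold_mm,
                 frame_rate = frame_rate,
                 t_ms = (seq_along(clearance_mm) - 1) / frame_rate * 1000,
                 closest_mandible = closest_mandible,
                 closest_maxilla = closest_maxilla),
            class = "occlusion_series")
}

#' @export
print.occlusion_series <- function(x, ...) {
  cat(sprintf(
    "Occlusion series: %d frames, %d in contact (threshold %g mm), min clearance %.4g mm\n",
    length(x$clearance_mm), sum(x$contact, na.rm = TRUE), x$threshold_mm,
    min(x$clearance_mm, na.rm = TRUE)))
  invisible(x)
}

#' Maximal contact intervals of an occlusion series
#'
#' @param occlusion an [occlusion_series()].
#' @return data.frame with columns `onset_frame`, `offset_frame` (inclusive,
#'   1-based) and `onset_ms`, `offset_ms`.
#' @export
contact_intervals <- function(occlusion) {
  stopifnot(inherits(occlusion, "occlusion_series"))
  flag <- occlusion$contact
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(onset_frame = starts[keep], offset_frame = ends[keep],
             onset_ms = occlusion$t_ms[starts[keep]],
             offset_ms = occlusion$t_ms[ends[keep]])
}
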