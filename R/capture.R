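#' Marker capture sequence
#'
#' Per-frame labeled marker positions from the motion-capture system. All
#' frames share one label set; missing observations within a frame are carried
#' as `NA` coordinates (a marker hidden from a camera), never dropped.
#'
#' @param frames list of `labeled_points` (identical label sets), or a 3-D
#'   array `[frame, marker, xyz]` with marker dimnames.
#' @param frame_rate capture frame rate in Hz (the reference hardware runs at
#'   200 frames/s).
#' @param frame_ids optional strictly increasing integer frame numbers;
#'   defaults to `1:n`.
#' @return Object of class `capture_sequence` with elements `coords`
#'   (n_frames x n_markers x 3 array), `labels`, `frame_ids`, `frame_rate`.
#' @export
capture_sequence <- function(frames, frame_rate, frame_ids = NULL) {
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0)
    stop("capture_sequence: frame_rate must be a positive scalar (Hz)")
  if (is.array(frames) && length(dim(frames)) == 3L) {
    coords <- frames
    labels <- dimnames(coords)[[2]]
    if (is.null(labels)) labels <- paste0("m", seq_len(dim(coords)[2]))
  } else {
    if (!length(frames)) stop("capture_sequence: no frames")
    labels <- frames[[1]]$labels
    for (f in frames)
      if (!identical(sort(f$labels), sort(labels)))
        stop("capture_sequence: all frames must share the same label set")
    coords <- array(NA_real_, c(length(frames), length(labels), 3L))
    for (i in seq_along(frames))
      coords[i, , ] <- frames[[i]]$points[labels, , drop = FALSE]
  }
  n <- dim(coords)[1]
  if (is.null(frame_ids)) frame_ids <- seq_len(n)
  frame_ids <- as.integer(frame_ids)
  if (length(frame_ids) != n || any(diff(frame_ids) <= 0))
    stop("capture_sequence: frame_ids must be strictly increasing, one per frame")
  dimnames(coords) <- list(NULL, labels, c("x", "y", "z"))
  structure(list(coords = coords, labels = labels, frame_ids = frame_ids,
                 frame_rate = frame_rate),
            class = "capture_sequence")
}

#' @export
print.capture_sequence <- function(x, ...) {
  cat(sprintf("Capture sequence: %d frames, %d markers (%s), %g frames/s\n",
              n_frames(x), length(x$labels),
              paste(x$labels, collapse = ", "), x$frame_rate))
  invisible(x)
}

#' @rdname capture_sequence
#' @param x a `capture_sequence` or `pose_series`.
#' @export
n_frames <- function(x) UseMethod("n_frames")

#' @export
n_frames.capture_sequence <- function(x) dim(x$coords)[1]

#' @export
n_frames.pose_series <- function(x) length(x$valid)

#' Extract one frame of a capture as labeled points
#'
#' Markers with any non-finite coordinate in that frame are omitted.
#' @param capture a `capture_sequence`.
#' @param i frame index (position, not frame_id).
#' @return `labeled_points` for the usable markers of frame `i`.
#' @export
capture_frame <- function(capture, i) {
  m <- capture$coords[i, , , drop = TRUE]
  if (is.null(dim(m))) m <- matrix(m, ncol = 3, dimnames = list(capture$labels, NULL))
  ok <- apply(is.finite(m), 1, all)
  if (!any(ok)) stop("capture_frame: no usable markers in frame ", i)
  labeled_points(m[ok, , drop = FALSE], capture$labels[ok],
                 frame_id = capture$frame_ids[i])
}

#' Per-frame pose series
#'
#' The result of registering the marker reference configuration onto every
#' capture frame: one rigid pose per frame plus its fit residual. Frames where
#' fewer than three markers were usable are flagged invalid and carried as
#' gaps.
#'
#' @param rotations 3x3xn array of rotation matrices.
#' @param translations n x 3 matrix (mm).
#' @param frame_rate Hz.
#' @param residual_rmsd per-frame fit RMSD (mm), `NA` at invalid frames.
#' @param valid logical vector, `FALSE` at flagged frames.
#' @param frame_ids integer frame numbers.
#' @return Object of class `pose_series`.
#' @export
pose_series <- function(rotations, translations, frame_rate,
                        residual_rmsd = NULL, valid = NULL, frame_ids = NULL) {
  n <- dim(rotations)[3]
  stopifnot(nrow(translations) == n)
  if (is.null(valid)) valid <- rep(TRUE, n)
  if (is.null(residual_rmsd)) residual_rmsd <- rep(NA_real_, n)
  if (is.null(frame_ids)) frame_ids <- seq_len(n)
  for (i in which(valid)) {
    R <- rotations[, , i]
    if (max(abs(crossprod(R) - diag(3))) > 1e-9 || abs(det(R) - 1) > 1e-9)
      stop("pose_series: invalid rotation at frame ", i)
  }
  structure(list(rotations = rotations, translations = as.matrix(translations),
                 frame_rate = frame_rate, residual_rmsd = residual_rmsd,
                 valid = valid, frame_ids = as.integer(frame_ids)),
            class = "pose_series")
}

#' @export
print.pose_series <- function(x, ...) {
  cat(sprintf(
    "Pose series: %d frames at %g Hz, %d invalid, mean fit RMSD %.4g mm\n",
    n_frames(x), x$frame_rate, sum(!x$valid),
    mean(x$residual_rmsd[x$valid], na.rm = TRUE)))
  invisible(x)
}

#' Extract one pose from a pose series
#' @param ps a `pose_series`.
#' @param i frame index.
#' @return `rigid_pose`, or `NULL` when frame `i` is flagged invalid.
#' @export
pose_at <- function(ps, i) {
  if (!ps$valid[i]) return(NULL)
  rigid_pose(ps$rotations[, , i], ps$translations[i, ])
}

#' Estimate the mandibular pose for every capture frame
#'
#' Runs [fit_rigid()] of the marker reference configuration (anatomical / CT
#' frame) onto each frame's observed markers, yielding the per-frame CT-to-
#' capture pose. Frames with missing markers fall back to the usable subset
#' when at least three non-collinear markers remain; otherwise the frame is
#' flagged invalid (a gap), not interpolated.
#'
#' @param capture a `capture_sequence`.
#' @param reference `labeled_points` giving marker coordinates in the
#'   anatomical frame; labels must be a subset of the capture labels.
#' @param interpolate fill flagged frames by linear interpolation of the
#'   translation and spherical-linear interpolation of the rotation between
#'   the nearest valid neighbours (default `FALSE`).
#' @return A [pose_series()].
#' @export
estimate_pose_series <- function(capture, reference, interpolate = FALSE) {
  stopifnot(inherits(capture, "capture_sequence"),
            inherits(reference, "labeled_points"))
  if (!all(reference$labels %in% capture$labels))
    stop("estimate_pose_series: reference labels missing from capture: ",
         paste(setdiff(reference$labels, capture$labels), collapse = ", "))
  n <- n_frames(capture)
  rot <- array(NA_real_, c(3, 3, n))
  tra <- matrix(NA_real_, n, 3)
  rmsd <- rep(NA_real_, n)
  valid <- rep(FALSE, n)
  for (i in seq_len(n)) {
    m <- matrix(capture$coords[i, reference$labels, ], ncol = 3,
                dimnames = list(reference$labels, NULL))
    ok <- apply(is.finite(m), 1, all)
    if (sum(ok) < 3L) next
    obs <- labeled_points(m[ok, , drop = FALSE], reference$labels[ok])
    p <- tryCatch(fit_rigid(reference, obs), error = function(e) NULL)
    if (is.null(p)) next
    rot[, , i] <- p$rotation
    tra[i, ] <- p$translation
    rmsd[i] <- attr(p, "residual_rmsd")
    valid[i] <- TRUE
  }
  if (!any(valid))
    stop("estimate_pose_series: no frame had >= 3 usable markers")
  ps <- pose_series(rot, tra, capture$frame_rate, rmsd, valid,
                    capture$frame_ids)
  if (interpolate) ps <- interpolate_pose_series(ps) else ps
}

#' Fill invalid frames of a pose series by interpolation
#'
#' Linear interpolation on the translation and spherical-linear (quaternion)
#' interpolation on the rotation between the nearest valid frames. Leading or
#' trailing gaps are filled by the nearest valid pose. Filled frames keep
#' `valid = FALSE`... they remain marked as reconstructed, with the fill noted
#' in the `interpolated` attribute.
#'
#' @param ps a `pose_series`.
#' @return `pose_series` with gaps filled; attribute `interpolated` gives the
#'   filled frame indices.
#' @export
interpolate_pose_series <- function(ps) {
  bad <- which(!ps$valid)
  if (!length(bad)) return(ps)
  good <- which(ps$valid)
  if (!length(good)) stop("interpolate_pose_series: no valid frames")
  for (i in bad) {
    lo <- max(good[good < i], -Inf)
    hi <- min(good[good > i], Inf)
    if (!is.finite(lo)) { src <- hi
      ps$rotations[, , i] <- ps$rotations[, , src]
      ps$translations[i, ] <- ps$translations[src, ]
    } else if (!is.finite(hi)) { src <- lo
      ps$rotations[, , i] <- ps$rotations[, , src]
      ps$translations[i, ] <- ps$translations[src, ]
    } else {
      u <- (i - lo) / (hi - lo)
      ps$translations[i, ] <- (1 - u) * ps$translations[lo, ] +
        u * ps$translations[hi, ]
      q <- .quat_slerp(.rot_to_quat(ps$rotations[, , lo]),
                       .rot_to_quat(ps$rotations[, , hi]), u)
      ps$rotations[, , i] <- .quat_to_rot(q)
    }
  }
  attr(ps, "interpolated") <- bad
  ps
}
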