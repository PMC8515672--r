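#' Read and write marker trajectory CSV
#'
#' Long-format marker interchange: columns `frame`, `time_ms`, `label`,
#' `x_mm`, `y_mm`, `z_mm`; comma-separated, `.` decimal separator, UTF-8,
#' header row. Round trips are lossless to better than 1e-9 mm. Malformed
#' rows are reported with their line numbers.
#'
#' @param capture a `capture_sequence`.
#' @param path CSV path.
#' @return `read_markers` returns a `capture_sequence`; `write_markers`
#'   returns `path` invisibly.
#' @export
write_markers <- function(capture, path) {
  stopifnot(inherits(capture, "capture_sequence"))
  n <- n_frames(capture)
  labs <- capture$labels
  d <- data.frame(
    frame = rep(capture$frame_ids, each = length(labs)),
    time_ms = rep((capture$frame_ids - capture$frame_ids[1]) /
                    capture$frame_rate * 1000, each = length(labs)),
    label = rep(labs, n),
    x_mm = as.vector(t(capture$coords[, , 1])),
    y_mm = as.vector(t(capture$coords[, , 2])),
    z_mm = as.vector(t(capture$coords[, , 3])))
  .write_csv(d, path)
  invisible(path)
}

#' @rdname write_markers
#' @param frame_rate frames per second; when `NULL`, inferred from the
#'   `time_ms` column.
#' @export
read_markers <- function(path, frame_rate = NULL) {
  d <- .read_csv_checked(path, c("frame", "time_ms", "label", "x_mm", "y_mm",
                                 "z_mm"),
                         numeric_cols = c("frame", "time_ms", "x_mm", "y_mm",
                                          "z_mm"))
  if (anyDuplicated(d[c("frame", "label")])) {
    dup <- which(duplicated(d[c("frame", "label")]))[1]
    stop("read_markers: duplicate (frame,label) pair at data line ", dup,
         " of ", path)
  }
  frames <- sort(unique(d$frame))
  labs <- unique(d$label)
  if (is.null(frame_rate)) {
    tu <- sort(unique(d$time_ms))
    if (length(tu) < 2)
      stop("read_markers: cannot infer frame rate from a single frame; ",
           "pass frame_rate")
    frame_rate <- 1000 / stats::median(diff(tu))
  }
  coords <- array(NA_real_, c(length(frames), length(labs), 3),
                  dimnames = list(NULL, labs, c("x", "y", "z")))
  fi <- match(d$frame, frames)
  li <- match(d$label, labs)
  coords[cbind(fi, li, 1L)] <- d$x_mm
  coords[cbind(fi, li, 2L)] <- d$y_mm
  coords[cbind(fi, li, 3L)] <- d$z_mm
  capture_sequence(coords, frame_rate, frame_ids = frames)
}

#' Read and write labeled point CSV (markers, landmarks)
#'
#' Columns `label`, `x_mm`, `y_mm`, `z_mm`.
#' @param points a `labeled_points`.
#' @param path CSV path.
#' @export
write_points <- function(points, path) {
  stopifnot(inherits(points, "labeled_points"))
  .write_csv(data.frame(label = points$labels, x_mm = points$points[, 1],
                        y_mm = points$points[, 2], z_mm = points$points[, 3]),
             path)
  invisible(path)
}

#' @rdname write_points
#' @export
read_points <- function(path) {
  d <- .read_csv_checked(path, c("label", "x_mm", "y_mm", "z_mm"),
                         numeric_cols = c("x_mm", "y_mm", "z_mm"))
  labeled_points(cbind(d$x_mm, d$y_mm, d$z_mm), d$label)
}

#' Read and write EMG CSV
#'
#' Columns `time_ms` plus one column per channel (µV). The capture
#' synchronization offset travels in a `# sync_offset_ms:` comment line so
#' misaligned acquisitions remain representable in the file itself.
#'
#' @param record an [emg_record()].
#' @param path CSV path.
#' @export
write_emg <- function(record, path) {
  stopifnot(inherits(record, "emg_record"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# sync_offset_ms: %.9g", record$sync_offset_ms), con)
  d <- data.frame(time_ms = record$t_ms, record$signals, check.names = FALSE)
  utils::write.csv(d, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_emg
#' @export
read_emg <- function(path) {
  if (!file.exists(path)) stop("read_emg: no such file: ", path)
  first <- readLines(path, n = 1)
  sync <- 0
  if (grepl("^#", first)) {
    m <- regmatches(first, regexec("sync_offset_ms:\\s*([-0-9.eE+]+)", first))[[1]]
    if (length(m) == 2) sync <- as.numeric(m[2])
  }
  d <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  if (!"time_ms" %in% names(d))
    stop("read_emg: missing column 'time_ms' in ", path)
  if (ncol(d) < 2) stop("read_emg: no channel columns in ", path)
  t <- d$time_ms
  sr <- 1000 / stats::median(diff(t))
  emg_record(as.matrix(d[setdiff(names(d), "time_ms")]), sr,
             sync_offset_ms = sync)
}

#' Write a trajectory CSV
#'
#' Columns `frame`, `time_ms`, `landmark`, `x_mm`, `y_mm`, `z_mm`.
#' @param traj a [trajectory()].
#' @param path CSV path.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  .write_csv(data.frame(frame = seq_len(nrow(traj$coords)),
                        time_ms = traj$t_ms, landmark = traj$landmark,
                        x_mm = traj$coords[, 1], y_mm = traj$coords[, 2],
                        z_mm = traj$coords[, 3]), path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  d <- .read_csv_checked(path, c("frame", "time_ms", "landmark", "x_mm",
                                 "y_mm", "z_mm"),
                         numeric_cols = c("frame", "time_ms"))
  fr <- if (nrow(d) > 1) 1000 / stats::median(diff(d$time_ms)) else 1
  trajectory(cbind(d$x_mm, d$y_mm, d$z_mm), d$landmark[1], fr)
}

#' Write a pose series CSV
#'
#' Columns `frame`, `time_ms`, `valid`, `rmsd_mm`, the nine rotation entries
#' `r11`..`r33` (row-major) and `tx_mm`, `ty_mm`, `tz_mm`.
#' @param ps a [pose_series()].
#' @param path CSV path.
#' @export
write_pose_series <- function(ps, path) {
  stopifnot(inherits(ps, "pose_series"))
  n <- n_frames(ps)
  R <- t(apply(ps$rotations, 3, function(m) as.vector(t(m))))
  colnames(R) <- paste0("r", c(11, 12, 13, 21, 22, 23, 31, 32, 33))
  d <- data.frame(frame = ps$frame_ids,
                  time_ms = (ps$frame_ids - ps$frame_ids[1]) /
                    ps$frame_rate * 1000,
                  valid = as.integer(ps$valid), rmsd_mm = ps$residual_rmsd,
                  R, tx_mm = ps$translations[, 1],
                  ty_mm = ps$translations[, 2], tz_mm = ps$translations[, 3])
  .write_csv(d, path)
  invisible(path)
}

#' @rdname write_pose_series
#' @param frame_rate frames per second; inferred from `time_ms` when `NULL`.
#' @export
read_pose_series <- function(path, frame_rate = NULL) {
  rc <- paste0("r", c(11, 12, 13, 21, 22, 23, 31, 32, 33))
  d <- .read_csv_checked(path, c("frame", "time_ms", "valid", rc, "tx_mm",
                                 "ty_mm", "tz_mm"),
                         numeric_cols = c("frame", "time_ms", rc))
  if (is.null(frame_rate))
    frame_rate <- 1000 / stats::median(diff(d$time_ms))
  n <- nrow(d)
  rot <- array(NA_real_, c(3, 3, n))
  for (i in seq_len(n))
    rot[, , i] <- matrix(as.numeric(d[i, rc]), 3, 3, byrow = TRUE)
  pose_series(rot, cbind(d$tx_mm, d$ty_mm, d$tz_mm), frame_rate,
              residual_rmsd = d$rmsd_mm, valid = d$valid > 0,
              frame_ids = d$frame)
}

#' Write an occlusion series CSV
#'
#' Columns `frame`, `time_ms`, `clearance_mm`, `contact` (0/1).
#' @param occlusion an [occlusion_series()].
#' @param path CSV path.
#' @export
write_occlusion <- function(occlusion, path) {
  stopifnot(inherits(occlusion, "occlusion_series"))
  .write_csv(data.frame(frame = seq_along(occlusion$clearance_mm),
                        time_ms = occlusion$t_ms,
                        clearance_mm = occlusion$clearance_mm,
                        contact = as.integer(occlusion$contact)), path)
  invisible(path)
}

#' Serialize a rigid pose to/from JSON
#' @param pose a `rigid_pose`.
#' @param path JSON path.
#' @export
write_pose <- function(pose, path) {
  stopifnot(is_rigid_pose(pose))
  jsonlite::write_json(
    list(rotation = pose$rotation, translation = pose$translation,
         residual_rmsd_mm = attr(pose, "residual_rmsd")),
    path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_pose
#' @export
read_pose <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- rigid_pose(matrix(unlist(j$rotation), 3, 3), unlist(j$translation))
  attr(p, "residual_rmsd") <- j$residual_rmsd_mm
  p
}

#' Write synthetic ground truth to JSON
#'
#' Phase boundaries, contact flags, EMG burst windows and the generating
#' motion parameters; consumed by tests and external comparisons.
#' @param truth a `synthetic_truth`.
#' @param path JSON path.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  jsonlite::write_json(list(
    spec = unclass(truth$spec),
    phase_boundaries = truth$phase_boundaries,
    contact_frames = which(truth$contact),
    contact_threshold_mm = truth$contact_threshold,
    gap_mm = truth$gap_mm,
    emg_burst_windows = truth$emg_burst_windows),
    path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# ---- internal CSV helpers (fixed dialect: comma, ".", UTF-8, header) ----

.write_csv <- function(d, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.csv(format(d, digits = 15, scientific = FALSE, trim = TRUE,
                          justify = "none"),
                   con, row.names = FALSE, quote = FALSE)
}

.read_csv_checked <- function(path, required, numeric_cols = character()) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                       comment.char = "#")
  missing <- setdiff(required, names(d))
  if (length(missing))
    stop("parse error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  for (cn in numeric_cols) {
    v <- suppressWarnings(as.numeric(d[[cn]]))
    bad <- which(is.na(v) & !(d[[cn]] %in% c("NA", "")))
    if (length(bad))
      stop("parse error in ", path, ": non-numeric value '", d[[cn]][bad[1]],
           "' in column ", cn, " at data line ", bad[1],
           " (file line ", bad[1] + 1L, ")")
    d[[cn]] <- v
  }
  for (cn in setdiff(names(d), c(numeric_cols, "label", "landmark", "channel",
                                 "phase", "axis")))
    d[[cn]] <- utils::type.convert(d[[cn]], as.is = TRUE)
  d
}
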