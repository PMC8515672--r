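#' Calibration-grid accuracy protocol
#'
#' Re-creates the working-volume accuracy test of marker-based tracking: a
#' marker assembly is commanded to every node of a cubic grid (origin
#' included, so an extent of 3 mm in 0.5-mm increments gives 7^3 = 343
#' points), capture noise is added to each marker coordinate, the assembly
#' position is estimated through the rigid-fit pipeline, and the measured
#' displacement from the (equally estimated) origin is compared with the
#' commanded displacement. Per-axis percent error is
#' `|measured - commanded| / |commanded| * 100`, evaluated on nonzero
#' commanded components only (zero components admit no relative error).
#'
#' @param extent_mm cube edge length (mm); must be an integer multiple of
#'   `step_mm`.
#' @param step_mm grid increment (mm), > 0.
#' @param noise_sigma_mm isotropic marker noise SD (mm).
#' @param seed RNG seed.
#' @param marker_geometry marker assembly ([default_marker_geometry()]).
#' @return Object of class `calibration_result`: data.frame `points`
#'   (commanded and measured displacements plus per-axis percent errors),
#'   `mean_percent_error` per axis, `grid_dims`, `n_points`.
#' @export
accuracy_grid <- function(extent_mm = 3, step_mm = 0.5, noise_sigma_mm = 0,
                          seed = NULL,
                          marker_geometry = default_marker_geometry()) {
  if (step_mm <= 0) stop("accuracy_grid: step_mm must be positive")
  k <- extent_mm / step_mm
  if (abs(k - round(k)) > 1e-9)
    stop("accuracy_grid: extent_mm must be an integer multiple of step_mm")
  k <- as.integer(round(k))
  ax <- seq(0, extent_mm, by = step_mm)
  grid <- expand.grid(x = ax, y = ax, z = ax, KEEP.OUT.ATTRS = FALSE)
  ref <- marker_geometry
  measure <- function(offset, noise) {
    obs <- ref$points + matrix(offset, nrow(ref$points), 3, byrow = TRUE) +
      noise
    fit <- fit_rigid(ref, labeled_points(obs, ref$labels))
    as.numeric(fit$rotation %*% colMeans(ref$points)) + fit$translation
  }
  nm <- nrow(ref$points)
  res <- .with_seed(seed, {
    origin <- measure(c(0, 0, 0),
                      matrix(stats::rnorm(nm * 3, 0, noise_sigma_mm), nm, 3))
    t(apply(grid, 1, function(g)
      measure(as.numeric(g),
              matrix(stats::rnorm(nm * 3, 0, noise_sigma_mm), nm, 3)) -
        origin))
  })
  colnames(res) <- c("measured_x", "measured_y", "measured_z")
  pe <- abs(res - as.matrix(grid)) / abs(as.matrix(grid)) * 100
  pe[as.matrix(grid) == 0] <- NA_real_
  colnames(pe) <- c("pe_x", "pe_y", "pe_z")
  structure(list(
    points = cbind(stats::setNames(grid, c("commanded_x", "commanded_y",
                                           "commanded_z")),
                   as.data.frame(res), as.data.frame(pe)),
    mean_percent_error = colMeans(pe, na.rm = TRUE),
    grid_dims = rep(k + 1L, 3L),
    n_points = nrow(grid),
    step_mm = step_mm, extent_mm = extent_mm,
    noise_sigma_mm = noise_sigma_mm),
    class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "Calibration grid: %d points (%s), step %g mm, noise sigma %g mm\n",
    x$n_points, paste(x$grid_dims, collapse = " x "), x$step_mm,
    x$noise_sigma_mm))
  pe <- x$mean_percent_error
  cat(sprintf("  mean percent error: x %.3g%%, y %.3g%%, z %.3g%%\n",
              pe[1], pe[2], pe[3]))
  invisible(x)
}

#' Step-resolution protocol
#'
#' Simulates the dwell-step-dwell displacement test along each axis: the
#' marker assembly dwells, is stepped by `step_mm`, and dwells again, with
#' capture noise on every frame. A step is resolved when the change in the
#' measured displacement exceeds the peak-to-peak fluctuation of the dwell
#' segments.
#'
#' @param step_mm commanded step (mm), > 0.
#' @param noise_sigma_mm marker noise SD (mm).
#' @param n_dwell_frames frames per dwell segment.
#' @param seed RNG seed.
#' @param marker_geometry marker assembly.
#' @return data.frame per axis: `axis`, `step_mm`, `measured_change_mm`,
#'   `fluctuation_mm` (peak-to-peak), `resolved`.
#' @export
resolution_test <- function(step_mm = 0.005, noise_sigma_mm = 0,
                            n_dwell_frames = 50, seed = NULL,
                            marker_geometry = default_marker_geometry()) {
  if (step_mm <= 0) stop("resolution_test: step_mm must be positive")
  noise <- .with_seed(seed, .resolution_noise(n_dwell_frames, noise_sigma_mm,
                                              marker_geometry))
  do.call(rbind, lapply(1:3, function(ax)
    .resolve_axis(ax, step_mm, noise, marker_geometry)))
}

# per-frame marker noise for both dwell segments of all three axes,
# generated once so that step sweeps reuse identical realizations
.resolution_noise <- function(n_dwell, sigma, geometry) {
  nm <- nrow(geometry$points)
  lapply(1:3, function(ax)
    lapply(1:2, function(seg)
      lapply(seq_len(n_dwell), function(i)
        matrix(stats::rnorm(nm * 3, 0, sigma), nm, 3))))
}

.resolve_axis <- function(ax, step_mm, noise, geometry) {
  ref <- geometry
  measure <- function(offset, nz) {
    obs <- ref$points + matrix(offset, nrow(ref$points), 3, byrow = TRUE) + nz
    fit <- fit_rigid(ref, labeled_points(obs, ref$labels))
    (as.numeric(fit$rotation %*% colMeans(ref$points)) + fit$translation)[ax]
  }
  off <- c(0, 0, 0)
  pre <- vapply(noise[[ax]][[1]], function(nz) measure(off, nz), numeric(1))
  off[ax] <- step_mm
  post <- vapply(noise[[ax]][[2]], function(nz) measure(off, nz), numeric(1))
  change <- abs(mean(post) - mean(pre))
  fluct <- max(diff(range(pre)), diff(range(post)))
  data.frame(axis = c("x", "y", "z")[ax], step_mm = step_mm,
             measured_change_mm = change, fluctuation_mm = fluct,
             resolved = change > fluct)
}

#' Minimal resolvable step by bisection
#'
#' Finds, per axis, the smallest step that the dwell-step-dwell criterion
#' resolves at a given noise level. The same noise realization (fixed by
#' `seed`) is reused for every candidate step, making the criterion monotone
#' in the step size so that bisection is valid and agrees with a direct
#' sweep.
#'
#' @param noise_sigma_mm marker noise SD (mm).
#' @param n_dwell_frames frames per dwell segment.
#' @param seed RNG seed.
#' @param lower_mm,upper_mm bracketing step sizes (mm).
#' @param tol_mm bisection tolerance (mm).
#' @param marker_geometry marker assembly.
#' @return named numeric vector: minimal resolvable step per axis (mm).
#' @export
min_resolvable_step <- function(noise_sigma_mm, n_dwell_frames = 50,
                                seed = NULL, lower_mm = 1e-6, upper_mm = 1,
                                tol_mm = 1e-5,
                                marker_geometry = default_marker_geometry()) {
  noise <- .with_seed(seed, .resolution_noise(n_dwell_frames, noise_sigma_mm,
                                              marker_geometry))
  vapply(1:3, function(ax) {
    resolved_at <- function(s)
      .resolve_axis(ax, s, noise, marker_geometry)$resolved
    if (resolved_at(lower_mm)) return(lower_mm)
    if (!resolved_at(upper_mm)) return(NA_real_)
    lo <- lower_mm
    hi <- upper_mm
    while (hi - lo > tol_mm) {
      mid <- (lo + hi) / 2
      if (resolved_at(mid)) hi <- mid else lo <- mid
    }
    hi
  }, numeric(1)) -> out
  names(out) <- c("x", "y", "z")
  out
}
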