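#' Chewing-motion specification
#'
#' Parameters of the synthetic masticatory cycle. The cycle is anchored at the
#' maximum jaw-closing (intercuspal) position at phase 0; the jaw then opens,
#' passes its most anterior point, reaches maximum opening, closes while
#' moving posteriorly, and re-enters tooth contact for the final
#' `occlusal_fraction` of the cycle.
#'
#' @param n_cycles number of successive chewing cycles.
#' @param cycle_ms duration of one cycle (ms). 150 ms at 200 frames/s gives
#'   the canonical 30 frames (5 ms apart) per cycle.
#' @param gape_mm peak vertical opening of the molar landmark (mm).
#' @param ap_excursion_mm peak antero-posterior excursion scale (mm).
#' @param lateral_mm peak added lateral (transverse) deviation (mm).
#' @param occlusal_fraction fraction of the cycle spent in occlusal contact.
#' @param working_side chewing side, `"left"` or `"right"`.
#' @param frame_rate capture frame rate (Hz).
#' @param occlusal_depth_mm residual vertical closing during the occlusal
#'   phase (mm); must stay below the contact threshold so that contact holds
#'   throughout the occlusal phase.
#' @param seed RNG seed recorded with the spec (the motion itself is
#'   deterministic; the seed feeds the noise generators that consume a spec).
#' @return Object of class `motion_spec`.
#' @export
motion_spec <- function(n_cycles = 10, cycle_ms = 150, gape_mm = 2,
                        ap_excursion_mm = 1.5, lateral_mm = 0.3,
                        occlusal_fraction = 0.1,
                        working_side = c("left", "right"), frame_rate = 200,
                        occlusal_depth_mm = 0.02, seed = 1L) {
  working_side <- match.arg(working_side)
  stopifnot(n_cycles >= 1, cycle_ms > 0, gape_mm >= 0, ap_excursion_mm >= 0,
            lateral_mm >= 0, occlusal_fraction >= 0, occlusal_fraction < 1,
            frame_rate > 0, occlusal_depth_mm >= 0)
  structure(list(n_cycles = n_cycles, cycle_ms = cycle_ms, gape_mm = gape_mm,
                 ap_excursion_mm = ap_excursion_mm, lateral_mm = lateral_mm,
                 occlusal_fraction = occlusal_fraction,
                 working_side = working_side, frame_rate = frame_rate,
                 occlusal_depth_mm = occlusal_depth_mm, seed = seed),
            class = "motion_spec")
}

# canonical anatomical geometry shared by the motion generator and the toy
# dentition (CT frame, mm; +X anterior, +Y animal-left, +Z superior;
# intercuspal position = identity pose)
.jaw_geometry <- function(working_side = "left") {
  sgn <- if (working_side == "left") 1 else -1
  landmarks <- rbind(
    incisor_edge = c(4.3, 0, 0.4),
    molar_cusp   = c(0, sgn * 1.5, 1.1),
    condyle_left = c(-4, 3.5, 1.5),
    condyle_right = c(-4, -3.5, 1.5))
  list(
    landmarks = labeled_points(landmarks),
    condyle_center = c(-4, 0, 1.5),
    condyle_halfwidth = 3.5,
    molar = landmarks["molar_cusp", ],
    working_sign = sgn)
}

#' Default mandibular marker configuration
#'
#' Four non-coplanar reflective markers on the lower border of the mandible
#' (CT frame, mm), mirroring the four-marker assembly of the tracking system.
#' @return `labeled_points` with markers `m1`..`m4`.
#' @export
default_marker_geometry <- function() {
  labeled_points(rbind(m1 = c(2, 0, -3), m2 = c(-1, 1.2, -3.2),
                       m3 = c(-1, -1.2, -3.2), m4 = c(0.5, 0, -4.5)))
}

# piecewise-C1 cycle profiles ------------------------------------------------

# vertical molar opening depth (mm) as a function of cycle phase in [0,1)
.gap_profile <- function(phi, gape, phi_o, phi_c, delta) {
  d <- numeric(length(phi))
  a <- phi < phi_o
  d[a] <- gape * (1 - cos(pi * phi[a] / phi_o)) / 2
  b <- phi >= phi_o & phi < phi_c
  d[b] <- delta + (gape - delta) *
    (1 + cos(pi * (phi[b] - phi_o) / (phi_c - phi_o))) / 2
  cc <- phi >= phi_c
  d[cc] <- delta * (1 + cos(pi * (phi[cc] - phi_c) / (1 - phi_c))) / 2
  d
}

# condylar advance bump peaking at peak_frac * phi_c, zero from phi_c on;
# beta-shaped so both ends have zero slope (no jerk at cycle boundaries)
.advance_bump <- function(phi, phi_c, peak_frac) {
  if (peak_frac <= 0.5) {
    a <- 2; b <- 2 * (1 - peak_frac) / peak_frac
  } else {
    b <- 2; a <- 2 * peak_frac / (1 - peak_frac)
  }
  u <- pmin(phi / phi_c, 1)
  (u^a * (1 - u)^b) / (peak_frac^a * (1 - peak_frac)^b)
}

# occlusal retrusion dip: 0 before phi_o, rises to 1 at phi_c, back to 0 at 1
.occlusal_dip <- function(phi, phi_o, phi_c) {
  r <- numeric(length(phi))
  b <- phi >= phi_o & phi < phi_c
  r[b] <- sin(pi / 2 * (phi[b] - phi_o) / (phi_c - phi_o))^2
  cc <- phi >= phi_c
  r[cc] <- cos(pi / 2 * (phi[cc] - phi_c) / (1 - phi_c))^2
  r
}

# pitch angle (rad) producing a molar drop of `drop` mm about the condylar
# axis: solves dx*sin(th) - dz*(cos(th)-1) = drop in closed form
.pitch_for_drop <- function(drop, dx, dz) {
  a <- dx
  b <- -dz
  r <- sqrt(a^2 + b^2)
  alpha <- atan2(b, a)
  asin(pmin(1, pmax(-1, (drop + b) / r))) - alpha
}

#' Simulate ground-truth chewing motion
#'
#' Generates a smooth periodic 6-DOF mandibular pose sequence (CT frame;
#' identity = intercuspal position) built from a pitch rotation about the
#' intercondylar axis, an asymmetric yaw that advances the balancing-side
#' condyle through the whole opening phase while the working-side condyle
#' reverses mid-opening, and translations for the antero-posterior loop and
#' lateral deviation. Per cycle the molar-landmark trajectory has exactly one
#' maximum-closing, most-anterior, maximum-opening and most-posterior point,
#' in that cyclic order, and the final `occlusal_fraction` of the cycle keeps
#' the cusp within `occlusal_depth_mm` of the intercuspal contact.
#'
#' @param spec a [motion_spec()].
#' @return Object of class `synthetic_truth`: ground-truth `pose_series`,
#'   per-frame analytic occlusal gap `gap_mm`, contact flags/intervals at the
#'   default 0.05-mm threshold, per-cycle phase-boundary frames, ground-truth
#'   landmark paths, and EMG burst windows (capture time, ms).
#' @export
simulate_jaw_motion <- function(spec) {
  stopifnot(inherits(spec, "motion_spec"))
  g <- .jaw_geometry(spec$working_side)
  n <- round(spec$n_cycles * spec$cycle_ms / 1000 * spec$frame_rate)
  t_ms <- (seq_len(n) - 1) / spec$frame_rate * 1000
  phi <- (t_ms / spec$cycle_ms) %% 1
  cycle <- floor(t_ms / spec$cycle_ms + 1e-12)

  phi_c <- 1 - spec$occlusal_fraction        # contact onset phase
  phi_o <- 2 / 3 * phi_c                     # maximum opening phase
  delta <- min(spec$occlusal_depth_mm, spec$gape_mm / 2)

  dgap <- .gap_profile(phi, spec$gape_mm, phi_o, phi_c, delta)
  kappa <- 0.25                              # translation share of opening
  dm <- g$molar - g$condyle_center           # molar lever arm
  theta <- .pitch_for_drop((1 - kappa) * dgap, dm[1], dm[3])

  A_w <- spec$ap_excursion_mm
  A_b <- 0.8 * spec$ap_excursion_mm
  A_o <- 0.25 * spec$ap_excursion_mm
  x_work <- A_w * .advance_bump(phi, phi_c, 1 / 3)
  x_bal <- A_b * .advance_bump(phi, phi_c, 2 / 3)
  dip <- A_o * .occlusal_dip(phi, phi_o, phi_c)
  w <- g$condyle_halfwidth
  # working side carries the earlier-peaking condylar advance
  if (spec$working_side == "left") {
    sin_psi <- pmin(1, pmax(-1, (x_bal - x_work) / (2 * w)))
  } else {
    sin_psi <- pmin(1, pmax(-1, (x_work - x_bal) / (2 * w)))
  }
  psi <- asin(sin_psi)
  u_x <- (x_work + x_bal) / 2 - dip
  u_y <- g$working_sign * spec$lateral_mm * sin(pi * pmin(phi / phi_c, 1))^2
  u_z <- -kappa * dgap

  c0 <- g$condyle_center
  rot <- array(NA_real_, c(3, 3, n))
  tra <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    R <- rot_z(psi[i]) %*% rot_y(theta[i])
    rot[, , i] <- R
    tra[i, ] <- c0 - as.numeric(R %*% c0) + c(u_x[i], u_y[i], u_z[i])
  }
  ps <- pose_series(rot, tra, spec$frame_rate)

  # ground-truth landmark paths
  lm <- g$landmarks$points
  paths <- lapply(rownames(lm), function(nm) {
    p <- lm[nm, ]
    out <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("x", "y", "z")))
    for (i in seq_len(n))
      out[i, ] <- as.numeric(rot[, , i] %*% p) + tra[i, ]
    out
  })
  names(paths) <- rownames(lm)

  contact_threshold <- 0.05
  contact <- dgap <= contact_threshold

  boundaries <- NULL
  if (spec$gape_mm > 0) {
    mol <- paths$molar_cusp
    boundaries <- do.call(rbind, lapply(sort(unique(cycle)), function(k) {
      idx <- which(cycle == k)
      z <- mol[idx, 3]; x <- mol[idx, 1]
      max_closing <- idx[which.max(z)]
      max_opening <- idx[which.min(z)]
      post <- idx[idx >= max_opening]
      data.frame(cycle = k + 1L,
                 max_closing = max_closing,
                 most_anterior = idx[which.max(x)],
                 max_opening = max_opening,
                 most_posterior = post[which.min(mol[post, 1])],
                 contact_onset = {
                   cn <- post[contact[post]]
                   if (length(cn)) cn[1] else NA_integer_
                 })
    }))
  }

  # EMG burst windows (capture time, ms): digastric spans the opening phase;
  # the working-side masseter fires in late closing, one tenth of a cycle
  # before contact onset; the balancing-side masseter fires at contact onset;
  # both masseters switch off at maximum closing (cycle end)
  phi_w <- max(phi_o, phi_c - 0.1)
  emg_windows <- do.call(rbind, lapply(seq_len(spec$n_cycles) - 1L, function(k) {
    t0 <- k * spec$cycle_ms
    data.frame(
      channel = c("digastric", "masseter_working", "masseter_balancing"),
      cycle = k + 1L,
      onset_ms = t0 + c(0, phi_w, phi_c) * spec$cycle_ms,
      offset_ms = t0 + c(phi_o, 1, 1) * spec$cycle_ms)
  }))

  structure(list(
    spec = spec, pose_series = ps, t_ms = t_ms, cycle = cycle + 1L,
    phase = list(phi = phi, phi_open = phi_o, phi_contact = phi_c),
    gap_mm = dgap, contact = contact, contact_threshold = contact_threshold,
    phase_boundaries = boundaries, landmark_paths = paths,
    emg_burst_windows = emg_windows, geometry = g),
    class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "Synthetic chewing truth: %d cycles x %g ms, %d frames at %g Hz\n",
    x$spec$n_cycles, x$spec$cycle_ms, n_frames(x$pose_series),
    x$spec$frame_rate))
  cat(sprintf("  gape %.2f mm, AP %.2f mm, working side %s\n",
              x$spec$gape_mm, x$spec$ap_excursion_mm, x$spec$working_side))
  invisible(x)
}

# run code with a temporarily seeded RNG, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Synthesize a marker capture from ground-truth motion
#'
#' Applies each ground-truth pose to the marker reference configuration, maps
#' the result through a fixed mounting pose (the CT-to-capture coordinate
#' change; the capture system's axes are arbitrary relative to the anatomy),
#' and adds isotropic Gaussian coordinate noise.
#'
#' @param truth a `synthetic_truth` from [simulate_jaw_motion()].
#' @param marker_geometry `labeled_points` with at least 3 non-collinear
#'   markers (default [default_marker_geometry()]).
#' @param noise_sigma_mm isotropic Gaussian noise SD per coordinate (mm).
#' @param seed RNG seed for reproducible noise.
#' @param mount `rigid_pose` mapping CT coordinates into capture coordinates;
#'   defaults to a fixed oblique pose so that the two frames genuinely differ.
#' @return `capture_sequence`; the mounting pose is kept in attribute
#'   `"mount"` and the intercuspal (static registration) marker frame in
#'   attribute `"static_frame"`.
#' @export
synth_capture <- function(truth, marker_geometry = default_marker_geometry(),
                          noise_sigma_mm = 0, seed = NULL, mount = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"), noise_sigma_mm >= 0)
  sv <- svd(scale(marker_geometry$points, scale = FALSE), nu = 0, nv = 0)$d
  if (nrow(marker_geometry$points) < 3L || sv[2] < 1e-6)
    stop("synth_capture: degenerate marker geometry (collinear markers)")
  if (is.null(mount))
    mount <- rigid_pose(rot_z(0.35) %*% rot_x(0.2) %*% rot_y(-0.1),
                        c(12, -8, 25))
  ps <- truth$pose_series
  n <- n_frames(ps)
  nm <- nrow(marker_geometry$points)
  coords <- array(NA_real_, c(n, nm, 3),
                  dimnames = list(NULL, marker_geometry$labels, c("x", "y", "z")))
  for (i in seq_len(n)) {
    p <- apply_pose(mount, apply_pose(pose_at(ps, i), marker_geometry$points))
    coords[i, , ] <- p
  }
  if (noise_sigma_mm > 0)
    coords <- coords + .with_seed(seed,
      array(stats::rnorm(length(coords), 0, noise_sigma_mm), dim(coords)))
  cap <- capture_sequence(coords, ps$frame_rate)
  attr(cap, "mount") <- mount
  static <- apply_pose(mount, marker_geometry$points)
  if (noise_sigma_mm > 0)
    static <- static + .with_seed(if (is.null(seed)) NULL else seed + 1L,
      matrix(stats::rnorm(length(static), 0, noise_sigma_mm), nrow(static)))
  attr(cap, "static_frame") <- labeled_points(static, marker_geometry$labels)
  cap
}

# smooth plateau profile: 1 on |u| < half - ramp, cosine fall to 0 at |u| = half
.plateau <- function(u, half, ramp) {
  a <- pmax(0, pmin(1, (half - abs(u)) / ramp))
  ifelse(abs(u) >= half, 0, ifelse(abs(u) <= half - ramp, 1,
                                   sin(pi / 2 * a)^2))
}

#' Toy cusp-and-fossa dentition meshes
#'
#' Builds watertight mandible and maxilla surface blocks that stand in for
#' segmented micro-CT dentition: the maxilla carries an antero-posteriorly
#' elongated molar fossa (central groove) and a downward upper-incisor ridge;
#' the mandible carries a conical molar cusp whose tip touches the fossa
#' ceiling exactly at the intercuspal (identity) pose, and an upward lower-
#' incisor edge kept clear of the upper ridge. Landmark coordinates (incisor
#' edge, molar mesiobuccal cusp, left and right condylar points) are returned
#' in the same CT frame.
#'
#' @param resolution_mm grid edge length of the occlusal surfaces (mm).
#' @param working_side side carrying the toy molar, `"left"` or `"right"`.
#' @param fossa_depth_mm depth of the molar fossa (mm).
#' @param cusp_height_mm height of the molar cusp above its base plane (mm).
#' @param cusp_radius_mm base radius of the conical cusp (mm); kept well
#'   inside the fossa half-width so the cusp never grazes the fossa walls
#'   during normal excursions.
#' @return Object of class `dentition`: list with `mandible` and `maxilla`
#'   (`tri_mesh`, mm, CT frame) and `landmarks` (`labeled_points`).
#' @export
synth_dentition <- function(resolution_mm = 0.05,
                            working_side = c("left", "right"),
                            fossa_depth_mm = 0.1, cusp_height_mm = 0.15,
                            cusp_radius_mm = 0.3) {
  working_side <- match.arg(working_side)
  g <- .jaw_geometry(working_side)
  s <- g$working_sign
  res <- resolution_mm
  mc <- g$molar                              # cusp tip (on-grid by design)
  grid <- function(a, b) seq(min(a, b), max(a, b), by = res)

  # --- maxilla: occlusal surface faces down; solid extends upward ---
  xs <- grid(-2.2, 2.2); ys <- grid(mc[2] - 1, mc[2] + 1)
  Z <- outer(xs, ys, function(x, y)
    1.0 + fossa_depth_mm * .plateau(x, 1.8, 0.15) * .plateau(y - mc[2], 0.45, 0.15))
  max_molar <- .heightfield_block(xs, ys, Z, 2.5)
  xi <- grid(4.0, 5.4); yi <- grid(-0.7, 0.7)
  Zi <- outer(xi, yi, function(x, y)
    1.0 - 0.3 * .plateau(x - 4.7, 0.35, 0.2) * .plateau(y, 0.5, 0.2))
  max_incisor <- .heightfield_block(xi, yi, Zi, 2.5)
  maxilla <- .merge_meshes(max_molar, max_incisor)

  # --- mandible: occlusal surface faces up; solid extends downward ---
  xm <- grid(-2.0, 2.0); ym <- grid(mc[2] - 0.9, mc[2] + 0.9)
  # cusp base plane sits cusp_height below the tip; tip reaches the fossa
  # ceiling (1.0 + fossa_depth) at intercuspal position
  tipz <- 1.0 + fossa_depth_mm
  basez <- tipz - cusp_height_mm
  Zm <- outer(xm, ym, function(x, y) {
    r <- sqrt((x - mc[1])^2 + (y - mc[2])^2)
    basez + cusp_height_mm * pmax(0, 1 - r / cusp_radius_mm)
  })
  man_molar <- .heightfield_block(xm, ym, Zm, -1.5)
  xmi <- grid(3.6, 5.0); ymi <- grid(-0.7, 0.7)
  Zmi <- outer(xmi, ymi, function(x, y)
    0.4 * .plateau(x - 4.3, 0.35, 0.2) * .plateau(y, 0.5, 0.2))
  man_incisor <- .heightfield_block(xmi, ymi, Zmi, -1.5)
  mandible <- .merge_meshes(man_molar, man_incisor)

  structure(list(mandible = mandible, maxilla = maxilla,
                 landmarks = g$landmarks, resolution_mm = res),
            class = "dentition")
}

#' @export
print.dentition <- function(x, ...) {
  cat(sprintf(
    "Toy dentition (%.3g mm resolution): mandible %d faces, maxilla %d faces\n",
    x$resolution_mm, nrow(x$mandible$faces), nrow(x$maxilla$faces)))
  invisible(x)
}

.merge_meshes <- function(a, b) {
  tri_mesh(rbind(a$vertices, b$vertices),
           rbind(a$faces, b$faces + nrow(a$vertices)))
}

#' Synthesize phase-locked EMG
#'
#' Band-limited (100-Hz high-passed Gaussian) activity bursts gated by the
#' ground-truth burst windows of the motion, over a continuous baseline noise
#' floor. The record starts `lead_ms` before the capture so that a quiet
#' baseline segment precedes all programmed activity; the capture-
#' synchronization offset therefore equals `lead_ms`.
#'
#' @param truth a `synthetic_truth`.
#' @param channels channel subset (default: all three muscles).
#' @param sampling_hz EMG sampling rate (Hz); must exceed twice the 100-Hz
#'   signal band.
#' @param burst_amplitude_uv RMS amplitude of burst activity (µV).
#' @param noise_amplitude_uv RMS amplitude of the baseline noise floor (µV).
#' @param seed RNG seed.
#' @param lead_ms quiet lead-in before capture start (ms).
#' @param tail_ms quiet run-out after capture end (ms), so bursts ending at
#'   the last frame are recorded in full.
#' @param ramp_ms raised-cosine burst on/off ramp (ms).
#' @return An [emg_record()]; attribute `"burst_windows_emg_ms"` holds the
#'   true windows on the EMG time axis.
#' @export
synth_emg <- function(truth,
                      channels = c("masseter_working", "masseter_balancing",
                                   "digastric"),
                      sampling_hz = 1000, burst_amplitude_uv = 200,
                      noise_amplitude_uv = 8, seed = NULL, lead_ms = 250,
                      tail_ms = 50, ramp_ms = 2) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (sampling_hz <= 2 * 100)
    stop("synth_emg: sampling_hz must exceed twice the 100-Hz signal band")
  dur_ms <- lead_ms + tail_ms + n_frames(truth$pose_series) /
    truth$pose_series$frame_rate * 1000
  nsamp <- ceiling(dur_ms / 1000 * sampling_hz)
  t_ms <- (seq_len(nsamp) - 1) / sampling_hz * 1000
  win <- truth$emg_burst_windows
  win <- win[win$channel %in% channels, , drop = FALSE]
  win$onset_ms <- win$onset_ms + lead_ms
  win$offset_ms <- win$offset_ms + lead_ms

  bp <- signal::butter(4, 100 / (sampling_hz / 2), type = "high")
  hp_noise <- function() {
    x <- signal::filtfilt(bp, stats::rnorm(nsamp))
    x / stats::sd(x)
  }
  sig <- .with_seed(seed, {
    out <- sapply(channels, function(ch) {
      env <- numeric(nsamp)
      for (j in which(win$channel == ch)) {
        on <- win$onset_ms[j]; off <- win$offset_ms[j]
        inw <- t_ms >= on & t_ms <= off
        e <- rep(1, sum(inw))
        tt <- t_ms[inw]
        rise <- tt < on + ramp_ms
        fall <- tt > off - ramp_ms
        e[rise] <- sin(pi / 2 * (tt[rise] - on) / ramp_ms)^2
        e[fall] <- sin(pi / 2 * (off - tt[fall]) / ramp_ms)^2
        env[inw] <- pmax(env[inw], e)
      }
      burst <- burst_amplitude_uv * hp_noise() * env
      floorn <- if (noise_amplitude_uv > 0)
        noise_amplitude_uv * hp_noise() else 0
      burst + floorn
    })
    out
  })
  sig <- matrix(sig, nsamp, length(channels),
                dimnames = list(NULL, channels))
  rec <- emg_record(sig, sampling_hz, sync_offset_ms = lead_ms)
  attr(rec, "burst_windows_emg_ms") <- win
  rec
}

#' Write a full synthetic fixture set to disk
#'
#' Generates truth motion, capture, dentition and EMG with one seed and
#' writes every interchange file the pipeline reads: marker CSV, static-
#' registration marker CSV, mandible/maxilla STL, marker-reference and
#' landmark CSV, EMG CSV, and a truth JSON.
#'
#' @param dir output directory (created if missing).
#' @param spec a [motion_spec()].
#' @param noise_sigma_mm capture noise SD (mm).
#' @param seed master seed; stage seeds are derived from it.
#' @param resolution_mm dentition mesh resolution (mm).
#' @return Invisibly, a named list of the written paths.
#' @export
write_synthetic_fixtures <- function(dir, spec = motion_spec(),
                                     noise_sigma_mm = 0, seed = 1L,
                                     resolution_mm = 0.05) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- simulate_jaw_motion(spec)
  cap <- synth_capture(truth, noise_sigma_mm = noise_sigma_mm, seed = seed)
  dent <- synth_dentition(resolution_mm, spec$working_side)
  emg <- synth_emg(truth, seed = seed + 2L)
  paths <- list(
    markers = file.path(dir, "markers.csv"),
    static_markers = file.path(dir, "static_markers.csv"),
    mandible = file.path(dir, "mandible.stl"),
    maxilla = file.path(dir, "maxilla.stl"),
    marker_reference = file.path(dir, "marker_reference.csv"),
    landmarks = file.path(dir, "landmarks.csv"),
    emg = file.path(dir, "emg.csv"),
    truth = file.path(dir, "truth.json"))
  write_markers(cap, paths$markers)
  static <- attr(cap, "static_frame")
  write_points(static, paths$static_markers)
  write_mesh(dent$mandible, paths$mandible)
  write_mesh(dent$maxilla, paths$maxilla)
  write_points(default_marker_geometry(), paths$marker_reference)
  write_points(dent$landmarks, paths$landmarks)
  write_emg(emg, paths$emg)
  write_truth(truth, paths$truth)
  invisible(paths)
}
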