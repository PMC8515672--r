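#' Segment masticatory cycles into opening, closing and occlusal phases
#'
#' Detects the four key timepoints of each chewing cycle from a molar
#' trajectory in the maxilla-fixed frame, following the kinematic
#' definitions: cycles are delimited by successive maxima of the vertical
#' (Z) molar coordinate (maximum jaw closing); within a cycle the most
#' anterior point is the X maximum, maximum opening the Z minimum, and the
#' most posterior point the X minimum after maximum opening. The occlusal
#' phase starts at the first contact frame at or after maximum opening -
#' kinematically this coincides with the most posterior position, and a
#' consistency flag records whether the two agree within
#' `consistency_tol_frames`. Phases partition each cycle: opening runs from
#' maximum closing to maximum opening, closing from maximum opening to
#' contact onset, occlusal from contact onset to the next maximum closing.
#'
#' @param trajectory molar [trajectory()] in the maxilla frame.
#' @param occlusion matching [occlusion_series()].
#' @param prominence_frac minimum prominence of a cycle-delimiting Z maximum,
#'   as a fraction of the vertical range (default 0.1: jitter below 10% of
#'   gape never splits a cycle).
#' @param median_prefilter apply a 3-frame median prefilter before extremum
#'   detection (default off).
#' @param consistency_tol_frames tolerance for the most-posterior /
#'   contact-onset agreement flag.
#' @return Object of class `phase_segmentation`: per-cycle data.frame
#'   `timepoints` (frames of max_closing, most_anterior, max_opening,
#'   most_posterior, contact_onset), data.frame `phases` (cycle, phase,
#'   start_frame, end_frame), flags, and the source landmark name.
#' @export
detect_key_timepoints <- function(trajectory, occlusion,
                                  prominence_frac = 0.1,
                                  median_prefilter = FALSE,
                                  consistency_tol_frames = 2L) {
  stopifnot(inherits(trajectory, "trajectory"),
            inherits(occlusion, "occlusion_series"))
  if (length(occlusion$clearance_mm) != nrow(trajectory$coords))
    stop("detect_key_timepoints: trajectory and occlusion length mismatch")
  z <- trajectory$coords[, 3]
  x <- trajectory$coords[, 1]
  if (median_prefilter) {
    z <- stats::runmed(z, 3, endrule = "keep")
    x <- stats::runmed(x, 3, endrule = "keep")
  }
  if (anyNA(z)) {
    # gaps: interpolate for delimitation only (timepoints still reported on
    # observed frames)
    z <- stats::approx(seq_along(z), z, seq_along(z), rule = 2)$y
  }
  n <- length(z)
  rng <- diff(range(z))
  if (rng <= 0) stop("detect_key_timepoints: flat trajectory, no cycles")
  prom <- prominence_frac * rng
  delim <- .z_maxima(z, prom)
  if (length(delim) < 2L)
    stop("detect_key_timepoints: no complete cycle in trajectory")

  contact <- occlusion$contact
  contact[is.na(contact)] <- FALSE
  tps <- list()
  phases <- list()
  degenerate_ap <- FALSE
  for (k in seq_len(length(delim) - 1L)) {
    a <- delim[k]
    b <- delim[k + 1L]
    idx <- a:(b - 1L)
    xk <- x[idx]
    max_opening <- idx[which.min(z[idx])]
    most_anterior <- idx[which.max(xk)]
    post <- idx[idx >= max_opening]
    most_posterior <- post[which.min(x[post])]
    if (diff(range(xk, na.rm = TRUE)) < 1e-9) degenerate_ap <- TRUE
    cn <- post[contact[post]]
    contact_onset <- if (length(cn)) cn[1] else NA_integer_
    occl_start <- if (is.na(contact_onset)) b else contact_onset
    tps[[k]] <- data.frame(
      cycle = k, max_closing = a, most_anterior = most_anterior,
      max_opening = max_opening, most_posterior = most_posterior,
      contact_onset = contact_onset,
      consistent = !is.na(contact_onset) &&
        abs(most_posterior - contact_onset) <= consistency_tol_frames)
    phases[[k]] <- data.frame(
      cycle = k,
      phase = c("opening", "closing", "occlusal"),
      start_frame = c(a, max_opening, occl_start),
      end_frame = c(max_opening, occl_start, b))
  }
  structure(list(timepoints = do.call(rbind, tps),
                 phases = do.call(rbind, phases),
                 cycle_delimiters = delim,
                 landmark = trajectory$landmark,
                 frame_rate = trajectory$frame_rate,
                 degenerate_ap = degenerate_ap),
            class = "phase_segmentation")
}

# cycle-delimiting maxima of z with a minimum prominence; boundary frames
# count as delimiters when they dominate their neighbour (ties -> earliest)
.z_maxima <- function(z, prom) {
  n <- length(z)
  is_max <- logical(n)
  for (i in seq_len(n)) {
    lo <- if (i > 1) z[i - 1] else -Inf
    hi <- if (i < n) z[i + 1] else -Inf
    is_max[i] <- z[i] > lo && z[i] >= hi
  }
  cand <- which(is_max)
  if (z[1] >= z[2]) cand <- union(1L, cand)
  if (z[n] > z[n - 1]) cand <- union(cand, n)
  cand <- sort(cand)
  # prominence = drop from the peak to the deeper of the dips separating it
  # from its neighbouring candidates; boundary candidates use their single
  # interior side. Re-evaluate after removals so a low-prominence bump does
  # not shield a genuine cycle maximum.
  repeat {
    keep <- logical(length(cand))
    for (j in seq_along(cand)) {
      i <- cand[j]
      dl <- if (j == 1 && i == 1L) Inf else
        z[i] - min(z[(if (j == 1) 1L else cand[j - 1]):i])
      dr <- if (j == length(cand) && i == n) Inf else
        z[i] - min(z[i:(if (j == length(cand)) n else cand[j + 1])])
      keep[j] <- min(dl, dr) >= prom
    }
    if (all(keep) || !any(keep)) break
    # drop only the least prominent candidate, then re-evaluate
    promv <- numeric(length(cand))
    for (j in seq_along(cand)) {
      i <- cand[j]
      dl <- if (j == 1 && i == 1L) Inf else
        z[i] - min(z[(if (j == 1) 1L else cand[j - 1]):i])
      dr <- if (j == length(cand) && i == n) Inf else
        z[i] - min(z[i:(if (j == length(cand)) n else cand[j + 1])])
      promv[j] <- min(dl, dr)
    }
    cand <- cand[-which.min(promv)]
  }
  cand[keep]
}

#' @export
print.phase_segmentation <- function(x, ...) {
  cat(sprintf(
    "Phase segmentation (%s): %d complete cycle(s)%s\n", x$landmark,
    nrow(x$timepoints),
    if (x$degenerate_ap) " [degenerate antero-posterior excursion]" else ""))
  print(x$timepoints, row.names = FALSE)
  invisible(x)
}

#' Per-phase durations and cycle summaries
#'
#' @param segmentation a [detect_key_timepoints()] result.
#' @param frame_rate frames per second; defaults to the segmentation's rate.
#' @return List with `per_cycle` (data.frame of per-cycle phase durations and
#'   cycle duration, ms) and `summary` (mean and SD across cycles; SD is `NA`
#'   for a single cycle).
#' @export
phase_statistics <- function(segmentation, frame_rate = NULL) {
  stopifnot(inherits(segmentation, "phase_segmentation"))
  if (is.null(frame_rate)) frame_rate <- segmentation$frame_rate
  ms <- 1000 / frame_rate
  ph <- segmentation$phases
  per <- do.call(rbind, lapply(split(ph, ph$cycle), function(d) {
    dur <- (d$end_frame - d$start_frame) * ms
    data.frame(cycle = d$cycle[1],
               opening_ms = dur[d$phase == "opening"],
               closing_ms = dur[d$phase == "closing"],
               occlusal_ms = dur[d$phase == "occlusal"],
               cycle_ms = sum(dur))
  }))
  rownames(per) <- NULL
  cols <- c("opening_ms", "closing_ms", "occlusal_ms", "cycle_ms")
  summary <- data.frame(
    phase = cols,
    mean_ms = vapply(per[cols], mean, numeric(1)),
    sd_ms = if (nrow(per) > 1) vapply(per[cols], stats::sd, numeric(1))
            else rep(NA_real_, length(cols)))
  rownames(summary) <- NULL
  list(per_cycle = per, summary = summary)
}
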