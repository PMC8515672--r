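#' Multichannel EMG record
#'
#' Masticatory-muscle EMG (typically working- and balancing-side masseter and
#' digastric), sampled uniformly, with an explicit signed synchronization
#' offset to the motion capture: `sync_offset_ms` is EMG time minus capture
#' time at acquisition start (positive when the EMG record starts before the
#' capture).
#'
#' @param signals n x k numeric matrix (µV), one named column per channel.
#' @param sampling_rate Hz (the reference chain digitizes at 1000 Hz).
#' @param sync_offset_ms signed offset, ms.
#' @return Object of class `emg_record`.
#' @export
emg_record <- function(signals, sampling_rate, sync_offset_ms = 0) {
  signals <- as.matrix(signals)
  if (is.null(colnames(signals)))
    colnames(signals) <- paste0("ch", seq_len(ncol(signals)))
  stopifnot(sampling_rate > 0, is.numeric(signals))
  structure(list(signals = signals, sampling_rate = sampling_rate,
                 sync_offset_ms = sync_offset_ms,
                 t_ms = (seq_len(nrow(signals)) - 1) / sampling_rate * 1000),
            class = "emg_record")
}

#' @export
print.emg_record <- function(x, ...) {
  cat(sprintf(
    "EMG record: %d samples x %d channel(s) [%s] at %g Hz, sync offset %g ms\n",
    nrow(x$signals), ncol(x$signals),
    paste(colnames(x$signals), collapse = ", "), x$sampling_rate,
    x$sync_offset_ms))
  invisible(x)
}

#' EMG preprocessing: high-pass, rectify, envelope
#'
#' Zero-phase (forward-backward) 4th-order Butterworth high-pass at
#' `highpass_hz` (default the conventional 100-Hz cutoff), full-wave
#' rectification, and a centered moving-RMS envelope over
#' `envelope_window_ms`.
#'
#' @param record an [emg_record()].
#' @param highpass_hz high-pass cutoff (Hz); must be below Nyquist. Set to 0
#'   to skip filtering (already-filtered input).
#' @param envelope_window_ms moving-RMS window (ms).
#' @param order filter order.
#' @return `emg_record` of the same shape whose `signals` hold the RMS
#'   envelope (µV); class gains `"emg_envelope"`.
#' @export
preprocess_emg <- function(record, highpass_hz = 100,
                           envelope_window_ms = 10, order = 4) {
  stopifnot(inherits(record, "emg_record"))
  nyq <- record$sampling_rate / 2
  if (highpass_hz >= nyq)
    stop("preprocess_emg: high-pass cutoff (", highpass_hz,
         " Hz) must be below the Nyquist frequency (", nyq, " Hz)")
  win <- max(1L, round(envelope_window_ms / 1000 * record$sampling_rate))
  env <- record$signals
  if (highpass_hz > 0) {
    bf <- signal::butter(order, highpass_hz / nyq, type = "high")
    for (j in seq_len(ncol(env)))
      env[, j] <- signal::filtfilt(bf, env[, j])
  }
  env <- env^2
  kern <- rep(1 / win, win)
  for (j in seq_len(ncol(env)))
    env[, j] <- sqrt(pmax(0, stats::filter(env[, j], kern, sides = 2)))
  # centered window: edges where the window runs out are padded with the
  # nearest computed value
  for (j in seq_len(ncol(env))) {
    v <- env[, j]
    ok <- which(!is.na(v))
    v[seq_len(ok[1] - 1)] <- v[ok[1]]
    v[seq(ok[length(ok)] + 1, length.out = length(v) - ok[length(ok)])] <-
      v[ok[length(ok)]]
    env[, j] <- v
  }
  out <- emg_record(env, record$sampling_rate, record$sync_offset_ms)
  class(out) <- c("emg_envelope", class(out))
  attr(out, "envelope_window_ms") <- envelope_window_ms
  attr(out, "highpass_hz") <- highpass_hz
  out
}

#' Detect EMG bursts by baseline thresholding
#'
#' A burst is a maximal run of envelope samples above
#' `baseline mean + k_sd * baseline SD` lasting at least `min_duration_ms`;
#' shorter above-threshold runs are discarded and bursts separated by less
#' than `min_duration_ms` are merged. Because the primary threshold sits in
#' the tail of the baseline envelope's own fluctuations, a burst is
#' additionally validated by a second, higher threshold
#' (`baseline mean + k_sd_peak * baseline SD`) that its peak must reach
#' (double-threshold detection); runs that never reach the peak threshold
#' can bridge interior dropouts but never extend a burst outward or stand
#' alone. The baseline is the first `baseline_window_ms` of the record,
#' which the caller must keep free of programmed activity. A flat baseline
#' (SD = 0) falls back to `k_sd * global envelope SD` (single threshold) and
#' is flagged.
#'
#' @param envelope an envelope record from [preprocess_emg()].
#' @param baseline_window_ms baseline segment length (ms).
#' @param k_sd primary threshold multiplier.
#' @param min_duration_ms minimum burst duration and merge gap (ms).
#' @param k_sd_peak peak-validation threshold multiplier.
#' @return Object of class `burst_set`: data.frame `bursts` with columns
#'   `channel`, `onset_ms`, `offset_ms` (EMG time), thresholds used, flags.
#' @export
detect_bursts <- function(envelope, baseline_window_ms = 200, k_sd = 3,
                          min_duration_ms = 10, k_sd_peak = 2 * k_sd) {
  stopifnot(inherits(envelope, "emg_record"))
  sr <- envelope$sampling_rate
  nb <- max(2L, round(baseline_window_ms / 1000 * sr))
  nb <- min(nb, nrow(envelope$signals))
  min_n <- max(1L, round(min_duration_ms / 1000 * sr))
  half_win_ms <- (attr(envelope, "envelope_window_ms") %||% 0) / 2
  out <- list()
  thresholds <- numeric(ncol(envelope$signals))
  flagged <- logical(ncol(envelope$signals))
  for (j in seq_len(ncol(envelope$signals))) {
    v <- envelope$signals[, j]
    base <- v[seq_len(nb)]
    bsd <- stats::sd(base)
    if (!is.finite(bsd) || bsd <= 0) {
      thr <- k_sd * stats::sd(v)
      thr2 <- thr                       # no peak validation without a baseline
      flagged[j] <- TRUE
    } else {
      thr <- mean(base) + k_sd * bsd
      thr2 <- mean(base) + k_sd_peak * bsd
    }
    thresholds[j] <- thr
    above <- v > thr
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ron <- starts[r$values]
    roff <- ends[r$values]
    # group runs separated by less than the persistence window, but let the
    # burst boundaries be set by runs that themselves persist: an isolated
    # sub-persistence noise blip can bridge an interior dropout, never extend
    # a burst outward
    on <- integer(0); off <- integer(0); pon <- integer(0); poff <- integer(0)
    if (length(ron)) {
      grp <- cumsum(c(1L, (ron[-1] - roff[-length(roff)] - 1L) >= min_n))
      for (g in unique(grp)) {
        i <- which(grp == g)
        span <- ron[i[1]]:roff[i[length(i)]]
        hot <- span[v[span] >= thr2]
        if (!length(hot)) next         # never reached the peak threshold
        on <- c(on, hot[1])
        off <- c(off, hot[length(hot)])
        pon <- c(pon, span[1])
        poff <- c(poff, span[length(span)])
      }
    }
    if (length(on)) {
      # a step edge first enters the centered RMS window half a window early
      # (and leaves half a window late): correct the reported crossings back
      # to the edge. Persistence is judged on the primary-threshold span of
      # the group, minus the one-window smear the envelope adds
      onset <- envelope$t_ms[on] + half_win_ms
      offset <- pmax(onset, envelope$t_ms[off] - half_win_ms)
      dur_primary <- envelope$t_ms[poff] - envelope$t_ms[pon] + 1000 / sr -
        2 * half_win_ms
      dur_ok <- dur_primary >= min_duration_ms
      onset <- onset[dur_ok]; offset <- offset[dur_ok]
      if (length(onset))
        out[[colnames(envelope$signals)[j]]] <- data.frame(
          channel = colnames(envelope$signals)[j],
          onset_ms = onset, offset_ms = offset)
    }
  }
  bursts <- if (length(out)) do.call(rbind, out) else
    data.frame(channel = character(), onset_ms = numeric(),
               offset_ms = numeric())
  rownames(bursts) <- NULL
  structure(list(bursts = bursts,
                 parameters = list(baseline_window_ms = baseline_window_ms,
                                   k_sd = k_sd, k_sd_peak = k_sd_peak,
                                   min_duration_ms = min_duration_ms,
                                   thresholds = stats::setNames(
                                     thresholds, colnames(envelope$signals)),
                                   envelope_half_window_ms = half_win_ms),
                 baseline_flagged = stats::setNames(
                   flagged, colnames(envelope$signals)),
                 sync_offset_ms = envelope$sync_offset_ms),
            class = "burst_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.burst_set <- function(x, ...) {
  cat(sprintf("Burst set: %d burst(s) across %d channel(s)\n",
              nrow(x$bursts), length(unique(x$bursts$channel))))
  if (nrow(x$bursts)) print(x$bursts, row.names = FALSE)
  invisible(x)
}

#' Align EMG bursts to capture frames
#'
#' Converts burst onset/offset times from the EMG time axis to capture frame
#' indices: `frame = floor((t - sync_offset) * frame_rate / 1000)` (0-based
#' frame arithmetic; returned indices are 1-based, so frame 0 maps to index
#' 1). At 1000 Hz sampling and 200 frames/s each frame spans exactly 5 EMG
#' samples. Events before capture start clip to the first frame and are
#' flagged.
#'
#' @param bursts a [detect_bursts()] result.
#' @param frame_rate capture frame rate (Hz).
#' @param sync_offset_ms overrides the record's stored offset when given.
#' @return data.frame: `channel`, `onset_ms`, `offset_ms`, `onset_frame`,
#'   `offset_frame` (1-based), `clipped`.
#' @export
align_to_frames <- function(bursts, frame_rate, sync_offset_ms = NULL) {
  stopifnot(inherits(bursts, "burst_set"), frame_rate > 0)
  off <- sync_offset_ms %||% bursts$sync_offset_ms
  b <- bursts$bursts
  to_frame <- function(t) as.integer(floor((t - off) * frame_rate / 1000))
  onset <- to_frame(b$onset_ms)
  offset <- to_frame(b$offset_ms)
  clipped <- onset < 0 | offset < 0
  cbind(b,
        onset_frame = pmax(0L, onset) + 1L,
        offset_frame = pmax(0L, offset) + 1L,
        clipped = clipped)
}
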