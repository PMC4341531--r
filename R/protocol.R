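#' Acquisition protocol for a DCV fusion assay
#'
#' Describes one time-lapse recording: frame interval, pixel size, the
#' electrical stimulation train (bursts of action potentials), and an
#' optional NH4+ de-quench epoch used to reveal the total labeled vesicle
#' pool. The default protocol is 2 Hz acquisition for 90 s with 16 bursts
#' of 50 action potentials at 50 Hz, 0.5 s between bursts, starting at
#' second 30.
#'
#' The stimulation epoch is `[stim_start_s, stim_start_s + stim_duration_s)`
#' with `stim_duration_s = n_bursts * (aps_per_burst / burst_freq_hz +
#' inter_burst_s)`; at the defaults this is 16 * (1 + 0.5) = 24 s, counting
#' the trailing inter-burst interval as part of the epoch.
#'
#' @param frame_interval_s Seconds per frame (default 0.5, i.e. 2 Hz).
#' @param pixel_size_um Micrometres per pixel (default 0.2).
#' @param stim_start_s Stimulation onset in seconds (default 30).
#' @param n_bursts Number of action-potential bursts (default 16).
#' @param aps_per_burst Action potentials per burst (default 50).
#' @param burst_freq_hz Within-burst AP frequency in Hz (default 50).
#' @param inter_burst_s Interval between bursts in seconds (default 0.5).
#' @param movie_duration_s Total recording length in seconds (default 90).
#' @param nh4_start_s Optional NH4+ application onset (seconds), or `NULL`.
#' @param nh4_duration_s Optional NH4+ epoch length (seconds).
#'
#' @return An object of class `dcv_protocol`: a list with the arguments
#'   plus `stim_duration_s`, `stim_end_s`, `n_frames`, and `burst_times_s`
#'   (matrix of burst start/end times).
#' @examples
#' p <- build_protocol()
#' p$stim_duration_s  # 24
#' @export
build_protocol <- function(frame_interval_s = 0.5,
                           pixel_size_um = 0.2,
                           stim_start_s = 30,
                           n_bursts = 16,
                           aps_per_burst = 50,
                           burst_freq_hz = 50,
                           inter_burst_s = 0.5,
                           movie_duration_s = 90,
                           nh4_start_s = NULL,
                           nh4_duration_s = NULL) {
  if (frame_interval_s <= 0) stop("invalid protocol: frame_interval_s must be > 0")
  if (pixel_size_um <= 0) stop("invalid protocol: pixel_size_um must be > 0")
  if (burst_freq_hz <= 0) stop("invalid protocol: burst_freq_hz must be > 0")
  if (n_bursts < 0 || aps_per_burst <= 0) stop("invalid protocol: bursts must be positive")
  if (inter_burst_s < 0) stop("invalid protocol: inter_burst_s must be >= 0")

  burst_len <- aps_per_burst / burst_freq_hz
  stim_duration_s <- n_bursts * (burst_len + inter_burst_s)
  stim_end_s <- stim_start_s + stim_duration_s
  if (stim_end_s > movie_duration_s + 1e-9)
    stop("invalid protocol: stimulation epoch extends beyond the movie")
  if (!is.null(nh4_start_s)) {
    if (is.null(nh4_duration_s) || nh4_duration_s <= 0)
      stop("invalid protocol: nh4_duration_s required with nh4_start_s")
    if (nh4_start_s + nh4_duration_s > movie_duration_s + 1e-9)
      stop("invalid protocol: NH4+ epoch extends beyond the movie")
  }

  starts <- stim_start_s + (seq_len(n_bursts) - 1) * (burst_len + inter_burst_s)
  burst_times_s <- cbind(start = starts, end = starts + burst_len)

  structure(list(
    frame_interval_s = frame_interval_s,
    pixel_size_um = pixel_size_um,
    stim_start_s = stim_start_s,
    n_bursts = n_bursts,
    aps_per_burst = aps_per_burst,
    burst_freq_hz = burst_freq_hz,
    inter_burst_s = inter_burst_s,
    movie_duration_s = movie_duration_s,
    nh4_start_s = nh4_start_s,
    nh4_duration_s = nh4_duration_s,
    stim_duration_s = stim_duration_s,
    stim_end_s = stim_end_s,
    n_frames = as.integer(round(movie_duration_s / frame_interval_s)),
    burst_times_s = burst_times_s
  ), class = "dcv_protocol")
}

#' @export
print.dcv_protocol <- function(x, ...) {
  cat(sprintf("DCV acquisition protocol: %.3g s/frame, %g um/px, %d frames\n",
              x$frame_interval_s, x$pixel_size_um, x$n_frames))
  cat(sprintf("  stim: %d x %d AP @ %g Hz, %g s interval -> [%g, %g) s (%g s)\n",
              x$n_bursts, x$aps_per_burst, x$burst_freq_hz, x$inter_burst_s,
              x$stim_start_s, x$stim_end_s, x$stim_duration_s))
  if (!is.null(x$nh4_start_s))
    cat(sprintf("  NH4+: [%g, %g) s\n", x$nh4_start_s,
                x$nh4_start_s + x$nh4_duration_s))
  invisible(x)
}

#' Convert between seconds and frame indices
#'
#' Frames are 1-based; frame `k` covers time `[(k-1)*dt, k*dt)`.
#'
#' @param protocol A `dcv_protocol`.
#' @param t_s Time(s) in seconds.
#' @return Frame index (integer) for `time_to_frame`; seconds for
#'   `frame_to_time` (time at the start of the frame).
#' @export
time_to_frame <- function(protocol, t_s) {
  as.integer(floor(t_s / protocol$frame_interval_s)) + 1L
}

#' @rdname time_to_frame
#' @param frame 1-based frame index.
#' @export
frame_to_time <- function(protocol, frame) {
  (frame - 1) * protocol$frame_interval_s
}

#' Frame indices of the stimulation epoch
#' @param protocol A `dcv_protocol`.
#' @return Integer vector of frames whose start time lies in the stim epoch.
#' @export
stim_frames <- function(protocol) {
  t0 <- time_to_frame(protocol, protocol$stim_start_s)
  t1 <- time_to_frame(protocol, protocol$stim_end_s - 1e-9)
  seq.int(t0, min(t1, protocol$n_frames))
}

#' Frame indices of the NH4+ de-quench epoch
#' @param protocol A `dcv_protocol` with an NH4+ epoch.
#' @return Integer vector of frame indices.
#' @export
nh4_frames <- function(protocol) {
  if (is.null(protocol$nh4_start_s))
    stop("protocol error: no NH4+ epoch defined")
  t0 <- time_to_frame(protocol, protocol$nh4_start_s)
  t1 <- time_to_frame(protocol, protocol$nh4_start_s + protocol$nh4_duration_s - 1e-9)
  seq.int(t0, min(t1, protocol$n_frames))
}

#' Window covering the first N stimulation bursts
#'
#' Used for early-release quantification (events during the first four
#' bursts of the train).
#'
#' @param protocol A `dcv_protocol`.
#' @param n_bursts Number of leading bursts (default 4).
#' @return `c(t0, t1)` in seconds, the half-open window
#'   `[stim_start, stim_start + n * (burst + interval))`.
#' @export
first_bursts_window <- function(protocol, n_bursts = 4) {
  n <- min(n_bursts, protocol$n_bursts)
  len <- n * (protocol$aps_per_burst / protocol$burst_freq_hz + protocol$inter_burst_s)
  c(protocol$stim_start_s, protocol$stim_start_s + len)
}
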