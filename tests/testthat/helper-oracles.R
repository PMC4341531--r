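# Shared oracles for the test suite.

# Match detected events against ground-truth events: a pair matches when
# onsets agree within `tol_frames` and positions within `tol_px`.
# Assignment is greedy over candidate pairs sorted by distance, so a
# detection is never "consumed" by a farther ground-truth event when a
# closer one exists.
match_events <- function(gt, det, tol_frames = 1, tol_px = 4) {
  if (nrow(gt) == 0 || nrow(det) == 0)
    return(list(tp = 0L, fn = nrow(gt), fp = nrow(det)))
  pairs <- do.call(rbind, lapply(seq_len(nrow(gt)), function(i) {
    ok <- which(abs(det$onset_frame - gt$onset_frame[i]) <= tol_frames)
    if (!length(ok)) return(NULL)
    d <- sqrt((det$y_px[ok] - gt$y_px[i])^2 + (det$x_px[ok] - gt$x_px[i])^2)
    keep <- d <= tol_px
    if (!any(keep)) return(NULL)
    cbind(i, ok[keep], d[keep])
  }))
  tp <- 0L
  if (!is.null(pairs)) {
    pairs <- pairs[order(pairs[, 3]), , drop = FALSE]
    gused <- logical(nrow(gt)); dused <- logical(nrow(det))
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      if (!gused[i] && !dused[j]) { gused[i] <- dused[j] <- TRUE; tp <- tp + 1L }
    }
  }
  list(tp = tp, fn = nrow(gt) - tp, fp = nrow(det) - tp)
}

# Build a one-channel dcv_movie from an array of frames.
movie_from_array <- function(frames, channel = "cargo", pixel_size_um = 0.2,
                             frame_interval_s = 0.5, reporter = "phluorin") {
  structure(list(channels = stats::setNames(list(frames), channel),
                 pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s, reporter = reporter),
            class = "dcv_movie")
}

# Render a movie of Gaussian spots following given trajectories.
# traj: list of data.frames (frame, y_px, x_px, amp).
render_spot_movie <- function(traj, shape = c(64, 64), n_frames,
                              background = 20, psf_sigma = 1.3,
                              poisson = FALSE, read_sd = 0, channel = "cargo") {
  frames <- array(background, c(shape[1], shape[2], n_frames))
  for (tr in traj) for (k in seq_len(nrow(tr))) {
    t <- tr$frame[k]
    frames[, , t] <- add_spot_test(frames[, , t], tr$y_px[k], tr$x_px[k],
                                   tr$amp[k], psf_sigma)
  }
  if (poisson) frames[] <- stats::rpois(length(frames), frames)
  if (read_sd > 0) frames[] <- frames + stats::rnorm(length(frames), 0, read_sd)
  frames
}

# Closed-form peak-normalized Gaussian spot (independent reimplementation
# of the generator's renderer, used as an oracle against it).
add_spot_test <- function(img, y0, x0, amp, sigma) {
  ys <- 0:(nrow(img) - 1); xs <- 0:(ncol(img) - 1)
  img + amp * exp(-outer((ys - y0)^2, (xs - x0)^2, "+") / (2 * sigma^2))
}
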