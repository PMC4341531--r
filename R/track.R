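#' Link per-frame punctum detections into tracks
#'
#' Greedy nearest-neighbour frame-to-frame assignment: candidate pairs are
#' taken in order of increasing distance (ties broken by lower punctum
#' index), pairs farther apart than `max_link_px` are never linked, and a
#' track missing from up to `max_gap_frames` consecutive frames is kept
#' alive and the gap closed by linear interpolation.
#'
#' @param detections List (one element per frame) of data.frames with
#'   columns `y_px`, `x_px`; empty data.frames allowed.
#' @param max_link_px Maximum frame-to-frame link distance (default 5).
#' @param max_gap_frames Maximum bridged gap (default 1).
#' @param min_length Discard tracks shorter than this many frames
#'   (default 1 = keep all).
#' @return List of tracks: data.frames `frame`, `y_px`, `x_px` with an
#'   `id` attribute; interpolated rows carry `interpolated = TRUE`.
#' @export
link_tracks <- function(detections, max_link_px = 5, max_gap_frames = 1,
                        min_length = 1) {
  active <- list()   # each: list(rows = data.frame, last = c(y,x), last_frame, miss)
  done <- list()
  for (f in seq_along(detections)) {
    det <- detections[[f]]
    n_det <- if (is.null(det)) 0L else nrow(det)
    used_det <- rep(FALSE, n_det)
    matched_tr <- rep(FALSE, length(active))
    if (length(active) && n_det) {
      last_pos <- t(vapply(active, `[[`, c(0, 0), "last"))
      dm <- cross_dist(last_pos, cbind(det$y_px, det$x_px))
      lim <- vapply(active, function(a)
        max_link_px * (a$miss + 1), 0)       # farther allowed across a gap
      ord <- order(as.vector(dm), rep(seq_len(n_det), each = nrow(dm)))
      for (idx in ord) {
        ti <- (idx - 1) %% nrow(dm) + 1
        di <- (idx - 1) %/% nrow(dm) + 1
        if (matched_tr[ti] || used_det[di]) next
        if (dm[ti, di] > lim[ti]) next
        a <- active[[ti]]
        gap <- f - a$last_frame - 1L
        if (gap > 0) {   # close the gap by linear interpolation
          for (g in seq_len(gap)) {
            w <- g / (gap + 1)
            a$rows <- rbind(a$rows, data.frame(
              frame = a$last_frame + g,
              y_px = (1 - w) * a$last[1] + w * det$y_px[di],
              x_px = (1 - w) * a$last[2] + w * det$x_px[di],
              interpolated = TRUE))
          }
        }
        a$rows <- rbind(a$rows, data.frame(frame = f, y_px = det$y_px[di],
                                           x_px = det$x_px[di],
                                           interpolated = FALSE))
        a$last <- c(det$y_px[di], det$x_px[di]); a$last_frame <- f; a$miss <- 0L
        active[[ti]] <- a
        matched_tr[ti] <- TRUE; used_det[di] <- TRUE
      }
    }
    # unmatched active tracks age; too-old ones close
    still <- list()
    for (ti in seq_along(active)) {
      a <- active[[ti]]
      if (length(matched_tr) >= ti && matched_tr[ti]) { still[[length(still) + 1]] <- a; next }
      a$miss <- a$miss + 1L
      if (a$miss > max_gap_frames) done[[length(done) + 1]] <- a$rows
      else still[[length(still) + 1]] <- a
    }
    active <- still
    # unmatched detections start new tracks
    if (n_det) for (di in which(!used_det)) {
      active[[length(active) + 1]] <- list(
        rows = data.frame(frame = f, y_px = det$y_px[di], x_px = det$x_px[di],
                          interpolated = FALSE),
        last = c(det$y_px[di], det$x_px[di]), last_frame = f, miss = 0L)
    }
  }
  for (a in active) done[[length(done) + 1]] <- a$rows
  done <- Filter(function(tr) nrow(tr) >= min_length, done)
  # stable ordering: by first frame, then first position
  if (length(done)) {
    key <- vapply(done, function(tr) tr$frame[1] * 1e6 + tr$y_px[1], 0)
    done <- done[order(key)]
  }
  for (i in seq_along(done)) attr(done[[i]], "id") <- i
  done
}

#' Build a kymograph along a polyline path
#'
#' Samples intensity at 1-px arclength steps along the path for every
#' frame, taking the maximum over a 3-px-wide band normal to the path, so
#' a punctum slightly off the drawn line is still captured. Rows are
#' frames (time), columns are positions along the path.
#'
#' @param movie A `dcv_movie`.
#' @param path Polyline matrix (columns y, x; 0-based px).
#' @param channel Channel name.
#' @param band_halfwidth_px Half-width of the normal band (default 1).
#' @return Object of class `dcv_kymograph`: `matrix` (frames x positions),
#'   `path`, `s` (arclengths), `pixel_size_um`, `frame_interval_s`.
#' @export
build_kymograph <- function(movie, path, channel = names(movie$channels)[1],
                            band_halfwidth_px = 1) {
  arr <- movie$channels[[channel]]
  ny <- dim(arr)[1]; nx <- dim(arr)[2]; Tn <- dim(arr)[3]
  if (any(path[, 1] < 0 | path[, 1] > ny - 1 | path[, 2] < 0 | path[, 2] > nx - 1))
    stop("bounds error: path outside image")
  ps <- path_samples(path, step = 1)
  offs <- seq(-band_halfwidth_px, band_halfwidth_px, by = 1)
  m <- matrix(NA_real_, Tn, length(ps$s))
  for (t in seq_len(Tn)) {
    img <- arr[, , t]
    vals <- sapply(offs, function(o)
      interp_bilinear(img, ps$points[, 1] + o * ps$normals[, 1],
                      ps$points[, 2] + o * ps$normals[, 2]))
    if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1)
    m[t, ] <- apply(vals, 1, max, na.rm = TRUE)
  }
  structure(list(matrix = m, path = path, s = ps$s,
                 pixel_size_um = movie$pixel_size_um,
                 frame_interval_s = movie$frame_interval_s),
            class = "dcv_kymograph")
}

#' Speed of the brightest ridge in a kymograph
#'
#' Fits a line to the per-frame argmax position along the path and
#' converts the slope to nm/s. This is the kymograph counterpart of the
#' track-based velocity estimate.
#'
#' @param kym A `dcv_kymograph`.
#' @param frames Optional frame subset (default all).
#' @return Absolute ridge speed in nm/s.
#' @export
kymograph_ridge_speed <- function(kym, frames = NULL) {
  m <- kym$matrix
  if (is.null(frames)) frames <- seq_len(nrow(m))
  pos <- kym$s[apply(m[frames, , drop = FALSE], 1, which.max)]
  fit <- stats::lm(pos ~ frames)
  unname(abs(stats::coef(fit)[2])) * kym$pixel_size_um * 1000 /
    kym$frame_interval_s
}

#' Classify a track as stationary or moving
#'
#' A vesicle is moving when its trajectory shows net displacement
#' anywhere in the movie: operationally, when the net displacement across
#' any sliding window of `window_frames` frames exceeds
#' `displacement_threshold_px` (2 px = 400 nm at 0.2 um/px, well above
#' localization jitter). The default window of 10 frames (5 s at 2 Hz) is
#' the time in which the slowest relevant directed transport (~100 nm/s)
#' covers the 400 nm threshold, so nominal-speed movers exceed it with
#' margin while stationary jitter (tens of nm) never accumulates net
#' displacement. Tracks shorter than the window are classified on their
#' full span and flagged `short`.
#'
#' @param track data.frame `frame`, `y_px`, `x_px`.
#' @param window_frames Sliding-window length (default 10).
#' @param displacement_threshold_px Net-displacement threshold (default 2).
#' @return `"moving"` or `"stationary"`, attribute `short`.
#' @export
classify_motility <- function(track, window_frames = 10,
                              displacement_threshold_px = 2) {
  n <- nrow(track)
  short <- n < window_frames
  w <- min(window_frames, n)
  if (n < 2) return(structure("stationary", short = TRUE))
  dy <- track$y_px[seq.int(w, n)] - track$y_px[seq.int(1, n - w + 1)]
  dx <- track$x_px[seq.int(w, n)] - track$x_px[seq.int(1, n - w + 1)]
  moving <- any(sqrt(dy^2 + dx^2) > displacement_threshold_px)
  structure(if (moving) "moving" else "stationary", short = short)
}

#' Mean instantaneous speed of a track in a time window
#'
#' Mean of per-frame speeds `|dposition| * pixel_size / frame_interval`
#' over the frames whose start time lies in `[t0, t1)`. Per-frame speeds
#' (not net displacement over time) are used so direction reversals do
#' not cancel.
#'
#' @param track data.frame `frame`, `y_px`, `x_px`.
#' @param window `c(t0, t1)` in seconds.
#' @param protocol A `dcv_protocol` (pixel size and frame interval).
#' @return Speed in nm/s; `NA` with a warning when the track does not
#'   overlap the window with at least two frames.
#' @export
mean_velocity <- function(track, window, protocol) {
  t_s <- frame_to_time(protocol, track$frame)
  sel <- which(t_s >= window[1] & t_s < window[2])
  if (length(sel) < 2) {
    warning("undefined velocity: track does not overlap the window")
    return(NA_real_)
  }
  tr <- track[sel, ]
  dfr <- diff(tr$frame)
  step <- sqrt(diff(tr$y_px)^2 + diff(tr$x_px)^2)
  speeds <- step * protocol$pixel_size_um * 1000 /
    (dfr * protocol$frame_interval_s)
  mean(speeds)
}

#' Velocity analysis windows
#'
#' Pre-stimulation is the first 30 s; the stimulation window runs from
#' stimulation onset to the fusion onset (for fusing vesicles) or the end
#' of the stimulation epoch; post-stimulation is the 36 s after the
#' epoch ends.
#'
#' @param protocol A `dcv_protocol`.
#' @param fusion_onset_s Optional fusion onset (s) truncating the stim
#'   window.
#' @return Named list of `c(t0, t1)` windows: `prestim`, `stim`,
#'   `poststim`.
#' @export
velocity_windows <- function(protocol, fusion_onset_s = NULL) {
  stim_end <- if (is.null(fusion_onset_s)) protocol$stim_end_s
  else min(fusion_onset_s, protocol$stim_end_s)
  list(prestim = c(0, protocol$stim_start_s),
       stim = c(protocol$stim_start_s, stim_end),
       poststim = c(protocol$stim_end_s,
                    min(protocol$stim_end_s + 36, protocol$movie_duration_s)))
}

#' Assign positions to synaptic or extra-synaptic sites
#'
#' A release event (or punctum) is synaptic when its centroid lies within
#' `radius_nm` (default 200 nm, i.e. +/- 1 pixel at 0.2 um/px, about the
#' minimal point spread function) of the nearest synapse-marker centroid.
#' Equidistant synapses resolve to the lowest synapse index. An empty
#' synapse list makes everything extra-synaptic.
#'
#' @param positions Matrix/data.frame of (y, x) positions (0-based px),
#'   or a single `c(y, x)`.
#' @param synapses data.frame with `y_px`, `x_px`.
#' @param radius_nm Assignment radius (default 200).
#' @param pixel_size_um Pixel size (default 0.2).
#' @return Character vector `"synaptic"` / `"extra-synaptic"`, with
#'   attribute `synapse_id` (NA when extra-synaptic).
#' @export
assign_synaptic <- function(positions, synapses, radius_nm = 200,
                            pixel_size_um = 0.2) {
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 2)
  if (is.data.frame(positions))
    positions <- cbind(positions$y_px %||% positions[[1]],
                       positions$x_px %||% positions[[2]])
  n <- nrow(positions)
  if (is.null(synapses) || nrow(synapses) == 0)
    return(structure(rep("extra-synaptic", n), synapse_id = rep(NA_integer_, n)))
  dm <- cross_dist(positions, cbind(synapses$y_px, synapses$x_px))
  nn <- apply(dm, 1, which.min)   # which.min takes the lowest index on ties
  dist_nm <- dm[cbind(seq_len(n), nn)] * pixel_size_um * 1000
  synaptic <- dist_nm <= radius_nm + 1e-9
  structure(ifelse(synaptic, "synaptic", "extra-synaptic"),
            synapse_id = ifelse(synaptic, as.integer(nn), NA_integer_))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Co-trafficking of two punctum tracks
#'
#' Two puncta co-traffic when, over their temporal overlap, both are
#' moving, their mean separation stays within `max_dist_px`, and their
#' frame-to-frame displacement vectors correlate strongly.
#'
#' @param trackA,trackB data.frames `frame`, `y_px`, `x_px`.
#' @param max_dist_px Mean-separation bound (default 2).
#' @param min_overlap_frames Minimum shared frames (default 10).
#' @param corr_min Displacement-vector correlation threshold (default 0.8).
#' @param window_frames,displacement_threshold_px Passed to
#'   [classify_motility()].
#' @return Logical flag, attribute `reason` describing the outcome.
#' @export
detect_cotrafficking <- function(trackA, trackB, max_dist_px = 2,
                                 min_overlap_frames = 10, corr_min = 0.8,
                                 window_frames = 10,
                                 displacement_threshold_px = 2) {
  fr <- intersect(trackA$frame, trackB$frame)
  if (length(fr) < min_overlap_frames)
    return(structure(FALSE, reason = "insufficient overlap"))
  a <- trackA[match(fr, trackA$frame), ]
  b <- trackB[match(fr, trackB$frame), ]
  if (classify_motility(a, window_frames, displacement_threshold_px) != "moving" ||
      classify_motility(b, window_frames, displacement_threshold_px) != "moving")
    return(structure(FALSE, reason = "not both moving"))
  sep <- mean(sqrt((a$y_px - b$y_px)^2 + (a$x_px - b$x_px)^2))
  if (sep > max_dist_px) return(structure(FALSE, reason = "too far apart"))
  da <- cbind(diff(a$y_px), diff(a$x_px))
  db <- cbind(diff(b$y_px), diff(b$x_px))
  r <- suppressWarnings(stats::cor(as.vector(da), as.vector(db)))
  if (!is.finite(r) || r < corr_min)
    return(structure(FALSE, reason = "uncorrelated displacement"))
  structure(TRUE, reason = "co-trafficking")
}

#' Co-trafficking bookkeeping table
#'
#' Summarizes per-track co-trafficking flags into counts and percentages
#' (one decimal), the form used to report the fraction of mobile cargo
#' tracks accompanied by a second marker.
#'
#' @param flags Logical vector, one per mobile track.
#' @return data.frame `category`, `n`, `percent`.
#' @export
cotraffic_summary <- function(flags) {
  n <- length(flags)
  co <- sum(flags)
  data.frame(category = c("co-trafficking", "non-co-trafficking"),
             n = c(co, n - co),
             percent = round(100 * c(co, n - co) / n, 1))
}
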