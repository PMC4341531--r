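#' Detection parameters for fusion-event calling
#'
#' The event rule is the 2-SD rule: an event is counted when a ROI trace
#' shows a sudden increase two standard deviations above its baseline
#' \eqn{F_0} (mean of the first four frames), and the onset is the first
#' supra-threshold frame. The remaining knobs make the rule operational on
#' noisy data.
#'
#' @param k_sigma Threshold multiplier (default 2).
#' @param baseline_frames Frames averaged for \eqn{F_0} (default 4).
#' @param rise_frames_max Frames within which the threshold crossing must
#'   complete for the increase to count as "sudden" (default 2, i.e. 1 s
#'   at 2 Hz).
#' @param refractory_frames Minimum frames between events at one ROI
#'   (default 10, i.e. 5 s at 2 Hz).
#' @param transient_return_frames Consecutive sub-threshold frames after
#'   onset required to call an event transient (default 4).
#' @param disappearance_frac Residual fraction of the pre-drop mean below
#'   which a red-cargo punctum counts as completely disappeared
#'   (default 0.1).
#' @param min_prestim_frames Minimum pre-stimulation frames demanded for
#'   the baseline-noise estimate (default 8).
#' @return List of class `dcv_detection_params`.
#' @export
detection_params <- function(k_sigma = 2, baseline_frames = 4,
                             rise_frames_max = 2, refractory_frames = 10,
                             transient_return_frames = 4,
                             disappearance_frac = 0.1,
                             min_prestim_frames = 8) {
  if (k_sigma <= 0) stop("k_sigma must be > 0")
  if (baseline_frames < 1) stop("baseline_frames must be >= 1")
  structure(as.list(environment()), class = "dcv_detection_params")
}

roi_topleft <- function(center, roi_size) {
  # 0-based top-left of the block covering the punctum
  if (roi_size %% 2 == 0) floor(center) - (roi_size / 2 - 1)
  else round(center) - (roi_size - 1) / 2
}

#' Extract a square-ROI intensity trace from a movie
#'
#' Mean intensity per frame over a `roi_size` x `roi_size` pixel block
#' (default 2x2, i.e. 0.4 x 0.4 um at 0.2 um/px) covering the punctum at
#' `center`. The baseline \eqn{F_0} is the mean of the first
#' `baseline_frames` values; when a protocol is supplied, the baseline
#' noise SD `sigma0` is estimated from all pre-stimulation frames.
#'
#' @param movie A `dcv_movie`.
#' @param channel Channel name.
#' @param center `c(y, x)` 0-based continuous position.
#' @param roi_size Block side in pixels (default 2).
#' @param protocol Optional `dcv_protocol`; enables the `sigma0` estimate.
#' @param params Detection parameters ([detection_params()]).
#' @return Object of class `dcv_roi_trace`: `values`, `center`, `roi_size`,
#'   `F0`, `sigma0` (`NA` without a protocol), `frame_interval_s`.
#' @export
extract_trace <- function(movie, channel = names(movie$channels)[1],
                          center, roi_size = 2,
                          protocol = NULL, params = detection_params()) {
  arr <- movie$channels[[channel]]
  if (is.null(arr)) stop("unknown channel: ", channel)
  ny <- dim(arr)[1]; nx <- dim(arr)[2]
  tl <- roi_topleft(center, roi_size)
  if (any(tl < 0) || tl[1] + roi_size > ny || tl[2] + roi_size > nx)
    stop("bounds error: ROI outside image")
  block <- arr[tl[1] + seq_len(roi_size), tl[2] + seq_len(roi_size), , drop = FALSE]
  values <- apply(block, 3, mean)
  F0 <- mean(values[seq_len(min(params$baseline_frames, length(values)))])
  sigma0 <- NA_real_
  if (!is.null(protocol)) {
    pre <- which((seq_along(values) - 1) * protocol$frame_interval_s <
                   protocol$stim_start_s)
    if (length(pre) >= 2) {
      if (length(pre) < params$min_prestim_frames)
        warning("fewer than ", params$min_prestim_frames,
                " pre-stimulation frames for the noise estimate")
      sigma0 <- stats::sd(values[pre])
    }
  }
  structure(list(values = values, center = center, roi_size = roi_size,
                 F0 = F0, sigma0 = sigma0,
                 frame_interval_s = if (is.null(protocol)) movie$frame_interval_s
                 else protocol$frame_interval_s),
            class = "dcv_roi_trace")
}

#' Build a ROI trace from raw values
#'
#' Constructor used when trace values come from elsewhere than a movie
#' (fixtures, unit constructions).
#' @param values Per-frame intensities.
#' @param center Optional `c(y, x)` position.
#' @param frame_interval_s Seconds per frame.
#' @param protocol Optional protocol for the pre-stim `sigma0` estimate.
#' @param params Detection parameters.
#' @inheritParams extract_trace
#' @return A `dcv_roi_trace`.
#' @export
roi_trace <- function(values, center = c(NA_real_, NA_real_),
                      frame_interval_s = 0.5, protocol = NULL,
                      params = detection_params(), roi_size = 2) {
  F0 <- mean(values[seq_len(min(params$baseline_frames, length(values)))])
  sigma0 <- NA_real_
  if (!is.null(protocol)) {
    pre <- which((seq_along(values) - 1) * protocol$frame_interval_s <
                   protocol$stim_start_s)
    if (length(pre) >= 2) sigma0 <- stats::sd(values[pre])
    frame_interval_s <- protocol$frame_interval_s
  }
  structure(list(values = values, center = center, roi_size = roi_size,
                 F0 = F0, sigma0 = sigma0, frame_interval_s = frame_interval_s),
            class = "dcv_roi_trace")
}

#' Relative fluorescence change of a trace
#'
#' \eqn{\Delta F / F_0} per frame, with \eqn{F_0} the mean of the first
#' four frames of the recording.
#' @param trace A `dcv_roi_trace`.
#' @return Numeric vector, one value per frame.
#' @export
dff <- function(trace) {
  if (!is.finite(trace$F0) || trace$F0 <= 0)
    stop("degenerate baseline: F0 must be > 0")
  (trace$values - trace$F0) / trace$F0
}

#' Detect pHluorin fusion events on a ROI trace
#'
#' An event is called at the first frame where the trace crosses
#' `F0 + k_sigma * sigma0` from below, provided the increase of at least
#' `k_sigma * sigma0` completed within `rise_frames_max` frames (the
#' "sudden" requirement). At most one event is called per refractory
#' window. Events with onset before stimulation are reported but flagged
#' `pre_stim`; crossings during an NH4+ de-quench epoch are not events and
#' are ignored. If `sigma0` is zero the threshold degenerates to "any
#' increase above F0" and events are flagged `degenerate`.
#'
#' @param trace A `dcv_roi_trace` (with `sigma0`; supply a protocol to
#'   [extract_trace()] or it is computed here from pre-stim frames).
#' @param params [detection_params()].
#' @param protocol A `dcv_protocol`.
#' @param arrival_veto Optional `function(onset_frame, rise_counts)`
#'   returning `FALSE` to reject a candidate onset (used by
#'   [detect_fusion_events()] to discard brightness that translated into
#'   the ROI instead of appearing de novo).
#' @return data.frame with columns `onset_frame`, `onset_time_s`,
#'   `peak_dff`, `pre_stim`, `degenerate`, `y_px`, `x_px`; zero rows when
#'   no event.
#' @export
detect_fusion_phluorin <- function(trace, params = detection_params(),
                                   protocol = build_protocol(),
                                   arrival_veto = NULL) {
  v <- trace$values
  Tn <- length(v)
  sigma0 <- trace$sigma0
  if (is.na(sigma0)) {
    pre <- which((seq_len(Tn) - 1) * protocol$frame_interval_s <
                   protocol$stim_start_s)
    if (length(pre) < 2) stop("cannot estimate sigma0: too few pre-stim frames")
    sigma0 <- stats::sd(v[pre])
  }
  degenerate <- sigma0 == 0
  thr <- trace$F0 + params$k_sigma * sigma0
  above <- if (degenerate) v > trace$F0 else v >= thr
  # forbid calls during an NH4+ epoch and after it starts
  t_max <- Tn
  if (!is.null(protocol$nh4_start_s))
    t_max <- min(Tn, time_to_frame(protocol, protocol$nh4_start_s) - 1L)

  onsets <- integer(0)
  last <- -Inf
  for (t in 2:Tn) {
    if (t > t_max) break
    if (!above[t]) next
    w0 <- max(1, t - params$rise_frames_max)
    rise <- v[t] - min(v[w0:(t - 1)])
    # "sudden": the whole >= k*sigma increase completed within the window.
    # A fusion on top of an already-elevated trace still qualifies through
    # its own fresh jump.
    if (degenerate) { if (above[t - 1]) next }
    else if (rise < params$k_sigma * sigma0) next
    if (!is.null(arrival_veto) && !arrival_veto(t, rise)) next
    if (t - last < params$refractory_frames) next
    onsets <- c(onsets, t)
    last <- t
  }
  if (!length(onsets))
    return(data.frame(onset_frame = integer(0), onset_time_s = numeric(0),
                      peak_dff = numeric(0), pre_stim = logical(0),
                      degenerate = logical(0), y_px = numeric(0),
                      x_px = numeric(0)))
  d <- dff(trace)
  peak <- vapply(onsets, function(t)
    max(d[t:min(Tn, t_max, t + params$refractory_frames)]), 0)
  times <- frame_to_time(protocol, onsets)
  data.frame(onset_frame = onsets, onset_time_s = times, peak_dff = peak,
             pre_stim = times < protocol$stim_start_s,
             degenerate = degenerate,
             y_px = trace$center[1], x_px = trace$center[2])
}

#' Classify a fusion event as persistent or transient
#'
#' Transient iff, after onset, the trace falls below the detection
#' threshold for at least `transient_return_frames` consecutive frames
#' before the movie (or the NH4+ epoch) ends; otherwise persistent. Events
#' too close to the end of the usable trace are persistent with a
#' `censored` attribute.
#'
#' @param trace The `dcv_roi_trace` the event was called on.
#' @param event One-row event data.frame (needs `onset_frame`).
#' @param params [detection_params()].
#' @param protocol A `dcv_protocol`.
#' @return `"persistent"` or `"transient"`, with attribute `censored`.
#' @export
classify_event_mode <- function(trace, event, params = detection_params(),
                                protocol = build_protocol()) {
  v <- trace$values
  Tn <- length(v)
  t_max <- Tn
  if (!is.null(protocol$nh4_start_s))
    t_max <- min(Tn, time_to_frame(protocol, protocol$nh4_start_s) - 1L)
  sigma0 <- trace$sigma0
  if (is.na(sigma0)) sigma0 <- 0
  thr <- trace$F0 + params$k_sigma * sigma0
  onset <- event$onset_frame
  if (t_max - onset < params$transient_return_frames)
    return(structure("persistent", censored = TRUE))
  below <- v[(onset + 1):t_max] < thr
  r <- rle(below)
  transient <- any(r$values & r$lengths >= params$transient_return_frames)
  structure(if (transient) "transient" else "persistent", censored = FALSE)
}

#' Detect a complete-cargo-release event on a red-cargo trace
#'
#' For pH-insensitive cargo, full release shows as the complete
#' disappearance of the punctum. The trace is first bleach-corrected
#' ratiometrically — divided by the soma's relative fluorescence course
#' `F_soma(t) / F_0^soma` — because the disappearance criterion is a
#' fractional intensity level: a subtractive correction leaves a pedestal
#' of `F0 * (1 - bleach)` that a fully released punctum could never drop
#' below late in a recording. An event is called when the corrected
#' intensity drops to at most `disappearance_frac` of the pre-drop mean
#' within `rise_frames_max` frames and remains there to the end of the
#' movie — "remains" meaning the post-drop mean stays at or below the
#' residual level and the trace never re-exceeds it for
#' `transient_return_frames` consecutive frames (isolated shot-noise
#' excursions do not cancel a disappearance). Without a soma trace an
#' exponential-fit correction is used instead (reported via a message).
#'
#' @param trace Red-channel `dcv_roi_trace` of the punctum.
#' @param soma_trace Soma-region `dcv_roi_trace`, or `NULL`.
#' @param params [detection_params()].
#' @param protocol A `dcv_protocol` (for onset times).
#' @return One-row event data.frame (`onset_frame`, `onset_time_s`,
#'   `mode = "full-release"`, `y_px`, `x_px`) or `NULL` when no event.
#' @export
detect_full_release <- function(trace, soma_trace = NULL,
                                params = detection_params(),
                                protocol = build_protocol()) {
  v <- trace$values
  Tn <- length(v)
  if (!is.null(soma_trace)) {
    rel <- soma_trace$values / soma_trace$F0
    if (any(rel <= 0)) stop("degenerate soma trace: non-positive values")
    corrected <- v / rel
  } else {
    message("soma trace missing; using exponential-fit bleach correction")
    tt <- seq_len(Tn)
    fitw <- seq_len(max(8L, Tn %/% 4L))
    fit <- stats::lm(log(pmax(v[fitw], 1e-6)) ~ tt[fitw])
    decay <- exp(stats::coef(fit)[1] + stats::coef(fit)[2] * tt)
    corrected <- v / (decay / decay[1])
  }
  rfm <- params$rise_frames_max
  for (t in seq.int(2L, Tn)) {
    pre_mean <- mean(corrected[seq_len(t - 1)])
    low <- params$disappearance_frac * pre_mean
    if (corrected[t] > low) next
    if (corrected[t - 1] <= low) next          # onset is the first low frame
    if (corrected[max(1, t - rfm)] < 0.5 * pre_mean) next  # not a sudden drop
    # must stay gone: on average below the residual level, with no
    # sustained recovery (isolated shot-noise excursions are tolerated)
    post <- corrected[t:Tn]
    if (mean(post) > low) next
    r <- rle(post > low)
    if (any(r$values & r$lengths >= params$transient_return_frames)) next
    return(data.frame(onset_frame = t,
                      onset_time_s = frame_to_time(protocol, t),
                      mode = "full-release",
                      y_px = trace$center[1], x_px = trace$center[2]))
  }
  NULL
}

#' Mean trace over a rectangular region
#'
#' @param movie A `dcv_movie`.
#' @param channel Channel name.
#' @param roi `c(y0, x0, y1, x1)` 0-based inclusive rectangle.
#' @param protocol,params As in [extract_trace()].
#' @return A `dcv_roi_trace` (center = rectangle centroid).
#' @export
extract_region_trace <- function(movie, channel, roi, protocol = NULL,
                                 params = detection_params()) {
  arr <- movie$channels[[channel]]
  if (is.null(arr)) stop("unknown channel: ", channel)
  block <- arr[(roi[1]:roi[3]) + 1, (roi[2]:roi[4]) + 1, , drop = FALSE]
  roi_trace(apply(block, 3, mean),
            center = c((roi[1] + roi[3]) / 2, (roi[2] + roi[4]) / 2),
            frame_interval_s = movie$frame_interval_s,
            protocol = protocol, params = params)
}

#' Movie-level fusion-event detection
#'
#' Finds candidate fusion sites as puncta appearing suddenly on
#' consecutive-frame difference images (which localizes each event at its
#' onset position and time, also for vesicles that keep moving after
#' fusion), extracts a 2x2 ROI trace at each site, applies the 2-SD event
#' rule and the persistent/transient classification — accepting only
#' events whose trace onset coincides with the sudden appearance — and
#' de-duplicates events detected at neighbouring ROIs. Candidates inside
#' the soma ROI are excluded (somatic release is not scored); NH4+ frames
#' are never scanned.
#'
#' @param movie A `dcv_movie`.
#' @param protocol A `dcv_protocol`.
#' @param channel Cargo channel (default `"cargo"`).
#' @param params [detection_params()].
#' @param soma_roi Optional `c(y0, x0, y1, x1)` somatic exclusion region.
#' @param candidate_k Threshold multiplier for candidate-site detection
#'   on the difference images (default 5).
#' @param dedupe_px,dedupe_frames Events closer than this in space and
#'   onset time are merged, keeping the larger peak (defaults 4 px,
#'   2 frames).
#' @param reject_moved_in Reject crossings explained by an already-bright
#'   punctum translating into the ROI rather than appearing de novo: when
#'   the baseline-subtracted image within `patch_radius_px` of the site,
#'   one to two frames before onset, already contains at least half the
#'   onset step, the crossing is an arrival, not a fusion (default TRUE).
#' @param patch_radius_px Radius of the pre-onset arrival check
#'   (default 2).
#' @param include_prestim Keep events flagged pre-stimulation?
#'   (default FALSE).
#' @return Event data.frame: onset, peak `dF/F0`, mode, position.
#' @export
detect_fusion_events <- function(movie, protocol, channel = "cargo",
                                 params = detection_params(),
                                 soma_roi = NULL, candidate_k = 5,
                                 dedupe_px = 4, dedupe_frames = 2,
                                 reject_moved_in = TRUE, patch_radius_px = 2,
                                 include_prestim = FALSE) {
  arr <- movie$channels[[channel]]
  d <- dim(arr)
  Tn <- d[3]
  base <- apply(arr[, , seq_len(min(params$baseline_frames, Tn)), drop = FALSE],
                c(1, 2), mean)
  t_max <- Tn
  if (!is.null(protocol$nh4_start_s))
    t_max <- min(Tn, time_to_frame(protocol, protocol$nh4_start_s) - 1L)

  # candidate (site, onset-hint) pairs from sudden appearances
  cand <- list()
  for (t in seq.int(2L, t_max)) {
    pts <- detect_puncta(arr[, , t] - arr[, , t - 1], k = candidate_k)
    if (nrow(pts)) cand[[length(cand) + 1]] <-
        data.frame(y_px = pts$y_px, x_px = pts$x_px, t_hint = t)
  }
  cand <- if (length(cand)) do.call(rbind, cand) else
    data.frame(y_px = numeric(0), x_px = numeric(0), t_hint = integer(0))
  if (!is.null(soma_roi) && nrow(cand)) {
    inside <- cand$y_px >= soma_roi[1] & cand$y_px <= soma_roi[3] &
      cand$x_px >= soma_roi[2] & cand$x_px <= soma_roi[4]
    cand <- cand[!inside, , drop = FALSE]
  }

  out <- list()
  trace_cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(cand))) {
    ctr <- c(cand$y_px[i], cand$x_px[i])
    tl <- roi_topleft(ctr, 2)
    if (any(tl < 0) || tl[1] + 2 > d[1] || tl[2] + 2 > d[2]) next
    key <- paste(tl, collapse = "_")
    ev <- get0(key, envir = trace_cache)
    if (is.null(ev)) {
      tr <- extract_trace(movie, channel, ctr, roi_size = 2,
                          protocol = protocol, params = params)
      veto <- NULL
      if (reject_moved_in) {
        ys <- max(1, round(ctr[1]) + 1 - patch_radius_px):
          min(d[1], round(ctr[1]) + 1 + patch_radius_px)
        xs <- max(1, round(ctr[2]) + 1 - patch_radius_px):
          min(d[2], round(ctr[2]) + 1 + patch_radius_px)
        veto <- function(t0, step) {
          if (t0 < 2) return(TRUE)
          pre <- max(1, t0 - 2):(t0 - 1)
          patch_max <- max(arr[ys, xs, pre, drop = FALSE] - c(base[ys, xs]))
          patch_max < 0.5 * step
        }
      }
      ev <- detect_fusion_phluorin(tr, params, protocol, arrival_veto = veto)
      if (nrow(ev))
        ev$mode <- vapply(seq_len(nrow(ev)), function(k)
          as.character(classify_event_mode(tr, ev[k, ], params, protocol)), "")
      assign(key, ev, envir = trace_cache)
    }
    if (!nrow(ev)) next
    # the trace onset must coincide with the sudden appearance
    ev <- ev[abs(ev$onset_frame - cand$t_hint[i]) <= 2, , drop = FALSE]
    if (nrow(ev)) out[[length(out) + 1]] <- ev
  }
  events <- if (length(out)) do.call(rbind, out) else
    data.frame(onset_frame = integer(0), onset_time_s = numeric(0),
               peak_dff = numeric(0), pre_stim = logical(0),
               degenerate = logical(0), y_px = numeric(0), x_px = numeric(0),
               mode = character(0))
  if (!include_prestim) events <- events[!events$pre_stim, , drop = FALSE]
  if (nrow(events) > 1) {
    keep <- order(-events$peak_dff)
    accepted <- integer(0)
    for (i in keep) {
      dup <- FALSE
      for (j in accepted) {
        if (abs(events$onset_frame[i] - events$onset_frame[j]) <= dedupe_frames &&
            sqrt((events$y_px[i] - events$y_px[j])^2 +
                 (events$x_px[i] - events$x_px[j])^2) <= dedupe_px) {
          dup <- TRUE; break
        }
      }
      if (!dup) accepted <- c(accepted, i)
    }
    events <- events[sort(accepted), , drop = FALSE]
  }
  rownames(events) <- NULL
  events
}
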