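#' Scene configuration for the synthetic movie generator
#'
#' Collects every tunable of the ground-truth simulator: geometry, vesicle
#' kinetics, fusion behaviour, optics and noise. Defaults emulate the study
#' conditions of a cultured-neuron DCV fusion assay: roughly one third of
#' vesicles mobile at ~190 nm/s, 60% of pHluorin fusion events transient,
#' diffraction-limited puncta on neurite paths, EMCCD-like Poisson + read
#' noise, and mild photobleaching.
#'
#' @param image_shape `c(Y, X)` in pixels.
#' @param n_neurites Number of neurite paths.
#' @param n_synapses Number of synapse-marker puncta (placed on neurites).
#' @param n_vesicles Number of labeled vesicles.
#' @param frac_mobile Fraction of vesicles that are mobile (default 0.33).
#' @param speed_mean_nm_s,speed_sd_nm_s Mobile speed distribution
#'   (defaults 190 and 30 nm/s).
#' @param reversal_prob Per-frame probability that a mobile vesicle
#'   reverses direction (default 0.02).
#' @param psf_sigma_px Gaussian PSF sigma in pixels (default 1.3).
#' @param amp_photons Peak photons of an unquenched cargo punctum.
#' @param quench_frac Residual pHluorin brightness at vesicular pH,
#'   as a fraction of `amp_photons` (default 0.03; ignored for the red
#'   reporter, which is pH-insensitive).
#' @param background_photons Diffuse fluorescent background (photons/px).
#' @param read_noise_sd Gaussian read noise SD in counts (0 disables).
#' @param poisson_noise Apply Poisson shot noise to photon counts?
#' @param bleach_tau_s Photobleaching time constant in seconds
#'   (`Inf` disables; default 300).
#' @param fusion_prob_stationary,fusion_prob_mobile Probability that a
#'   vesicle of that class fuses during the stimulation epoch.
#' @param frac_transient Fraction of pHluorin events that decay back to
#'   baseline rather than staying high (default 0.6).
#' @param transient_tau_s Exponential decay constant of transient events
#'   (default 5 s).
#' @param reporter `"phluorin"` (quenched until fusion; step unquench;
#'   NH4+ reveals all) or `"red"` (always visible; full-release events
#'   disappear completely).
#' @param synapse_amp_photons Peak photons of a synapse-marker punctum.
#' @param soma_extra_photons Extra diffuse photons/px inside the soma ROI.
#' @param min_spacing_px Minimum initial spacing between vesicles.
#' @param margin_px Border kept free of paths so spots stay inside.
#' @param rng_seed Integer seed fixing every stochastic draw.
#' @return A list of class `dcv_scene_config`.
#' @export
scene_config <- function(image_shape = c(96, 96),
                         n_neurites = 3,
                         n_synapses = 12,
                         n_vesicles = 30,
                         frac_mobile = 0.33,
                         speed_mean_nm_s = 190,
                         speed_sd_nm_s = 30,
                         reversal_prob = 0.02,
                         psf_sigma_px = 1.3,
                         amp_photons = 400,
                         quench_frac = 0.03,
                         background_photons = 20,
                         read_noise_sd = 2,
                         poisson_noise = TRUE,
                         bleach_tau_s = 300,
                         fusion_prob_stationary = 0.5,
                         fusion_prob_mobile = 0.3,
                         frac_transient = 0.6,
                         transient_tau_s = 5,
                         reporter = c("phluorin", "red"),
                         synapse_amp_photons = 300,
                         soma_extra_photons = 100,
                         min_spacing_px = 5,
                         margin_px = NULL,
                         rng_seed = 1L) {
  reporter <- match.arg(reporter)
  fr <- c(frac_mobile, frac_transient, fusion_prob_stationary, fusion_prob_mobile)
  if (any(fr < 0 | fr > 1)) stop("invalid config: fractions must lie in [0, 1]")
  if (amp_photons < 0 || background_photons < 0)
    stop("invalid config: photon rates must be >= 0")
  if (is.null(margin_px)) margin_px <- ceiling(4 * psf_sigma_px) + 2
  structure(as.list(environment()), class = "dcv_scene_config")
}

# Peak-normalized isotropic Gaussian spot added in place into `img`
# around continuous 0-based position (y0, x0); returns modified matrix.
add_spot <- function(img, y0, x0, amp, sigma) {
  if (amp == 0) return(img)
  r <- ceiling(4 * sigma)
  ys <- max(0, floor(y0) - r):min(nrow(img) - 1, ceiling(y0) + r)
  xs <- max(0, floor(x0) - r):min(ncol(img) - 1, ceiling(x0) + r)
  if (!length(ys) || !length(xs)) return(img)
  g <- amp * exp(-outer((ys - y0)^2, (xs - x0)^2, "+") / (2 * sigma^2))
  img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] + g
  img
}

# Random neurite polylines: gently bent chains of segments spanning the
# usable area.
make_neurites <- function(shape, n, margin) {
  lapply(seq_len(n), function(i) {
    lo <- margin; hiY <- shape[1] - 1 - margin; hiX <- shape[2] - 1 - margin
    p0 <- c(stats::runif(1, lo, hiY), stats::runif(1, lo, hiX))
    ang <- stats::runif(1, 0, 2 * pi)
    pts <- matrix(p0, ncol = 2)
    step <- max(hiY - lo, hiX - lo) / 4
    for (k in 1:6) {
      ang <- ang + stats::rnorm(1, 0, 0.25)
      nxt <- pts[nrow(pts), ] + step * c(sin(ang), cos(ang))
      # reflect off the usable-area walls
      if (nxt[1] < lo || nxt[1] > hiY) { ang <- -ang; nxt[1] <- pmin(pmax(nxt[1], lo), hiY) }
      if (nxt[2] < lo || nxt[2] > hiX) { ang <- pi - ang; nxt[2] <- pmin(pmax(nxt[2], lo), hiX) }
      pts <- rbind(pts, nxt)
    }
    unname(pts)
  })
}

#' Simulate a ground-truth-annotated DCV fusion movie
#'
#' Renders a multi-channel time-lapse: a cargo channel (pHluorin or red),
#' a synapse-marker channel, plus a bright soma region usable as a
#' bleaching reference. Vesicles sit on neurite polylines; the mobile
#' fraction advances along its path at speeds drawn from the configured
#' distribution with occasional direction reversals. Fusion events occur
#' only during the stimulation epoch: pHluorin events add a step unquench
#' at onset (transient events then decay exponentially), red-cargo
#' full-release events set the punctum amplitude to zero. All fluorescence
#' decays with the bleaching constant; counts are Poisson photons plus
#' Gaussian read noise. If the protocol defines an NH4+ epoch, every
#' vesicle in the pHluorin channel is de-quenched for its duration.
#'
#' @param config A [scene_config()].
#' @param protocol A [build_protocol()].
#' @return List with `movie` (class `dcv_movie`: named channel list of
#'   `Y x X x T` arrays plus `pixel_size_um`, `frame_interval_s`) and
#'   `truth` (vesicle trajectories and motility labels, fusion events with
#'   onset frame and mode, synapse table, soma ROI, neurite paths).
#' @export
simulate_scene <- function(config, protocol = build_protocol()) {
  stopifnot(inherits(config, "dcv_scene_config"), inherits(protocol, "dcv_protocol"))
  with_seed(config$rng_seed, simulate_scene_impl(config, protocol))
}

simulate_scene_impl <- function(cfg, protocol) {
  shape <- cfg$image_shape
  T_ <- protocol$n_frames
  dt <- protocol$frame_interval_s
  px_um <- protocol$pixel_size_um

  neurites <- make_neurites(shape, cfg$n_neurites, cfg$margin_px)
  path_len <- vapply(neurites, function(p) max(path_arclength(p)), 0)

  # soma: diffuse bright rectangle in one corner of the usable area
  soma_h <- max(6L, round(shape[1] * 0.18))
  soma_w <- max(6L, round(shape[2] * 0.18))
  soma_roi <- c(y0 = 1, x0 = 1, y1 = soma_h, x1 = soma_w)  # 0-based, inclusive

  # synapses along neurites
  syn <- NULL
  if (cfg$n_synapses > 0) {
    ni <- sample.int(cfg$n_neurites, cfg$n_synapses, replace = TRUE,
                     prob = path_len / sum(path_len))
    sp <- stats::runif(cfg$n_synapses, 0, path_len[ni])
    syn <- t(vapply(seq_len(cfg$n_synapses),
                    function(i) path_point(neurites[[ni[i]]], sp[i]), c(0, 0)))
  }
  synapses <- data.frame(id = seq_len(NROW(syn)),
                         y_px = if (is.null(syn)) numeric(0) else syn[, 1],
                         x_px = if (is.null(syn)) numeric(0) else syn[, 2])

  # vesicle placement with minimum spacing (capacity check)
  nv <- cfg$n_vesicles
  capacity <- floor(sum(path_len) / cfg$min_spacing_px)
  if (nv > capacity)
    stop(sprintf("capacity error: %d vesicles exceed spacing capacity %d",
                 nv, capacity))
  ves_path <- integer(0); ves_s <- numeric(0)
  if (nv > 0) {
    placed <- 0; tries <- 0
    ves_path <- integer(nv); ves_s <- numeric(nv)
    pos0 <- matrix(NA_real_, nv, 2)
    while (placed < nv) {
      tries <- tries + 1
      if (tries > 200 * nv)
        stop("capacity error: could not place vesicles at the configured spacing")
      pi_ <- sample.int(cfg$n_neurites, 1, prob = path_len / sum(path_len))
      s <- stats::runif(1, 0, path_len[pi_])
      p <- path_point(neurites[[pi_]], s)
      if (placed > 0) {
        d <- sqrt((pos0[seq_len(placed), 1] - p[1])^2 +
                  (pos0[seq_len(placed), 2] - p[2])^2)
        if (min(d) < cfg$min_spacing_px) next
      }
      placed <- placed + 1
      ves_path[placed] <- pi_; ves_s[placed] <- s; pos0[placed, ] <- p
    }
  }

  mobile <- rep(FALSE, nv)
  if (nv > 0) mobile[sample.int(nv, round(cfg$frac_mobile * nv))] <- TRUE

  # trajectories: arclength random walk with piecewise-constant speed
  pos <- array(NA_real_, c(nv, T_, 2))
  if (nv > 0) {
    speeds_nm <- pmax(1, stats::rnorm(nv, cfg$speed_mean_nm_s, cfg$speed_sd_nm_s))
    speed_px <- speeds_nm * 1e-3 / px_um * dt   # px per frame
    dir <- sample(c(-1, 1), nv, replace = TRUE)
    s_cur <- ves_s
    for (t in seq_len(T_)) {
      for (v in seq_len(nv)) {
        if (t > 1 && mobile[v]) {
          if (stats::runif(1) < cfg$reversal_prob) dir[v] <- -dir[v]
          s_new <- s_cur[v] + dir[v] * speed_px[v]
          L <- path_len[ves_path[v]]
          if (s_new < 0) { s_new <- -s_new; dir[v] <- 1 }
          if (s_new > L) { s_new <- 2 * L - s_new; dir[v] <- -1 }
          s_cur[v] <- s_new
        }
        pos[v, t, ] <- path_point(neurites[[ves_path[v]]], s_cur[v])
      }
    }
  }

  # fusion schedule: stim-epoch-gated
  sf <- stim_frames(protocol)
  events <- data.frame(vesicle = integer(0), onset_frame = integer(0),
                       mode = character(0), y_px = numeric(0), x_px = numeric(0))
  if (nv > 0) {
    p_fuse <- ifelse(mobile, cfg$fusion_prob_mobile, cfg$fusion_prob_stationary)
    fuses <- stats::runif(nv) < p_fuse
    for (v in which(fuses)) {
      onset <- sample(sf, 1)
      mode <- if (cfg$reporter == "red") "full-release"
              else if (stats::runif(1) < cfg$frac_transient) "transient"
              else "persistent"
      events <- rbind(events, data.frame(
        vesicle = v, onset_frame = onset, mode = mode,
        y_px = pos[v, onset, 1], x_px = pos[v, onset, 2]))
    }
    if (nrow(events)) {
      events <- events[order(events$onset_frame), , drop = FALSE]
      # somatic events exist in truth but release scoring excludes them
      events$somatic <- events$y_px >= soma_roi[1] & events$y_px <= soma_roi[3] &
        events$x_px >= soma_roi[2] & events$x_px <= soma_roi[4]
    } else events$somatic <- logical(0)
    rownames(events) <- NULL
  }

  # per-frame punctum amplitude in the cargo channel
  amp <- matrix(if (cfg$reporter == "phluorin") cfg$amp_photons * cfg$quench_frac
                else cfg$amp_photons, nv, T_)
  if (nrow(events)) {
    for (k in seq_len(nrow(events))) {
      v <- events$vesicle[k]; t0 <- events$onset_frame[k]
      if (events$mode[k] == "full-release") {
        amp[v, t0:T_] <- 0
      } else if (events$mode[k] == "persistent") {
        amp[v, t0:T_] <- cfg$amp_photons
      } else {
        tt <- (seq.int(t0, T_) - t0) * dt
        base <- cfg$amp_photons * cfg$quench_frac
        amp[v, t0:T_] <- base + (cfg$amp_photons - base) * exp(-tt / cfg$transient_tau_s)
      }
    }
  }
  if (cfg$reporter == "phluorin" && !is.null(protocol$nh4_start_s)) {
    nh <- nh4_frames(protocol)
    amp[, nh] <- cfg$amp_photons
  }

  # render channels
  bleach <- if (is.finite(cfg$bleach_tau_s))
    exp(-(seq_len(T_) - 1) * dt / cfg$bleach_tau_s) else rep(1, T_)
  soma_mask <- matrix(0, shape[1], shape[2])
  soma_mask[(soma_roi[1]:soma_roi[3]) + 1, (soma_roi[2]:soma_roi[4]) + 1] <- 1
  base_img <- cfg$background_photons + cfg$soma_extra_photons * soma_mask

  syn_img <- base_img
  if (nrow(synapses)) for (i in seq_len(nrow(synapses)))
    syn_img <- add_spot(syn_img, synapses$y_px[i], synapses$x_px[i],
                        cfg$synapse_amp_photons, cfg$psf_sigma_px)

  cargo <- array(0, c(shape[1], shape[2], T_))
  synch <- array(0, c(shape[1], shape[2], T_))
  for (t in seq_len(T_)) {
    img <- base_img
    if (nv > 0) for (v in seq_len(nv))
      img <- add_spot(img, pos[v, t, 1], pos[v, t, 2], amp[v, t], cfg$psf_sigma_px)
    cargo[, , t] <- img * bleach[t]
    synch[, , t] <- syn_img * bleach[t]
  }
  if (cfg$poisson_noise) {
    cargo[] <- stats::rpois(length(cargo), lambda = cargo)
    synch[] <- stats::rpois(length(synch), lambda = synch)
  }
  if (cfg$read_noise_sd > 0) {
    cargo[] <- cargo + stats::rnorm(length(cargo), 0, cfg$read_noise_sd)
    synch[] <- synch + stats::rnorm(length(synch), 0, cfg$read_noise_sd)
  }

  movie <- structure(list(
    channels = list(cargo = cargo, synapse = synch),
    pixel_size_um = px_um, frame_interval_s = dt,
    reporter = cfg$reporter), class = "dcv_movie")

  truth <- list(
    vesicles = data.frame(id = seq_len(nv), motility = ifelse(mobile, "moving", "stationary")),
    positions = pos,
    events = events,
    synapses = synapses,
    soma_roi = soma_roi,
    neurites = neurites,
    config = cfg, protocol = protocol)
  list(movie = movie, truth = truth)
}

#' @export
print.dcv_movie <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("DCV movie: %d x %d px, %d frames, channels: %s\n",
              d[1], d[2], d[3], paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Number of frames in a movie
#' @param movie A `dcv_movie`.
#' @return Integer frame count.
#' @export
n_frames <- function(movie) dim(movie$channels[[1]])[3]

#' Simulate punctum tracks without rendering a movie
#'
#' Generates linear-path trajectories with optional drift speed and
#' Gaussian localization jitter, as produced by centroid fitting of
#' diffraction-limited puncta. Speed 0 yields jitter-only stationary
#' tracks. Used to probe the motility classifier and velocity estimators
#' directly, at known ground truth.
#'
#' @param n_tracks Number of tracks.
#' @param n_frames Frames per track.
#' @param speed_nm_s Drift speed along the path (0 = stationary).
#' @param speed_sd_nm_s Between-track SD of the drift speed.
#' @param loc_sd_nm Localization jitter SD per coordinate (default 30 nm).
#' @param reversal_prob Per-frame direction reversal probability.
#' @param pixel_size_um,frame_interval_s Calibration (defaults 0.2, 0.5).
#' @param seed RNG seed.
#' @return List of track data.frames (`frame`, `y_px`, `x_px`).
#' @export
simulate_tracks <- function(n_tracks, n_frames = 60, speed_nm_s = 0,
                            speed_sd_nm_s = 0, loc_sd_nm = 30,
                            reversal_prob = 0.02,
                            pixel_size_um = 0.2, frame_interval_s = 0.5,
                            seed = 1L) {
  with_seed(seed, {
    lapply(seq_len(n_tracks), function(i) {
      ang <- stats::runif(1, 0, 2 * pi)
      u <- c(sin(ang), cos(ang))
      v_px <- max(0, stats::rnorm(1, speed_nm_s, speed_sd_nm_s)) *
        1e-3 / pixel_size_um * frame_interval_s
      dir <- sample(c(-1, 1), 1)
      s <- numeric(n_frames)
      for (t in 2:n_frames) {
        if (stats::runif(1) < reversal_prob) dir <- -dir
        s[t] <- s[t - 1] + dir * v_px
      }
      jit <- matrix(stats::rnorm(2 * n_frames, 0, loc_sd_nm * 1e-3 / pixel_size_um),
                    ncol = 2)
      data.frame(frame = seq_len(n_frames),
                 y_px = 500 + s * u[1] + jit[, 1],
                 x_px = 500 + s * u[2] + jit[, 2])
    })
  })
}

#' Simulate an activity-triggered protein dispersion movie
#'
#' Emulates the synaptic-protein dispersion experiment: punctate synaptic
#' enrichment on a neurite band, imaged at 0.5 Hz for 3 minutes with
#' stimulation at 30 s. After stimulation onset each synaptic punctum loses
#' `loss_frac` of its integrated intensity over `ramp_s` seconds; the lost
#' mass reappears uniformly over the neurite band, so total fluorescence is
#' conserved before bleaching and noise. A diffuse soma region provides the
#' bleaching reference.
#'
#' @param n_synaptic,n_extra Numbers of synaptic and extra-synaptic ROIs.
#' @param loss_frac Fraction of synaptic intensity dispersed (default 0.3).
#' @param ramp_s Dispersion ramp duration after stim onset (default 30 s).
#' @param amp_photons Synaptic punctum peak photons (default 600).
#' @param psf_sigma_px PSF sigma (default 1.3).
#' @param background_photons Diffuse background (default 20).
#' @param bleach_tau_s Bleaching constant (default 400 s; `Inf` disables).
#' @param read_noise_sd,poisson_noise Noise settings.
#' @param image_shape Image size (default 96 x 96).
#' @param protocol Acquisition protocol (default 0.5 Hz, 180 s, stim at 30 s).
#' @param rng_seed Seed.
#' @return List with `movie` (single channel `protein`), `synaptic_rois`,
#'   `extra_rois` (data.frames of 0-based centers), `soma_roi`, `protocol`,
#'   and `truth` (the configured loss fraction and ramp).
#' @export
simulate_dispersion_scene <- function(n_synaptic = 10, n_extra = 10,
                                      loss_frac = 0.3, ramp_s = 30,
                                      amp_photons = 600, psf_sigma_px = 1.3,
                                      background_photons = 20,
                                      bleach_tau_s = 400,
                                      read_noise_sd = 1, poisson_noise = TRUE,
                                      image_shape = c(96, 96),
                                      protocol = build_protocol(
                                        frame_interval_s = 2, movie_duration_s = 180),
                                      rng_seed = 1L) {
  with_seed(rng_seed, {
    shape <- image_shape; T_ <- protocol$n_frames; dt <- protocol$frame_interval_s
    margin <- ceiling(4 * psf_sigma_px) + 2
    soma_h <- max(6L, round(shape[1] * 0.18)); soma_w <- max(6L, round(shape[2] * 0.18))
    soma_roi <- c(y0 = 1, x0 = 1, y1 = soma_h, x1 = soma_w)

    # neurite band: horizontal strip in the lower half, away from the soma
    band_y <- c(round(shape[1] * 0.55), round(shape[1] * 0.9))
    band_x <- c(margin, shape[2] - 1 - margin)
    band_area <- (band_y[2] - band_y[1] + 1) * (band_x[2] - band_x[1] + 1)

    xs <- seq(band_x[1] + 2, band_x[2] - 2, length.out = n_synaptic + n_extra)
    ord <- sample(seq_along(xs))
    syn_idx <- sort(ord[seq_len(n_synaptic)])
    ext_idx <- sort(ord[n_synaptic + seq_len(n_extra)])
    ys <- stats::runif(length(xs), band_y[1] + 2, band_y[2] - 2)
    synaptic_rois <- data.frame(id = seq_len(n_synaptic),
                                y_px = ys[syn_idx], x_px = xs[syn_idx])
    extra_rois <- data.frame(id = seq_len(n_extra),
                             y_px = ys[ext_idx], x_px = xs[ext_idx])

    bleach <- if (is.finite(bleach_tau_s))
      exp(-(seq_len(T_) - 1) * dt / bleach_tau_s) else rep(1, T_)
    soma_mask <- matrix(0, shape[1], shape[2])
    soma_mask[(soma_roi[1]:soma_roi[3]) + 1, (soma_roi[2]:soma_roi[4]) + 1] <- 1
    band_mask <- matrix(0, shape[1], shape[2])
    band_mask[(band_y[1]:band_y[2]) + 1, (band_x[1]:band_x[2]) + 1] <- 1
    base_img <- background_photons + 120 * soma_mask

    spot_mass <- amp_photons * 2 * pi * psf_sigma_px^2
    frames <- array(0, c(shape[1], shape[2], T_))
    tvec <- (seq_len(T_) - 1) * dt
    for (t in seq_len(T_)) {
      # dispersed fraction at this time: 0 before stim, ramps to loss_frac
      f <- if (tvec[t] < protocol$stim_start_s) 0 else
        loss_frac * min(1, (tvec[t] - protocol$stim_start_s) / ramp_s)
      img <- base_img
      for (i in seq_len(n_synaptic))
        img <- add_spot(img, synaptic_rois$y_px[i], synaptic_rois$x_px[i],
                        amp_photons * (1 - f), psf_sigma_px)
      img <- img + band_mask * (f * spot_mass * n_synaptic / band_area)
      frames[, , t] <- img * bleach[t]
    }
    if (poisson_noise) frames[] <- stats::rpois(length(frames), frames)
    if (read_noise_sd > 0)
      frames[] <- frames + stats::rnorm(length(frames), 0, read_noise_sd)

    movie <- structure(list(channels = list(protein = frames),
                            pixel_size_um = protocol$pixel_size_um,
                            frame_interval_s = dt, reporter = "protein"),
                       class = "dcv_movie")
    list(movie = movie, synaptic_rois = synaptic_rois, extra_rois = extra_rois,
         soma_roi = soma_roi, protocol = protocol,
         truth = list(loss_frac = loss_frac, ramp_s = ramp_s, band_y = band_y,
                      band_x = band_x))
  })
}
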