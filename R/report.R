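#' Cumulative release curve
#'
#' Non-decreasing step curve of the cumulative number of fusion events
#' per frame. Optionally restricted to events during the first
#' `first_n_bursts` bursts of the stimulation train.
#'
#' @param events Event data.frame with `onset_frame` and `onset_time_s`.
#' @param protocol A `dcv_protocol`.
#' @param first_n_bursts Optional restriction to the leading bursts.
#' @return data.frame `frame`, `time_s`, `cumulative`.
#' @export
cumulative_curve <- function(events, protocol, first_n_bursts = NULL) {
  if (!is.null(first_n_bursts)) {
    w <- first_bursts_window(protocol, first_n_bursts)
    events <- events[events$onset_time_s >= w[1] & events$onset_time_s < w[2], ,
                     drop = FALSE]
  }
  frames <- seq_len(protocol$n_frames)
  counts <- tabulate(events$onset_frame, nbins = protocol$n_frames)
  data.frame(frame = frames, time_s = frame_to_time(protocol, frames),
             cumulative = cumsum(counts))
}

#' Fusion rate during stimulation
#'
#' Events with onset inside the stimulation epoch divided by the epoch
#' duration, in vesicles per second.
#'
#' @param events Event data.frame with `onset_time_s`.
#' @param protocol A `dcv_protocol`.
#' @return Rate in vesicles/s.
#' @export
fusion_rate <- function(events, protocol) {
  if (protocol$stim_duration_s <= 0) stop("zero-length stimulation epoch")
  n <- sum(events$onset_time_s >= protocol$stim_start_s &
             events$onset_time_s < protocol$stim_end_s)
  n / protocol$stim_duration_s
}

#' Normalized histogram of event amplitudes
#'
#' Bins peak \eqn{\Delta F / F_0} values; each bin is normalized to the
#' total number of events, so the fractions sum to 1.
#'
#' @param peaks Numeric vector of peak `dF/F0` values (or an event
#'   data.frame with a `peak_dff` column).
#' @param n_bins Number of equal-width bins (default 10).
#' @return data.frame `bin_lo`, `bin_hi`, `fraction`.
#' @export
dff_histogram <- function(peaks, n_bins = 10) {
  if (is.data.frame(peaks)) peaks <- peaks$peak_dff
  if (!length(peaks)) stop("undefined histogram: no events")
  rng <- range(peaks)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- graphics::hist(peaks, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE)
  data.frame(bin_lo = utils::head(h$breaks, -1), bin_hi = h$breaks[-1],
             fraction = h$counts / sum(h$counts))
}

#' Two-group (or multi-group) comparison with automatic test selection
#'
#' Reproduces the test-selection policy of the underlying assays: each
#' group is screened for normality with the Kolmogorov-Smirnov-type
#' Lilliefors test; when both groups pass, an unpaired t test is used
#' (Welch-corrected when an F test finds the variances unequal);
#' otherwise the Mann-Whitney test. With more than two groups a
#' Kruskal-Wallis test is used, followed by Bonferroni-corrected pairwise
#' Mann-Whitney comparisons.
#'
#' @param valuesA,valuesB Numeric vectors (>= 3 values each).
#' @param ... Further groups (switches to the multi-group path).
#' @param alpha Screening level for normality and variance-equality
#'   (default 0.05).
#' @return List: `test` (name), `statistic`, `p_value`, `normal`
#'   (per-group screen), and for >2 groups `pairwise` (Bonferroni-adjusted
#'   p matrix).
#' @export
compare_groups <- function(valuesA, valuesB, ..., alpha = 0.05) {
  groups <- c(list(valuesA, valuesB), list(...))
  if (any(vapply(groups, length, 0L) < 3))
    stop("insufficient data: each group needs >= 3 values")
  is_normal <- function(x) {
    if (length(x) < 5 || stats::sd(x) == 0) return(FALSE)
    p <- tryCatch(nortest::lillie.test(x)$p.value, error = function(e) 0)
    p > alpha
  }
  normal <- vapply(groups, is_normal, TRUE)

  if (length(groups) == 2) {
    a <- groups[[1]]; b <- groups[[2]]
    if (all(normal)) {
      equal_var <- tryCatch(stats::var.test(a, b)$p.value > alpha,
                            error = function(e) TRUE)
      tt <- stats::t.test(a, b, var.equal = equal_var)
      return(list(test = if (equal_var) "t-test" else "Welch t-test",
                  statistic = unname(tt$statistic), p_value = tt$p.value,
                  normal = normal))
    }
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
    return(list(test = "Mann-Whitney", statistic = unname(wt$statistic),
                p_value = wt$p.value, normal = normal))
  }

  kw <- stats::kruskal.test(groups)
  x <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  pw <- suppressWarnings(stats::pairwise.wilcox.test(
    x, g, p.adjust.method = "bonferroni", exact = FALSE))
  list(test = "Kruskal-Wallis", statistic = unname(kw$statistic),
       p_value = kw$p.value, normal = normal, pairwise = pw$p.value)
}

#' Per-cell summary of a DCV fusion assay
#'
#' @param events Annotated event data.frame (columns `onset_time_s`;
#'   optionally `synaptic`, `motility`).
#' @param protocol A `dcv_protocol`.
#' @param cell_id,label Identifiers for the cell and its condition.
#' @param pool_count Total labeled vesicle pool (e.g. from
#'   [count_pool_nh4()]), or `NA`.
#' @return One-row data.frame: `cell_id`, `label`, `n_events`,
#'   `n_events_first4bursts`, `fraction_synaptic`,
#'   `fraction_stationary_prior_to_fusion`, `fusion_rate_stim`,
#'   `pool_count`, `non_secreting`.
#' @export
cell_summary <- function(events, protocol, cell_id = "cell1", label = "",
                         pool_count = NA_integer_) {
  n <- nrow(events)
  w4 <- first_bursts_window(protocol, 4)
  n4 <- sum(events$onset_time_s >= w4[1] & events$onset_time_s < w4[2])
  frac_syn <- if (n && !is.null(events$synaptic))
    mean(events$synaptic == "synaptic") else NA_real_
  frac_stat <- if (n && !is.null(events$motility) && any(!is.na(events$motility)))
    mean(events$motility == "stationary", na.rm = TRUE) else NA_real_
  data.frame(cell_id = cell_id, label = label, n_events = n,
             n_events_first4bursts = n4,
             fraction_synaptic = frac_syn,
             fraction_stationary_prior_to_fusion = frac_stat,
             fusion_rate_stim = fusion_rate(events, protocol),
             pool_count = pool_count, non_secreting = n == 0)
}

#' Group average of per-cell summaries
#'
#' Averages per-cell event counts with non-secreting cells excluded (they
#' are reported separately as a percentage), mirroring how per-cell
#' release statistics are reported.
#'
#' @param summaries data.frame of rbind-ed [cell_summary()] rows.
#' @return List: `n_cells`, `pct_non_secreting`, `mean_events`
#'   (secreting cells only), `mean_rate`.
#' @export
summarize_cells <- function(summaries) {
  sec <- summaries[!summaries$non_secreting, , drop = FALSE]
  list(n_cells = nrow(summaries),
       pct_non_secreting = 100 * mean(summaries$non_secreting),
       mean_events = if (nrow(sec)) mean(sec$n_events) else NA_real_,
       mean_rate = if (nrow(sec)) mean(sec$fusion_rate_stim) else NA_real_)
}

#' Annotate events with synaptic assignment and prior motility
#'
#' @param events Event data.frame with `y_px`, `x_px`, `onset_frame`.
#' @param synapses Synapse centroid data.frame (`y_px`, `x_px`) or NULL.
#' @param tracks Optional list of tracks; each event inherits the motility
#'   class of the nearest track present at onset (within `match_px`).
#' @param protocol A `dcv_protocol`.
#' @param radius_nm Synaptic assignment radius (default 200).
#' @param match_px Event-to-track matching radius (default 3).
#' @return `events` with `synaptic` and `motility` columns added.
#' @export
annotate_events <- function(events, synapses, tracks = NULL, protocol,
                            radius_nm = 200, match_px = 3) {
  if (!nrow(events)) {
    events$synaptic <- character(0); events$motility <- character(0)
    return(events)
  }
  events$synaptic <- as.character(assign_synaptic(
    cbind(events$y_px, events$x_px), synapses, radius_nm,
    protocol$pixel_size_um))
  events$motility <- NA_character_
  if (!is.null(tracks) && length(tracks)) {
    cls <- vapply(tracks, function(tr) as.character(classify_motility(tr)), "")
    for (k in seq_len(nrow(events))) {
      best <- NA_integer_; bestd <- Inf
      for (i in seq_along(tracks)) {
        tr <- tracks[[i]]
        # position at (or nearest to) the frame before onset
        j <- which.min(abs(tr$frame - (events$onset_frame[k] - 1)))
        if (abs(tr$frame[j] - events$onset_frame[k]) > 2) next
        d <- sqrt((tr$y_px[j] - events$y_px[k])^2 +
                  (tr$x_px[j] - events$x_px[k])^2)
        if (d < bestd) { bestd <- d; best <- i }
      }
      if (!is.na(best) && bestd <= match_px) events$motility[k] <- cls[best]
    }
  }
  events
}

#' Run the full simulate-detect-classify-report pipeline
#'
#' Simulates a scene (or accepts one), detects fusion events, assigns
#' them to synapses, derives motility from tracks where the cargo is
#' visible before fusion (red reporter), and writes the report bundle:
#' `events.csv`, `summary.csv`, `cumulative.csv`, `coloc.json`, and
#' `log.yaml` with every resolved parameter and the seed.
#'
#' @param config List (or path to a YAML file) with optional entries
#'   `seed`, `protocol` (arguments to [build_protocol()]), `scene`
#'   (arguments to [scene_config()]), `detection` (arguments to
#'   [detection_params()]), `cell_id`, `label`.
#' @param out_dir Output directory; created if needed. `NULL` skips
#'   writing.
#' @param sim Optional pre-simulated scene (overrides `scene`).
#' @return List of class `dcv_report`: `events`, `summary`, `cumulative`,
#'   `coloc`, `tracks`, `protocol`, `config`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, sim = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config error: config must be a list or YAML path")
  bad <- setdiff(names(config),
                 c("seed", "protocol", "scene", "detection", "cell_id", "label"))
  if (length(bad)) stop("config error: unknown entries: ",
                        paste(bad, collapse = ", "))
  seed <- config$seed %||% 1L
  protocol <- do.call(build_protocol, config$protocol %||% list())
  params <- do.call(detection_params, config$detection %||% list())
  if (is.null(sim)) {
    scene_args <- config$scene %||% list()
    scene_args$rng_seed <- seed
    cfg <- do.call(scene_config, scene_args)
    sim <- simulate_scene(cfg, protocol)
  }
  movie <- sim$movie

  events <- detect_fusion_events(movie, protocol, params = params,
                                 soma_roi = sim$truth$soma_roi)
  # synapse map from the synapse-marker channel baseline
  synapses <- NULL
  if ("synapse" %in% names(movie$channels)) {
    base <- apply(movie$channels$synapse[, , 1:4, drop = FALSE], c(1, 2), mean)
    synapses <- detect_puncta(base)
  }
  tracks <- NULL
  if (identical(movie$reporter, "red")) {
    det <- lapply(seq_len(n_frames(movie)), function(t)
      detect_puncta(movie$channels$cargo[, , t]))
    tracks <- link_tracks(det, min_length = 5)
  }
  events <- annotate_events(events, synapses, tracks, protocol)

  summary <- cell_summary(events, protocol,
                          cell_id = config$cell_id %||% "cell1",
                          label = config$label %||% "")
  cumulative <- cumulative_curve(events, protocol)
  coloc <- NULL
  if (!is.null(synapses)) {
    cargo_base <- apply(movie$channels$cargo[, , 1:4, drop = FALSE],
                        c(1, 2), mean)
    syn_base <- apply(movie$channels$synapse[, , 1:4, drop = FALSE],
                      c(1, 2), mean)
    mc <- manders_coefficients(cargo_base, syn_base)
    coloc <- list(pearson = pearson_coefficient(cargo_base, syn_base),
                  m1 = mc$m1, m2 = mc$m2, tA = mc$tA, tB = mc$tB)
  }

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(events, file.path(out_dir, "events.csv"), row.names = FALSE)
    utils::write.csv(summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
    utils::write.csv(cumulative, file.path(out_dir, "cumulative.csv"),
                     row.names = FALSE)
    if (!is.null(coloc))
      jsonlite::write_json(coloc, file.path(out_dir, "coloc.json"),
                           auto_unbox = TRUE, digits = NA)
    yaml::write_yaml(list(seed = seed,
                          protocol = config$protocol %||% list(),
                          scene = config$scene %||% list(),
                          detection = unclass(params)),
                     file.path(out_dir, "log.yaml"))
  }
  structure(list(events = events, summary = summary, cumulative = cumulative,
                 coloc = coloc, tracks = tracks, protocol = protocol,
                 config = config),
            class = "dcv_report")
}
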