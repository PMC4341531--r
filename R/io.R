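#' Write a simulated scene to disk as a portable fixture
#'
#' One 16-bit multi-page TIFF per channel (counts clamped to
#' [0, 65535] and rounded), ground truth as JSON
#' (`{vesicles, events, synapses, soma_roi}`), the synapse table as CSV
#' (`id,y_px,x_px`), and the acquisition protocol as YAML. Reading the
#' fixture back reproduces the quantized movie bit-exactly.
#'
#' @param sim List with `movie` and `truth`, as returned by
#'   [simulate_scene()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of files written.
#' @export
write_fixture <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (file.access(dir, 2) != 0) stop("I/O error: directory not writable: ", dir)
  movie <- sim$movie; truth <- sim$truth
  files <- character(0)
  for (ch in names(movie$channels)) {
    arr <- movie$channels[[ch]]
    pages <- lapply(seq_len(dim(arr)[3]), function(t)
      pmin(pmax(round(arr[, , t]), 0), 65535) / 65535)
    f <- file.path(dir, paste0(ch, ".tif"))
    tiff::writeTIFF(pages, f, bits.per.sample = 16)
    files[ch] <- f
  }

  nv <- nrow(truth$vesicles)
  ves <- lapply(seq_len(nv), function(v) list(
    id = truth$vesicles$id[v],
    motility = truth$vesicles$motility[v],
    positions = unname(truth$positions[v, , , drop = TRUE])))
  ev <- truth$events
  gt <- list(
    vesicles = ves,
    events = lapply(seq_len(nrow(ev)), function(k) list(
      vesicle = ev$vesicle[k], onset_frame = ev$onset_frame[k],
      mode = ev$mode[k], y_px = ev$y_px[k], x_px = ev$x_px[k])),
    synapses = lapply(seq_len(nrow(truth$synapses)), function(k) list(
      id = truth$synapses$id[k], y_px = truth$synapses$y_px[k],
      x_px = truth$synapses$x_px[k])),
    soma_roi = unname(truth$soma_roi),
    neurites = lapply(truth$neurites, function(m)
      list(y_px = m[, 1], x_px = m[, 2])))
  fj <- file.path(dir, "truth.json")
  jsonlite::write_json(gt, fj, auto_unbox = TRUE, digits = NA)
  files["truth"] <- fj

  fc <- file.path(dir, "synapses.csv")
  utils::write.csv(truth$synapses, fc, row.names = FALSE)
  files["synapses"] <- fc

  p <- truth$protocol
  fp <- file.path(dir, "protocol.yaml")
  yaml::write_yaml(p[c("frame_interval_s", "pixel_size_um", "stim_start_s",
                       "n_bursts", "aps_per_burst", "burst_freq_hz",
                       "inter_burst_s", "movie_duration_s", "nh4_start_s",
                       "nh4_duration_s")], fp)
  files["protocol"] <- fp
  invisible(files)
}

#' Read a fixture written by [write_fixture()]
#'
#' @param dir Fixture directory.
#' @return List `movie` (integer counts), `truth` (vesicle table,
#'   positions array, events, synapses, soma_roi, neurite paths),
#'   `protocol`.
#' @export
read_fixture <- function(dir) {
  fp <- file.path(dir, "protocol.yaml")
  py <- yaml::read_yaml(fp)
  protocol <- do.call(build_protocol, py[!vapply(py, is.null, TRUE)])

  tifs <- list.files(dir, pattern = "\\.tif$", full.names = TRUE)
  channels <- list()
  for (f in tifs) {
    pages <- tiff::readTIFF(f, all = TRUE)
    arr <- array(0, c(dim(pages[[1]]), length(pages)))
    for (t in seq_along(pages)) arr[, , t] <- round(pages[[t]] * 65535)
    channels[[sub("\\.tif$", "", basename(f))]] <- arr
  }
  movie <- structure(list(channels = channels,
                          pixel_size_um = protocol$pixel_size_um,
                          frame_interval_s = protocol$frame_interval_s,
                          reporter = NA_character_), class = "dcv_movie")

  gt <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  nv <- if (is.data.frame(gt$vesicles)) nrow(gt$vesicles) else 0L
  Tn <- protocol$n_frames
  positions <- array(NA_real_, c(nv, Tn, 2))
  vesicles <- data.frame(id = integer(0), motility = character(0))
  if (nv > 0) {
    vesicles <- data.frame(id = gt$vesicles$id, motility = gt$vesicles$motility)
    for (v in seq_len(nv)) positions[v, , ] <- gt$vesicles$positions[[v]]
  }
  events <- if (is.data.frame(gt$events)) as.data.frame(gt$events)
  else data.frame(vesicle = integer(0), onset_frame = integer(0),
                  mode = character(0), y_px = numeric(0), x_px = numeric(0))
  synapses <- if (is.data.frame(gt$synapses)) as.data.frame(gt$synapses)
  else data.frame(id = integer(0), y_px = numeric(0), x_px = numeric(0))
  nr <- gt$neurites
  neurites <- if (is.data.frame(nr)) {
    # simplifyVector may collapse equal-length paths into matrix columns
    if (is.matrix(nr$y_px))
      lapply(seq_len(nrow(nr$y_px)), function(i) cbind(nr$y_px[i, ], nr$x_px[i, ]))
    else
      lapply(seq_len(nrow(nr)), function(i)
        cbind(unlist(nr$y_px[i]), unlist(nr$x_px[i])))
  } else {
    lapply(nr, function(n) cbind(unlist(n$y_px), unlist(n$x_px)))
  }
  truth <- list(vesicles = vesicles, positions = positions, events = events,
                synapses = synapses, soma_roi = unlist(gt$soma_roi),
                neurites = neurites, protocol = protocol)
  list(movie = movie, truth = truth, protocol = protocol)
}
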