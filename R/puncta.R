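#' Detect diffraction-limited puncta in a single frame
#'
#' Band-pass filters the frame with a difference of Gaussians
#' (`sigma_px` and `2 * sigma_px`), finds local maxima above
#' `mean + k * SD` of the filtered image with a minimum separation of
#' `min_sep` pixels, and refines each to sub-pixel precision by an
#' intensity-weighted centroid over a 3x3 window of the filtered image.
#'
#' @param frame Numeric matrix (one channel, one frame).
#' @param sigma_px PSF-scale Gaussian sigma for the band-pass (default 1.3).
#' @param k Threshold multiplier above the filtered-image mean (default 4).
#' @param min_sep Minimum separation between maxima in px (default 2).
#' @return data.frame `y_px`, `x_px` (0-based, sub-pixel), `intensity`
#'   (filtered-image value at the maximum); zero rows on a blank frame.
#' @export
detect_puncta <- function(frame, sigma_px = 1.3, k = 4, min_sep = 2) {
  empty <- data.frame(y_px = numeric(0), x_px = numeric(0),
                      intensity = numeric(0))
  if (all(frame == frame[1])) return(empty)
  g1 <- EBImage::gblur(frame, sigma = sigma_px)
  g2 <- EBImage::gblur(frame, sigma = 2 * sigma_px)
  dog <- g1 - g2
  thr <- mean(dog) + k * stats::sd(dog)
  ny <- nrow(dog); nx <- ncol(dog)
  cand <- which(dog > thr, arr.ind = TRUE)
  if (!nrow(cand)) return(empty)
  r <- max(1L, as.integer(min_sep))
  is_max <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    y <- cand[i, 1]; x <- cand[i, 2]
    win <- dog[max(1, y - r):min(ny, y + r), max(1, x - r):min(nx, x + r)]
    is_max[i] <- dog[y, x] >= max(win)
  }
  cand <- cand[is_max, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  # ties on plateaus: keep first in row-major order, drop near-duplicates
  if (nrow(cand) > 1) {
    keep <- rep(TRUE, nrow(cand))
    for (i in 2:nrow(cand)) {
      d <- sqrt((cand[seq_len(i - 1), 1] - cand[i, 1])^2 +
                (cand[seq_len(i - 1), 2] - cand[i, 2])^2)
      if (any(keep[seq_len(i - 1)] & d <= r)) keep[i] <- FALSE
    }
    cand <- cand[keep, , drop = FALSE]
  }
  out <- matrix(0, nrow(cand), 3)
  for (i in seq_len(nrow(cand))) {
    y <- cand[i, 1]; x <- cand[i, 2]
    ys <- max(1, y - 1):min(ny, y + 1)
    xs <- max(1, x - 1):min(nx, x + 1)
    w <- pmax(dog[ys, xs, drop = FALSE], 0)
    if (sum(w) == 0) w[] <- 1
    cy <- sum(outer(ys, rep(1, length(xs))) * w) / sum(w)
    cx <- sum(outer(rep(1, length(ys)), xs) * w) / sum(w)
    out[i, ] <- c(cy - 1, cx - 1, dog[y, x])   # back to 0-based
  }
  data.frame(y_px = out[, 1], x_px = out[, 2], intensity = out[, 3])
}

#' Count the labeled vesicle pool from the NH4+ de-quench epoch
#'
#' NH4+ neutralizes every vesicle lumen, so all cargo-pHluorin puncta
#' become fluorescent. Puncta are detected on the median projection of the
#' first `proj_frames` frames of the NH4+ epoch — a short window so that
#' mobile vesicles (~0.5 px/frame at typical transport speeds) are not
#' blurred out of the projection, while the median still rejects shot
#' noise. Each punctum's brightness is the background-subtracted mean
#' over its 2x2 ROI.
#'
#' @param movie A `dcv_movie`.
#' @param protocol A `dcv_protocol` defining the NH4+ epoch.
#' @param channel Cargo channel (default `"cargo"`).
#' @param sigma_px,k Punctum-detection settings passed to
#'   [detect_puncta()].
#' @param proj_frames Number of leading NH4+ frames in the projection
#'   (default 3).
#' @return List: `count`, `intensities` (per punctum), `puncta`
#'   (positions), `background` (projection median).
#' @export
count_pool_nh4 <- function(movie, protocol, channel = "cargo",
                           sigma_px = 1.3, k = 4, proj_frames = 3) {
  frames <- nh4_frames(protocol)   # errors when no NH4+ epoch
  frames <- frames[seq_len(min(proj_frames, length(frames)))]
  arr <- movie$channels[[channel]]
  proj <- apply(arr[, , frames, drop = FALSE], c(1, 2), stats::median)
  pts <- detect_puncta(proj, sigma_px = sigma_px, k = k)
  bg <- stats::median(proj)
  ints <- numeric(nrow(pts))
  ny <- nrow(proj); nx <- ncol(proj)
  for (i in seq_len(nrow(pts))) {
    tl <- roi_topleft(c(pts$y_px[i], pts$x_px[i]), 2)
    tl <- pmin(pmax(tl, 0), c(ny - 2, nx - 2))
    ints[i] <- mean(proj[tl[1] + 1:2, tl[2] + 1:2]) - bg
  }
  list(count = nrow(pts), intensities = ints, puncta = pts, background = bg)
}
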