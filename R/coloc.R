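#' Pearson correlation of two channels
#'
#' Cell-wide correlation of pixel intensities over an optional mask.
#'
#' @param imgA,imgB Numeric matrices of equal shape.
#' @param mask Optional logical matrix selecting pixels (default all).
#' @return Correlation coefficient in [-1, 1]; `NA` with a warning when
#'   either channel has zero variance over the mask.
#' @export
pearson_coefficient <- function(imgA, imgB, mask = NULL) {
  if (!all(dim(imgA) == dim(imgB))) stop("images must have equal shape")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(imgA), ncol(imgA))
  if (!any(mask)) stop("empty mask")
  a <- imgA[mask]; b <- imgB[mask]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("undefined correlation: zero variance in a channel")
    return(NA_real_)
  }
  stats::cor(a, b)
}

#' Manders co-occurrence coefficients
#'
#' `m1` is the fraction of channel-A intensity residing in B-positive
#' pixels (`B > tB`); `m2` is the converse. Default thresholds are
#' `mean + 2 SD` per channel over the mask; the thresholds used are
#' returned for reproducibility.
#'
#' @param imgA,imgB Numeric matrices of equal shape.
#' @param tA,tB Intensity thresholds (`NULL` = mean + 2 SD over mask).
#' @param mask Optional logical matrix.
#' @return List `m1`, `m2`, `tA`, `tB`; coefficients are `NA` with a
#'   warning when a channel has zero total intensity.
#' @export
manders_coefficients <- function(imgA, imgB, tA = NULL, tB = NULL,
                                 mask = NULL) {
  if (!all(dim(imgA) == dim(imgB))) stop("images must have equal shape")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(imgA), ncol(imgA))
  a <- imgA[mask]; b <- imgB[mask]
  if (is.null(tA)) tA <- mean(a) + 2 * stats::sd(a)
  if (is.null(tB)) tB <- mean(b) + 2 * stats::sd(b)
  if (tA < 0 || tB < 0) stop("thresholds must be >= 0")
  sA <- sum(a); sB <- sum(b)
  m1 <- if (sA == 0) { warning("undefined m1: zero total A intensity"); NA_real_ }
  else sum(a[b > tB]) / sA
  m2 <- if (sB == 0) { warning("undefined m2: zero total B intensity"); NA_real_ }
  else sum(b[a > tA]) / sB
  list(m1 = m1, m2 = m2, tA = tA, tB = tB)
}

#' Object-based colocalization of two punctum sets
#'
#' Fraction of A puncta with a B punctum within `radius_nm`
#' (nearest-neighbour matching). Directional: A-to-B, as percentages of
#' colocalizing puncta are usually reported per reference channel.
#'
#' @param punctaA,punctaB data.frames with `y_px`, `x_px`.
#' @param radius_nm Matching radius in nm.
#' @param pixel_size_um Pixel size (default 0.2).
#' @return Fraction in [0, 1]; `NA` with a warning for empty A; 0 for
#'   empty B.
#' @export
object_colocalization <- function(punctaA, punctaB, radius_nm,
                                  pixel_size_um = 0.2) {
  if (is.null(punctaA) || nrow(punctaA) == 0) {
    warning("undefined fraction: no reference puncta")
    return(NA_real_)
  }
  if (is.null(punctaB) || nrow(punctaB) == 0) return(0)
  dm <- cross_dist(cbind(punctaA$y_px, punctaA$x_px),
                   cbind(punctaB$y_px, punctaB$x_px))
  nn_nm <- apply(dm, 1, min) * pixel_size_um * 1000
  mean(nn_nm <= radius_nm + 1e-9)
}
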