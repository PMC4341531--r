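# Shared geometry helpers. All user-facing coordinates are 0-based
# continuous (y, x) pixel positions at pixel centers; R arrays are indexed
# internally as [y + 1, x + 1].

#' Cumulative arclength of a polyline
#' @param path Numeric matrix with columns `y`, `x` (0-based px).
#' @return Numeric vector, cumulative length in px from the first vertex.
#' @keywords internal
path_arclength <- function(path) {
  d <- sqrt(diff(path[, 1])^2 + diff(path[, 2])^2)
  c(0, cumsum(d))
}

#' Point on a polyline at a given arclength
#' @param path Polyline matrix (y, x).
#' @param s Arclength in px (clamped to the path span).
#' @return `c(y, x)`; with vector `s`, a matrix.
#' @keywords internal
path_point <- function(path, s) {
  cl <- path_arclength(path)
  s <- pmin(pmax(s, 0), cl[length(cl)])
  yi <- stats::approx(cl, path[, 1], xout = s, ties = "ordered")$y
  xi <- stats::approx(cl, path[, 2], xout = s, ties = "ordered")$y
  if (length(s) == 1L) c(yi, xi) else cbind(y = yi, x = xi)
}

#' Resample a polyline at unit arclength steps
#' @param path Polyline matrix (y, x).
#' @param step Sample spacing in px (default 1).
#' @return List with `points` (n x 2 matrix), `s` (arclengths), and
#'   `normals` (unit normal per sample).
#' @keywords internal
path_samples <- function(path, step = 1) {
  cl <- path_arclength(path)
  total <- cl[length(cl)]
  s <- seq(0, total, by = step)
  pts <- path_point(path, s)
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  # tangent by central differences, normal = rotate 90 degrees
  n <- nrow(pts)
  ty <- pts[pmin(seq_len(n) + 1, n), 1] - pts[pmax(seq_len(n) - 1, 1), 1]
  tx <- pts[pmin(seq_len(n) + 1, n), 2] - pts[pmax(seq_len(n) - 1, 1), 2]
  len <- sqrt(ty^2 + tx^2)
  len[len == 0] <- 1
  normals <- cbind(y = -tx / len, x = ty / len)
  list(points = pts, s = s, normals = normals)
}

#' Bilinear interpolation of an image at continuous positions
#' @param img Numeric matrix (Y x X).
#' @param y,x 0-based continuous coordinates (vectors).
#' @return Interpolated intensities; positions outside the image give `NA`.
#' @keywords internal
interp_bilinear <- function(img, y, x) {
  ny <- nrow(img); nx <- ncol(img)
  y0 <- floor(y); x0 <- floor(x)
  fy <- y - y0; fx <- x - x0
  y0 <- pmin(pmax(y0, 0), ny - 2)
  x0 <- pmin(pmax(x0, 0), nx - 2)
  fy <- pmin(pmax(y - y0, 0), 1)
  fx <- pmin(pmax(x - x0, 0), 1)
  out <- (1 - fy) * (1 - fx) * img[cbind(y0 + 1, x0 + 1)] +
    (1 - fy) * fx * img[cbind(y0 + 1, x0 + 2)] +
    fy * (1 - fx) * img[cbind(y0 + 2, x0 + 1)] +
    fy * fx * img[cbind(y0 + 2, x0 + 2)]
  out[y < 0 | y > ny - 1 | x < 0 | x > nx - 1] <- NA_real_
  out
}

#' Pairwise Euclidean distances between two point sets
#' @param a,b Matrices with columns (y, x).
#' @return `nrow(a)` x `nrow(b)` distance matrix.
#' @keywords internal
cross_dist <- function(a, b) {
  a <- matrix(as.numeric(a), ncol = 2)
  b <- matrix(as.numeric(b), ncol = 2)
  dy <- outer(a[, 1], b[, 1], "-")
  dx <- outer(a[, 2], b[, 2], "-")
  sqrt(dy^2 + dx^2)
}

# Run code with a private RNG stream seeded by `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
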