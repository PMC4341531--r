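test_that("Pearson correlation hits its closed-form identities", {
  set.seed(51)
  a <- matrix(rnorm(400, 100, 10), 20, 20)
  expect_equal(pearson_coefficient(a, 2 * a + 5), 1)
  expect_equal(pearson_coefficient(a, -a), -1)
  b <- matrix(rnorm(400, 100, 10), 20, 20)
  r <- pearson_coefficient(a, b)
  expect_lt(abs(r), 0.2)                         # independent channels
  expect_warning(r0 <- pearson_coefficient(a, matrix(3, 20, 20)), "variance")
  expect_true(is.na(r0))
  expect_error(pearson_coefficient(a, b[1:10, 1:10]), "shape")
  expect_error(pearson_coefficient(a, b, mask = matrix(FALSE, 20, 20)), "mask")
  # masking restricts the computation to the selected pixels
  mask <- matrix(FALSE, 20, 20); mask[1:10, ] <- TRUE
  expect_equal(pearson_coefficient(a, b, mask), cor(a[mask], b[mask]))
})

test_that("Manders coefficients are exact on constructed overlaps", {
  A <- matrix(0, 10, 10); A[1:5, ] <- 4
  # full overlap: all A intensity inside B-positive pixels
  B1 <- matrix(0, 10, 10); B1[1:5, ] <- 9
  expect_equal(manders_coefficients(A, B1, tA = 1, tB = 1)$m1, 1,
               tolerance = 1e-9)
  # zero overlap
  B0 <- matrix(0, 10, 10); B0[6:10, ] <- 9
  expect_equal(manders_coefficients(A, B0, tA = 1, tB = 1)$m1, 0,
               tolerance = 1e-9)
  # half overlap: B covers half of A's intensity
  Bh <- matrix(0, 10, 10); Bh[1:5, 1:5] <- 9
  mc <- manders_coefficients(A, Bh, tA = 1, tB = 1)
  expect_equal(mc$m1, 0.5, tolerance = 1e-9)
  expect_equal(mc$m2, 1, tolerance = 1e-9)       # all B sits inside A
  expect_warning(mz <- manders_coefficients(matrix(0, 10, 10), B1,
                                            tA = 1, tB = 1)$m1, "zero total")
  expect_true(is.na(mz))
})

test_that("Manders m1 decreases monotonically in the partner threshold", {
  set.seed(52)
  A <- matrix(runif(900, 0, 100), 30, 30)
  B <- matrix(runif(900, 0, 100), 30, 30)
  m1s <- vapply(c(10, 30, 50, 70, 90), function(tb)
    manders_coefficients(A, B, tA = 50, tB = tb)$m1, 0)
  expect_true(all(diff(m1s) <= 0))
})

test_that("object colocalization is affine in neither channel but exact in geometry", {
  A <- data.frame(y_px = c(10, 20, 30), x_px = c(10, 10, 10))
  # partner at 200 nm (1 px), at 400 nm, and missing
  B <- data.frame(y_px = c(11, 22), x_px = c(10, 10))
  expect_equal(object_colocalization(A, B, radius_nm = 200), 1 / 3)
  expect_equal(object_colocalization(A, B, radius_nm = 400), 2 / 3)
  expect_equal(object_colocalization(A, B, radius_nm = 2500), 1)
  expect_equal(object_colocalization(
    A, data.frame(y_px = numeric(0), x_px = numeric(0)), 200), 0)
  expect_warning(na <- object_colocalization(
    data.frame(y_px = numeric(0), x_px = numeric(0)), B, 200), "reference")
  expect_true(is.na(na))
})

test_that("random puncta colocalize at the Poisson-geometry chance level", {
  set.seed(53)
  # B is a homogeneous Poisson process; P(nearest B within r) = 1 - exp(-lambda pi r^2)
  side <- 300                       # px; 0.2 um/px
  lambda <- 0.01                    # puncta per px^2
  r_px <- 2.5; r_nm <- r_px * 200
  nB <- rpois(1, lambda * side^2)
  B <- data.frame(y_px = runif(nB, 0, side), x_px = runif(nB, 0, side))
  nA <- 400
  # keep A away from the border so edge effects do not bias the null
  A <- data.frame(y_px = runif(nA, r_px + 1, side - r_px - 1),
                  x_px = runif(nA, r_px + 1, side - r_px - 1))
  frac <- object_colocalization(A, B, radius_nm = r_nm)
  p <- 1 - exp(-lambda * pi * r_px^2)
  se <- sqrt(p * (1 - p) / nA)
  expect_lt(abs(frac - p), 3 * se)
})
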