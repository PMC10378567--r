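test_that("LBP codes match the naive bitwise oracle", {
  cst <- matrix(100L, 6, 6)
  expect_true(all(lbp_code_image(cst) == 255L))  # neighbor >= center everywhere
  ctr0 <- matrix(255L, 3, 3); ctr0[2, 2] <- 0L
  expect_identical(as.integer(lbp_code_image(ctr0)), 255L)
  hi <- matrix(0L, 3, 3); hi[2, 2] <- 255L
  expect_identical(as.integer(lbp_code_image(hi)), 0L)
  set.seed(3)
  for (rep in 1:10) {
    m <- matrix(sample(0:255, 36, replace = TRUE), 6, 6)
    expect_identical(unclass(lbp_code_image(m))[, ], oracle_lbp(m))
  }
  expect_error(lbp_code_image(matrix(1L, 2, 2)), "smaller")
  # literal printed sign convention is the bit complement of the default
  m <- matrix(sample(0:255, 25, replace = TRUE), 5, 5)
  expect_identical(unclass(lbp_code_image(m, literal_sign = TRUE))[, ],
                   255L - unclass(lbp_code_image(m))[, ])
})

test_that("LBP histograms count codes and conserve the interior pixel count", {
  z <- lbp_code_image(matrix(0L, 12, 12))
  h <- lbp_histogram(z)
  expect_identical(length(h), 256L)
  expect_identical(h[256], 100L)  # all-255 codes for a constant image
  expect_identical(sum(h), 100L)
  set.seed(5)
  m <- matrix(sample(0:255, 100, replace = TRUE), 10, 10)
  expect_identical(sum(lbp_histogram(lbp_code_image(m))), 64L)
  codes <- structure(matrix(c(3L, 3L, 7L), 1, 3), p = 8L)
  h2 <- lbp_histogram(codes)
  expect_identical(h2[4], 2L); expect_identical(h2[8], 1L); expect_identical(sum(h2), 3L)
})

test_that("gradients follow the central-difference oracle", {
  ramp <- matrix(rep(0:9 * 10L, each = 10), 10, 10) # I = 10 * (col - 1)
  g <- hog_gradients(ramp)
  inner <- g$magnitude[3:8, 3:8]
  expect_true(all(inner == 20))
  expect_true(all(g$orientation[3:8, 3:8] == 0))
  cst <- hog_gradients(matrix(50L, 8, 8))
  expect_true(all(cst$magnitude == 0))
  set.seed(6)
  m <- matrix(sample(0:255, 25, replace = TRUE), 5, 5)
  o <- oracle_gradients(m)
  g2 <- hog_gradients(m)
  expect_equal(g2$magnitude, sqrt(o$gx^2 + o$gy^2))
  expect_equal(g2$orientation, (atan2(o$gy, o$gx) * 180 / pi) %% 180)
})

test_that("cell histograms split votes linearly and conserve magnitude", {
  # single nonzero pixel at 90 degrees: 90 is the center of bin 4 -> full vote
  mag <- matrix(0, 8, 8); mag[3, 3] <- 1
  ang <- matrix(90, 8, 8)
  h <- hog_cell_histograms(list(magnitude = mag, orientation = ang))
  expect_equal(h[1, 1, 5], 1)
  expect_equal(sum(h), 1)
  # 75 degrees sits between centers 70 (bin 3) and 90 (bin 4): 3/4 vs 1/4
  ang2 <- matrix(75, 8, 8)
  h2 <- hog_cell_histograms(list(magnitude = mag, orientation = ang2))
  expect_equal(h2[1, 1, 4], 0.75)
  expect_equal(h2[1, 1, 5], 0.25)
  # wrap-around below the first bin center
  ang3 <- matrix(5, 8, 8)
  h3 <- hog_cell_histograms(list(magnitude = mag, orientation = ang3))
  expect_equal(h3[1, 1, 1], 0.75)
  expect_equal(h3[1, 1, 9], 0.25)
  # conservation: total vote mass per cell = sum of cell magnitudes
  set.seed(7)
  fld <- list(magnitude = matrix(runif(256, 0, 10), 16, 16),
              orientation = matrix(runif(256, 0, 180), 16, 16))
  h4 <- hog_cell_histograms(fld)
  expect_equal(apply(h4, c(1, 2), sum),
               matrix(c(sum(fld$magnitude[1:8, 1:8]), sum(fld$magnitude[9:16, 1:8]),
                        sum(fld$magnitude[1:8, 9:16]), sum(fld$magnitude[9:16, 9:16])),
                      2, 2))
})

test_that("HOG blocks normalize to unit scale and have the documented length", {
  cells <- array(1, c(2, 2, 9))
  d <- hog_descriptor(cells)
  expect_length(d, 36L)
  expect_true(all(abs(d - d[1]) < 1e-12))
  expect_equal(sqrt(sum(d^2)), 1, tolerance = 1e-4)
  expect_true(all(d >= 0 & d <= 1))
  zero <- hog_descriptor(array(0, c(2, 2, 9)))
  expect_true(all(zero == 0))
  # 24x24 input, cell 8, stride 8 -> 2x2 block grid -> 4 * 36 values
  set.seed(8)
  img <- matrix(sample(0:255, 24 * 24, replace = TRUE), 24, 24)
  cells24 <- hog_cell_histograms(hog_gradients(img))
  expect_length(hog_descriptor(cells24), 4L * 36L)
})

test_that("texture vectors are reproducible with fixed layout", {
  set.seed(9)
  img <- matrix(sample(0:200, 64 * 64, replace = TRUE), 64, 64)
  v1 <- texture_vector(img)
  v2 <- texture_vector(img)
  expect_identical(v1, v2)
  # 128/8 = 16 cells -> 15x15 blocks of 36, plus 256 LBP frequencies
  expect_length(v1, 15L * 15L * 36L + 256L)
  expect_identical(sum(startsWith(names(v1), "lbp_")), 256L)
  expect_equal(sum(v1[startsWith(names(v1), "lbp_")]), 1)
  # constant intensity offset leaves gradients (hence HOG) unchanged
  v3 <- texture_vector(img + 20L)
  hog_ix <- startsWith(names(v1), "hog_")
  expect_equal(v1[hog_ix], v3[hog_ix], tolerance = 1e-10)
})

test_that("PCA reproduces the variance structure and reconstruction identity", {
  # exact line: first component captures all variance
  t1 <- seq(-2, 2, length.out = 40)
  line <- cbind(t1, 2 * t1)
  m1 <- pca_fit(line, 2L)
  expect_equal(m1$explained_variance[1] / m1$total_variance, 1)
  # isotropic Gaussian: near-equal explained variances
  set.seed(10)
  iso <- matrix(rnorm(4000), 1000, 4)
  m2 <- pca_fit(iso, 4L)
  expect_lt(max(m2$explained_variance) / min(m2$explained_variance), 1.35)
  # orthonormality and reconstruction
  x <- matrix(rnorm(300), 30, 10)
  m3 <- pca_fit(x, 10L)
  expect_equal(crossprod(m3$components), diag(10), tolerance = 1e-8)
  expect_true(all(diff(m3$explained_variance) <= 1e-10))
  rec <- pca_inverse(m3, pca_transform(m3, x))
  expect_equal(rec, x, tolerance = 1e-8)
  expect_equal(sum(m3$explained_variance), sum(apply(x, 2, var)),
               tolerance = 1e-8)
  # transform of the training mean is the zero row
  expect_equal(as.vector(pca_transform(m3, matrix(m3$mean, 1))),
               rep(0, 10), tolerance = 1e-10)
  expect_warning(pca_fit(x, 31L), "cap")  # capped at the rank, not an error
  expect_error(pca_transform(m3, matrix(0, 2, 4)), "match")
})

test_that("the default texture PCA width is 199 components", {
  set.seed(11)
  x <- matrix(rnorm(220 * 300), 220, 300)
  m <- pca_fit(x)
  red <- pca_transform(m, x)
  expect_identical(ncol(red), 199L)
})
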