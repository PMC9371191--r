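test_that("read_rgb decodes PNG and TIFF and rescales bit depth", {
  p8 <- tempfile(fileext = ".png")
  png::writePNG(array(1, c(2, 2, 3)), p8)
  img <- read_rgb(p8)
  expect_equal(dim(img), c(2, 2, 3))
  expect_true(all(img == 255))

  p16 <- tempfile(fileext = ".tiff")
  tiff::writeTIFF(matrix(c(1, 0.5, 0, 1), 2, 2), p16, bits.per.sample = 16)
  img16 <- read_rgb(p16)
  expect_equal(max(img16), 255)          # 16-bit max maps to 255
  expect_equal(img16[2, 1, 1], 0.5 * 255, tolerance = 1e-4)
  expect_equal(img16[, , 1], img16[, , 2])  # gray replicated across channels

  expect_error(read_rgb(tempfile(fileext = ".png")), "does not exist")
  bad <- tempfile(fileext = ".png")
  writeLines("not a png", bad)
  expect_error(read_rgb(bad))
})

test_that("read_rgb preserves phantom dimensions and red-channel contrast", {
  ph <- generate_phantom(phantom_spec(width = 120, height = 90, n_nuclei = 10,
                                      n_white_patches = 0, seed = 7))
  p <- tempfile(fileext = ".png")
  png::writePNG(ph$rgb / 255, p)
  img <- read_rgb(p)
  expect_equal(dim(img), c(90, 120, 3))
  red <- red_channel(img)
  nuc <- ph$nuclei_truth > 0
  # nuclei darker than stroma in the red channel
  expect_lt(mean(red[nuc]), mean(red[!nuc]) - 30)
})

test_that("red_channel returns the R plane unchanged", {
  arr <- array(0, c(2, 2, 3))
  arr[1, 1, ] <- c(200, 50, 50)
  expect_equal(red_channel(arr)[1, 1], 200)
  blue <- array(rep(c(0, 0, 255), each = 4), c(2, 2, 3))
  expect_true(all(red_channel(blue) == 0))
})

test_that("label_components respects connectivity", {
  empty <- matrix(FALSE, 5, 5)
  expect_true(all(label_components(empty) == 0))

  two <- matrix(0, 10, 10)
  two[1:3, 1:3] <- 1; two[6:8, 6:8] <- 1
  expect_equal(max(label_components(two)), 2)

  diag2 <- matrix(0, 4, 4)
  diag2[1, 1] <- 1; diag2[2, 2] <- 1
  expect_equal(max(label_components(diag2, connectivity = 8)), 1)
  expect_equal(max(label_components(diag2, connectivity = 4)), 2)
})

test_that("region_properties measures areas, centroids and intensities", {
  m <- matrix(0L, 20, 20)
  m[6:15, 3:12] <- 1L
  intens <- matrix(200, 20, 20)
  rp <- region_properties(m, intens)
  expect_equal(nrow(rp), 1)
  expect_equal(rp$area, 100)
  expect_equal(rp$centroid_row, mean(5:14))  # 0-based
  expect_equal(rp$centroid_col, mean(2:11))
  expect_equal(rp$mean_intensity, 200)
  expect_equal(rp$intensity_mode, 200)

  expect_equal(nrow(region_properties(matrix(0L, 3, 3), matrix(0, 3, 3))), 0)
})

test_that("moment ellipse matches an axis-aligned 2:1 ellipse", {
  ell <- draw_ellipse(20, 10, angle = 0)
  rp <- region_properties(label_components(ell), ell * 0)
  expect_lt(abs(rp$ellipse_angle), 2)
  expect_equal(rp$ellipse_major / rp$ellipse_minor, 2, tolerance = 0.05)
  # equivalent-moments axes approximate the true diameters
  expect_equal(rp$ellipse_major, 40, tolerance = 0.1)
})

test_that("ellipse orientation is rotation-equivariant", {
  ell <- draw_ellipse(20, 10, angle = pi / 6)  # 30 deg off-axis
  rp <- region_properties(label_components(ell), ell * 0)
  expect_equal(abs(rp$ellipse_angle), 30, tolerance = 2)
  rot <- t(ell)[ncol(ell):1, ]  # rotate raster by 90 degrees
  rp90 <- region_properties(label_components(rot), rot * 0)
  d <- abs(rp90$ellipse_angle - rp$ellipse_angle) %% 180
  expect_equal(min(d, 180 - d), 90, tolerance = 2)
})

test_that("region areas sum to foreground count and labels are order-invariant", {
  set.seed(42)
  m <- matrix(rbinom(900, 1, 0.2), 30, 30)
  labs <- label_components(m)
  rp <- region_properties(labs, matrix(runif(900, 0, 255), 30, 30))
  expect_equal(sum(rp$area), sum(m))

  # permute label ids: per-region rows identical up to relabeling
  perm <- sample(max(labs))
  labs2 <- labs
  labs2[labs > 0] <- perm[labs[labs > 0]]
  rp2 <- region_properties(labs2, matrix(0, 30, 30))
  # row for new label j describes old region match(j, perm) = order(perm)[j]
  expect_equal(rp2$area, rp$area[order(perm)])
  expect_equal(rp2$centroid_row, rp$centroid_row[order(perm)])
})

test_that("mask and label PNG round-trips preserve values", {
  m <- matrix(0L, 8, 8); m[2:4, 2:4] <- 1L
  p <- tempfile(fileext = ".png")
  write_mask_png(m, p)
  back <- png::readPNG(p)
  expect_equal(back * 1L, m + 0)

  labs <- matrix(0L, 8, 8); labs[1, 1:3] <- 300L  # forces 16-bit encoding
  p2 <- tempfile(fileext = ".png")
  write_labels_png(labs, p2)
  expect_equal(read_labels_png(p2), labs + 0)
})
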