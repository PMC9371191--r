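#' Read an RGB histopathology image
#'
#' Decodes a PNG, TIFF or JPEG file into an 8-bit RGB array. Gray images are
#' replicated across the three channels; 16-bit inputs are rescaled so that
#' the maximum representable value maps to 255.
#'
#' @param path Path to a PNG, TIFF or JPEG file.
#' @return A `height x width x 3` numeric array with values in `[0, 255]`.
#' @export
read_rgb <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read image: file does not exist: ", path)
  }
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    jpg  = ,
    jpeg = ebimage_rgb(path),
    stop("unsupported image format: .", ext, " (expected png/tiff/jpeg)")
  )
  # readPNG/readTIFF return [0,1] regardless of bit depth
  if (is.matrix(arr)) arr <- array(arr, c(dim(arr), 1L))
  h <- dim(arr)[1]; w <- dim(arr)[2]; k <- dim(arr)[3]
  out <- array(0, c(h, w, 3L))
  if (k >= 3L) {
    out[] <- arr[, , 1:3]
  } else {
    for (ch in 1:3) out[, , ch] <- arr[, , 1L]
  }
  out <- out * .GRAY_MAX
  storage.mode(out) <- "double"
  out
}

# decode via EBImage (jpeg); transposed to row=y, col=x orientation
ebimage_rgb <- function(path) {
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 2L) {
    arr <- array(t(dat), c(dim(dat)[2], dim(dat)[1], 1L))
  } else {
    arr <- aperm(dat[, , 1:min(3L, dim(dat)[3]), drop = FALSE], c(2L, 1L, 3L))
  }
  arr
}

#' Extract the red channel
#'
#' In H&E staining the red channel carries the strongest nucleus/tissue
#' contrast (nuclei are darker in R than the pinkish stroma), and all
#' downstream processing operates on it.
#'
#' @param img An RGB array as returned by [read_rgb()].
#' @return A numeric matrix (gray image) in `[0, 255]`.
#' @export
red_channel <- function(img) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] >= 1L)
  img[, , 1L]
}

#' Label connected components of a binary mask
#'
#' @param mask Logical or 0/1 matrix.
#' @param connectivity 8 (default) or 4.
#' @return An integer matrix of labels, `0` = background, labels contiguous
#'   `1..L` in raster-scan order.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  m <- matrix(as.logical(mask != 0), nrow(mask), ncol(mask))
  cpp_label_components(m, as.integer(connectivity))
}

#' Per-region geometry and intensity descriptors
#'
#' Computes, for every label of a label map, the descriptors used across the
#' pipeline: pixel area, centroid, inner-boundary perimeter, mean intensity,
#' 8-bit intensity mode (ties broken towards the smallest value), the
#' moments-equivalent ellipse (centre, full axis lengths, orientation), and
#' optionally the MOR circularity.
#'
#' Coordinates are 0-based `(row, col)`; the ellipse angle is measured in
#' degrees counter-clockwise from the image x-axis and normalized to
#' `[-90, 90)`.
#'
#' @param labels Integer label matrix (0 = background).
#' @param intensity Gray matrix of the same dimensions.
#' @param circularity If `TRUE` (default), fill the `circularity` column with
#'   [mor()] of each region; otherwise `NA`.
#' @return A tibble with one row per label.
#' @export
region_properties <- function(labels, intensity, circularity = TRUE) {
  stopifnot(all(dim(labels) == dim(intensity)))
  labs <- sort(unique(labels[labels > 0L]))
  if (length(labs) == 0L) {
    return(tibble(
      label = integer(), area = numeric(),
      centroid_row = numeric(), centroid_col = numeric(),
      perimeter = numeric(), mean_intensity = numeric(),
      intensity_mode = numeric(),
      ellipse_row = numeric(), ellipse_col = numeric(),
      ellipse_major = numeric(), ellipse_minor = numeric(),
      ellipse_angle = numeric(), circularity = numeric()
    ))
  }
  idx <- which(labels > 0L)
  lab_v <- labels[idx]
  row_v <- (idx - 1L) %% nrow(labels)      # 0-based
  col_v <- (idx - 1L) %/% nrow(labels)
  int_v <- intensity[idx]
  bnd <- cpp_inner_boundary(labels)
  per_tab <- tapply(bnd[idx], lab_v, sum)

  ord <- order(lab_v)
  lab_s <- lab_v[ord]; row_s <- row_v[ord]; col_s <- col_v[ord]; int_s <- int_v[ord]
  grp <- split(seq_along(lab_s), lab_s)

  rows <- purrr::map(labs, function(l) {
    ii <- grp[[as.character(l)]]
    r <- row_s[ii]; cc <- col_s[ii]; v <- int_s[ii]
    a <- length(ii)
    cr <- mean(r); ccol <- mean(cc)
    ell <- moments_ellipse(r, cc)
    tab <- tabulate(as.integer(round(v)) + 1L, nbins = 256L)
    mode_v <- which.max(tab) - 1L  # which.max returns first (smallest) max
    circ <- NA_real_
    tibble(
      label = l, area = a, centroid_row = cr, centroid_col = ccol,
      perimeter = as.numeric(per_tab[[as.character(l)]]),
      mean_intensity = mean(v), intensity_mode = as.numeric(mode_v),
      ellipse_row = cr, ellipse_col = ccol,
      ellipse_major = ell$major, ellipse_minor = ell$minor,
      ellipse_angle = ell$angle, circularity = circ
    )
  })
  out <- dplyr::bind_rows(rows)
  if (circularity) {
    out$circularity <- purrr::map_dbl(labs, function(l) {
      suppressWarnings(mor(crop_to_region(labels == l)))
    })
  }
  out
}

# crop a logical mask to its bounding box plus a 1-px background border
crop_to_region <- function(mask) {
  idx <- which(mask)
  r <- range((idx - 1L) %% nrow(mask))
  cc <- range((idx - 1L) %/% nrow(mask))
  r0 <- max(r[1] + 1L - 1L, 1L); r1 <- min(r[2] + 1L + 1L, nrow(mask))
  c0 <- max(cc[1] + 1L - 1L, 1L); c1 <- min(cc[2] + 1L + 1L, ncol(mask))
  mask[r0:r1, c0:c1, drop = FALSE]
}

# Ellipse with the same second-order central moments as the pixel set.
# Axes are full lengths (4*sqrt(eigenvalue)); angle in degrees CCW from the
# x-axis (columns), y pointing down in raster coordinates, hence the sign
# flip on the cross moment; normalized to [-90, 90).
moments_ellipse <- function(rows, cols) {
  n <- length(rows)
  x <- cols - mean(cols)
  y <- rows - mean(rows)
  # 1/12 term: each pixel is a unit square, not a point
  mxx <- sum(x * x) / n + 1 / 12
  myy <- sum(y * y) / n + 1 / 12
  mxy <- sum(x * y) / n
  common <- sqrt((mxx - myy)^2 + 4 * mxy^2)
  e1 <- (mxx + myy + common) / 2
  e2 <- (mxx + myy - common) / 2
  ang <- 0.5 * atan2(-2 * mxy, mxx - myy) * 180 / pi
  if (ang < -90) ang <- ang + 180
  if (ang >= 90) ang <- ang - 180
  list(major = 4 * sqrt(max(e1, 0)), minor = 4 * sqrt(max(e2, 0)), angle = ang)
}

#' Write a binary mask as an 8-bit PNG (0/255)
#'
#' @param mask Logical or 0/1 matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Write a label map as a PNG
#'
#' Label maps with up to 255 labels are written as 8-bit gray PNGs. Larger
#' maps use a lossless 16-bit two-channel encoding: the red channel holds
#' the high byte and the green channel the low byte, so
#' `label = R * 256 + G`.
#'
#' @param labels Integer label matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_labels_png <- function(labels, path) {
  if (max(labels, 1L) > 255) {
    arr <- array(0, c(nrow(labels), ncol(labels), 3L))
    arr[, , 1] <- (labels %/% 256L) / 255
    arr[, , 2] <- (labels %% 256L) / 255
    png::writePNG(arr, path)
  } else {
    png::writePNG(labels / 255, path)
  }
  invisible(path)
}

#' Read a label map written by [write_labels_png()]
#' @param path PNG file path.
#' @return Integer label matrix.
#' @export
read_labels_png <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) {
    round(arr[, , 1] * 255) * 256L + round(arr[, , 2] * 255)
  } else {
    round(arr * 255)
  }
}
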