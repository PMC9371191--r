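#' Disk structuring element offsets
#'
#' The disk of scale `lambda` is the set of integer offsets within Euclidean
#' distance `lambda` of the origin, i.e. a symmetric (2*lambda+1)^2-bounded
#' footprint that contains its centre.
#'
#' @param lambda Disk radius in pixels (>= 0).
#' @return A list with integer vectors `dr`, `dc` and the footprint size `n`.
#' @export
disk_offsets <- function(lambda) {
  stopifnot(lambda >= 0)
  r <- as.integer(floor(lambda))
  g <- expand.grid(dr = -r:r, dc = -r:r)
  keep <- g$dr^2 + g$dc^2 <= lambda^2
  list(dr = as.integer(g$dr[keep]), dc = as.integer(g$dc[keep]), n = sum(keep))
}

#' Pixel area of a rasterized disk
#' @param lambda Disk radius in pixels.
#' @return Number of pixels in the disk footprint.
#' @export
disk_area <- function(lambda) disk_offsets(lambda)$n

#' Grayscale erosion and dilation by a disk
#'
#' Erosion is the windowed minimum over the disk support (image border padded
#' with the maximum gray value); dilation is the windowed maximum (border
#' padded with 0).
#'
#' @param img Numeric gray matrix in `[0, 255]` (binary masks may be passed
#'   as 0/1 matrices).
#' @param lambda Disk radius in pixels.
#' @return A matrix of the same dimensions.
#' @export
erode <- function(img, lambda) {
  se <- disk_offsets(lambda)
  cpp_min_filter(as_gray_matrix(img), se$dr, se$dc, pad = max(img))
}

#' @rdname erode
#' @export
dilate <- function(img, lambda) {
  se <- disk_offsets(lambda)
  cpp_max_filter(as_gray_matrix(img), se$dr, se$dc, pad = 0)
}

#' Morphological opening and closing by a disk
#'
#' Opening is dilation after erosion (removes structures narrower than the
#' disk); closing is erosion after dilation.
#'
#' @inheritParams erode
#' @return A matrix of the same dimensions.
#' @export
opening <- function(img, lambda) dilate(erode(img, lambda), lambda)

#' @rdname opening
#' @export
closing <- function(img, lambda) erode(dilate(img, lambda), lambda)

as_gray_matrix <- function(img) {
  stopifnot(is.matrix(img))
  storage.mode(img) <- "double"
  img
}
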