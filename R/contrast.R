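#' Tile an image at a nucleus-scale-derived size
#'
#' Partitions the image into non-overlapping square tiles of side
#' `25 * lambda_n` (ragged border tiles keep their natural smaller size) and
#' records per-tile statistics for local contrast stretching: mean `mu`,
#' standard deviation `sigma`, stretch bounds `low_in = max(mu - 2*sigma, 0)`
#' and `high_in = mu`. Tiles with `sigma < 1` are flagged degenerate
#' (near-flat regions would only amplify noise).
#'
#' @param img Gray matrix.
#' @param lambda_n Nucleus scale in pixels (>= 1).
#' @param tile_factor Tile side as a multiple of `lambda_n` (default 25).
#' @return A tibble with one row per tile: 1-based inclusive ranges
#'   `row0,row1,col0,col1`, statistics and the `degenerate` flag.
#' @export
make_tiles <- function(img, lambda_n, tile_factor = 25) {
  stopifnot(lambda_n >= 1)
  side <- max(1L, as.integer(round(tile_factor * lambda_n)))
  h <- nrow(img); w <- ncol(img)
  rstarts <- seq(1L, h, by = side)
  cstarts <- seq(1L, w, by = side)
  grid <- tidyr::expand_grid(row0 = rstarts, col0 = cstarts)
  out <- purrr::pmap(grid, function(row0, col0) {
    row1 <- min(row0 + side - 1L, h)
    col1 <- min(col0 + side - 1L, w)
    px <- img[row0:row1, col0:col1]
    mu <- mean(px); sg <- sd_pop(px)
    tibble(
      row0 = row0, row1 = row1, col0 = col0, col1 = col1,
      mu = mu, sigma = sg,
      low_in = max(mu - 2 * sg, 0), high_in = mu,
      degenerate = sg < 1 | mu - 2 * sg >= mu  # sigma ~ 0
    )
  })
  dplyr::bind_rows(out)
}

# population standard deviation (tiles are the full population of their pixels)
sd_pop <- function(x) {
  n <- length(x)
  if (n < 2) return(0)
  sqrt(sum((x - mean(x))^2) / n)
}

#' Local linear contrast stretch
#'
#' Linearly maps `[low_in, high_in]` onto `[0, 255]`; values below `low_in`
#' clamp to 0 and above `high_in` to 255. Output is rounded half-up to the
#' nearest integer for determinism across platforms.
#'
#' @param px Numeric vector or matrix of gray values.
#' @param low_in,high_in Stretch bounds with `low_in < high_in`.
#' @return Stretched values, same shape as `px`.
#' @export
local_stretch <- function(px, low_in, high_in) {
  stopifnot(high_in > low_in)
  y <- (px - low_in) / (high_in - low_in) * .GRAY_MAX
  y[y < 0] <- 0
  y[y > .GRAY_MAX] <- .GRAY_MAX
  out <- floor(y + 0.5)  # round half-up
  out
}

#' Tile-local nuclei binarization
#'
#' For each tile of [make_tiles()]: apply the local contrast stretch, then
#' threshold the stretched tile with Otsu's method. Nuclei are dark in the
#' red channel, so the foreground is the class at or below the threshold.
#' Degenerate (near-flat) tiles contribute no foreground.
#'
#' @param img Red-channel gray matrix.
#' @param lambda_n Nucleus scale in pixels.
#' @param tile_factor Tile side multiplier (default 25).
#' @return A logical matrix: `TRUE` on nucleus-candidate pixels.
#' @export
binarize_nuclei <- function(img, lambda_n, tile_factor = 25) {
  tiles <- make_tiles(img, lambda_n, tile_factor)
  mask <- matrix(FALSE, nrow(img), ncol(img))
  for (i in seq_len(nrow(tiles))) {
    t <- tiles[i, ]
    if (t$degenerate) next
    px <- img[t$row0:t$row1, t$col0:t$col1]
    st <- local_stretch(px, t$low_in, t$high_in)
    thr <- otsu_threshold(st)
    mask[t$row0:t$row1, t$col0:t$col1] <- st <= thr
  }
  mask
}

# Otsu threshold on an 8-bit tile, returned on the [0,255] scale.
otsu_threshold <- function(px) {
  img <- EBImage::Image(px / .GRAY_MAX)
  as.numeric(EBImage::otsu(img, range = c(0, 1), levels = 256L)) * .GRAY_MAX
}
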