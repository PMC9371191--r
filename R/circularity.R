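#' Boundary radius profile of a region
#'
#' Collects the Euclidean distances from the region's area centroid to every
#' pixel of its inner 8-connected boundary and bins them into a unit-width
#' histogram over `[0, ceil(max r)]`, normalized to unit mass. Regions with
#' fewer than 8 boundary pixels are flagged degenerate.
#'
#' @param region_mask Logical or 0/1 matrix containing a single region.
#' @return An object of class `radius_profile`: list with `center`
#'   (0-based row/col), `radii`, `breaks`, `density` (sums to 1),
#'   `mode_bin`, `degenerate`.
#' @export
radius_profile <- function(region_mask) {
  m <- matrix(as.integer(region_mask != 0), nrow(region_mask), ncol(region_mask))
  idx <- which(m == 1L)
  if (length(idx) == 0L) stop("empty region")
  rows <- (idx - 1L) %% nrow(m)
  cols <- (idx - 1L) %/% nrow(m)
  ctr <- c(row = mean(rows), col = mean(cols))
  bnd <- cpp_inner_boundary(m)
  bidx <- which(bnd)
  brow <- (bidx - 1L) %% nrow(m)
  bcol <- (bidx - 1L) %/% nrow(m)
  radii <- sqrt((brow - ctr[["row"]])^2 + (bcol - ctr[["col"]])^2)
  degenerate <- length(radii) < 8L
  nb <- max(1L, ceiling(max(radii, 1e-9)))
  bin <- pmin(floor(radii), nb - 1L)  # bin b covers [b, b+1)
  dens <- tabulate(bin + 1L, nbins = nb)
  dens <- dens / sum(dens)
  structure(
    list(center = ctr, radii = radii, breaks = 0:nb, density = dens,
         mode_bin = which.max(dens) - 1L, degenerate = degenerate),
    class = "radius_profile"
  )
}

#' MOR circularity of a binary region
#'
#' The MOR metric is the probability mass of the boundary-radius distribution
#' between the local minima flanking its mode: a circle concentrates all
#' boundary radii in one or two bins (MOR near 1), while elongated or
#' irregular shapes spread them out (MOR well below 1). Minima are
#' *non-strict* (a bin no larger than both neighbours), the nearest such bin
#' on each side of the mode is used, and the support ends serve as fallback;
#' mode ties break towards the smallest radius.
#'
#' @param region_mask Logical or 0/1 matrix containing a single region.
#' @return MOR value in `[0, 1]`; degenerate regions (fewer than 8 boundary
#'   pixels) return 0 with a warning.
#' @export
mor <- function(region_mask) {
  rp <- radius_profile(region_mask)
  if (rp$degenerate) {
    warning("degenerate region (< 8 boundary pixels); MOR set to 0")
    return(0)
  }
  f <- rp$density
  n <- length(f)
  mode <- rp$mode_bin + 1L  # 1-based index
  k1 <- mode; k2 <- mode
  if (mode > 1L) {
    found <- FALSE
    for (i in seq(mode - 1L, 1L)) {
      lo <- if (i > 1L) f[i - 1L] else Inf
      if (f[i] <= lo && f[i] <= f[i + 1L]) { k1 <- i; found <- TRUE; break }
    }
    if (!found) k1 <- 1L
  }
  if (mode < n) {
    found <- FALSE
    for (i in seq(mode + 1L, n)) {
      hi <- if (i < n) f[i + 1L] else Inf
      if (f[i] <= hi && f[i] <= f[i - 1L]) { k2 <- i; found <- TRUE; break }
    }
    if (!found) k2 <- n
  }
  sum(f[k1:k2])
}
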