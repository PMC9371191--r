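#' Characteristic scale of a connected component
#'
#' The scale of a component is the radius of its largest inscribed disk,
#' i.e. the maximum of the Euclidean distance transform inside the component,
#' rounded to the nearest integer.
#'
#' @param component_mask Logical or 0/1 matrix containing the component.
#' @return Integer scale in pixels.
#' @export
component_scale <- function(component_mask) {
  m <- matrix(as.integer(component_mask != 0), nrow(component_mask),
              ncol(component_mask))
  if (!any(m == 1L)) stop("empty component")
  d <- EBImage::distmap(m, metric = "euclidean")
  as.integer(round(max(d)))
}

#' Partition binary foreground by size relative to the nucleus scale
#'
#' Components are routed to three classes: `small` (area below the disk area
#' at `lambda_n / 2`; noise and artifacts), `clump` (inscribed-disk scale
#' above `lambda_n`, or area above twice the disk area at `lambda_n`, which
#' catches fused same-radius nuclei), and `medium` (single-nucleus
#' candidates) otherwise.
#'
#' @param mask Logical matrix of nucleus-candidate pixels.
#' @param lambda_n Nucleus scale in pixels.
#' @return A list with integer label maps `small`, `medium`, `clumps`
#'   (disjoint, union = input foreground) and a per-component tibble `sizes`.
#' @export
partition_by_size <- function(mask, lambda_n) {
  stopifnot(lambda_n >= 1)
  labels <- label_components(mask, connectivity = 8)
  n <- max(labels)
  small <- matrix(0L, nrow(mask), ncol(mask))
  medium <- matrix(0L, nrow(mask), ncol(mask))
  clumps <- matrix(0L, nrow(mask), ncol(mask))
  if (n == 0L) {
    return(list(small = small, medium = medium, clumps = clumps,
                sizes = tibble(label = integer(), area = numeric(),
                               scale = integer(), class = character())))
  }
  area_small <- disk_area(lambda_n / 2)
  area_clump <- 2 * disk_area(lambda_n)
  d <- EBImage::distmap(matrix(as.integer(labels > 0L), nrow(mask), ncol(mask)),
                        metric = "euclidean")
  areas <- tabulate(labels[labels > 0L], nbins = n)
  scales <- as.integer(round(tapply(d[labels > 0L], labels[labels > 0L], max)))
  cls <- dplyr::case_when(
    areas < area_small ~ "small",
    scales > lambda_n | areas > area_clump ~ "clump",
    TRUE ~ "medium"
  )
  for (l in seq_len(n)) {
    tgt <- switch(cls[l], small = "small", medium = "medium", clump = "clump")
    sel <- labels == l
    if (tgt == "small") small[sel] <- l
    else if (tgt == "medium") medium[sel] <- l
    else clumps[sel] <- l
  }
  list(small = small, medium = medium, clumps = clumps,
       sizes = tibble(label = seq_len(n), area = as.numeric(areas),
                      scale = scales, class = cls))
}

#' Split clumped nuclei with a distance-transform watershed
#'
#' Marker-controlled watershed of each clump on its (negated) Euclidean
#' distance transform: regional maxima of the distance map deeper than
#' `h = lambda_n / 2` seed the basins, so shallow rasterization bumps do not
#' oversplit while genuinely fused nuclei separate at their necks.
#'
#' @param clumps Integer label map (or logical mask) of clump pixels.
#' @param lambda_n Nucleus scale in pixels; sets the suppression depth.
#' @return A list with `labels` (integer basin label map, contiguous 1..B)
#'   and `basins` (tibble of basin count per input clump).
#' @export
split_clumps <- function(clumps, lambda_n) {
  mask <- matrix(as.integer(clumps != 0), nrow(clumps), ncol(clumps))
  if (!any(mask == 1L)) {
    return(list(labels = matrix(0L, nrow(clumps), ncol(clumps)),
                basins = tibble(clump = integer(), n_basins = integer())))
  }
  d <- EBImage::distmap(mask, metric = "euclidean")
  ws <- EBImage::watershed(d, tolerance = lambda_n / 2, ext = 1)
  labels <- matrix(as.integer(ws), nrow(clumps), ncol(clumps))
  # relabel contiguously in raster order
  labs <- unique(labels[labels > 0L])
  remap <- integer(max(labs)); remap[labs] <- seq_along(labs)
  labels[labels > 0L] <- remap[labels[labels > 0L]]
  clump_lab <- if (is.logical(clumps)) label_components(clumps) else clumps
  inside <- labels > 0L
  basins <- tibble(
    clump = as.integer(clump_lab[inside]),
    basin = labels[inside]
  ) |>
    dplyr::distinct() |>
    dplyr::count(.data$clump, name = "n_basins")
  list(labels = labels, basins = basins)
}

#' Segment nuclei in an H&E image
#'
#' Full nucleus extraction pipeline: red channel, granulometric nucleus
#' scale, tile-local contrast stretch + Otsu binarization, size partition,
#' watershed splitting of clumps, fusion of single-nucleus candidates with
#' watershed basins, and filtering by the size range
#' `T_lambda = [max(1, round(lambda_n/2)), lambda_2]` (falling back to
#' `2*lambda_n` when the spectrum has no secondary peak) and by the MOR
#' circularity threshold `T_c = mean(mor) - sd(mor)` over the size-filtered
#' candidates.
#'
#' @param img RGB array from [read_rgb()] (or a gray matrix, used directly).
#' @param lambda_n Nucleus scale; `NULL` (default) estimates it from the
#'   image with [nucleus_scale()].
#' @param lambda_2 Secondary spectrum peak; `NULL` (default) estimates it
#'   alongside `lambda_n` (falls back to `2 * lambda_n` when the spectrum
#'   has no secondary peak).
#' @param split Apply watershed clump splitting (default `TRUE`).
#' @param max_scale Largest granulometry scale (default 20).
#' @param tile_factor Tile side multiplier for binarization (default 25).
#' @return An object of class `nuclei_seg`: list with `labels` (final label
#'   map), `records` (tibble of per-nucleus descriptors incl. `scale` and
#'   `circularity`), `filter` (the `T_lambda` / `T_c` actually applied),
#'   `lambda_n`, `lambda_2` and `mask` (pre-partition binarization).
#' @export
segment_nuclei <- function(img, lambda_n = NULL, lambda_2 = NULL,
                           split = TRUE, max_scale = 20, tile_factor = 25) {
  red <- if (length(dim(img)) == 3L) red_channel(img) else as_gray_matrix(img)
  if (is.null(lambda_n)) {
    ns <- nucleus_scale(red, max_scale = max_scale)
    lambda_n <- ns$lambda_n
    if (is.null(lambda_2)) lambda_2 <- ns$lambda_2
  } else if (is.null(lambda_2)) {
    ns <- tryCatch(nucleus_scale(red, max_scale = max_scale),
                   error = function(e) NULL)
    lambda_2 <- if (!is.null(ns)) ns$lambda_2 else NA_integer_
  }
  if (is.null(lambda_2) || is.na(lambda_2)) lambda_2 <- 2L * lambda_n

  mask <- binarize_nuclei(red, lambda_n, tile_factor)
  empty <- function() {
    structure(list(labels = matrix(0L, nrow(red), ncol(red)),
                   records = region_properties(matrix(0L, 1, 1), matrix(0, 1, 1)),
                   filter = list(t_lambda = c(NA, NA), t_c = NA_real_,
                                 mu_c = NA_real_, sigma_c = NA_real_),
                   lambda_n = lambda_n, lambda_2 = lambda_2, mask = mask),
              class = "nuclei_seg")
  }
  if (!any(mask)) {
    warning("no foreground after binarization; empty segmentation")
    return(empty())
  }
  part <- partition_by_size(mask, lambda_n)

  # fuse medium candidates with watershed basins (or raw clumps if disabled)
  fused <- matrix(0L, nrow(red), ncol(red))
  medsel <- part$medium > 0L
  fused[medsel] <- part$medium[medsel]
  off <- max(fused)
  if (split) {
    ws <- split_clumps(part$clumps, lambda_n)
    csel <- ws$labels > 0L
    fused[csel] <- ws$labels[csel] + off
  } else {
    csel <- part$clumps > 0L
    fused[csel] <- part$clumps[csel] + off
  }
  labels <- relabel(fused)
  if (max(labels) == 0L) {
    warning("no candidates after partition; empty segmentation")
    return(empty())
  }

  recs <- region_properties(labels, red, circularity = TRUE)
  d <- EBImage::distmap(matrix(as.integer(labels > 0L), nrow(red), ncol(red)),
                        metric = "euclidean")
  recs$scale <- as.integer(round(tapply(d[labels > 0L], labels[labels > 0L], max)))

  t_lo <- max(1L, as.integer(round(lambda_n / 2)))
  t_hi <- lambda_2
  in_size <- recs$scale >= t_lo & recs$scale <= t_hi
  cand <- recs[in_size, ]
  mu_c <- mean(cand$circularity)
  sigma_c <- if (nrow(cand) > 1) sd(cand$circularity) else 0
  t_c <- mu_c - sigma_c
  keep <- in_size & recs$circularity >= t_c

  final <- labels
  final[!(labels %in% recs$label[keep])] <- 0L
  final <- relabel(final)
  records <- region_properties(final, red, circularity = TRUE)
  d2 <- EBImage::distmap(matrix(as.integer(final > 0L), nrow(red), ncol(red)),
                         metric = "euclidean")
  if (nrow(records) > 0) {
    records$scale <- as.integer(round(tapply(d2[final > 0L], final[final > 0L], max)))
  } else {
    records$scale <- integer()
  }

  structure(
    list(labels = final, records = records,
         filter = list(t_lambda = c(t_lo, t_hi), t_c = t_c,
                       mu_c = mu_c, sigma_c = sigma_c),
         lambda_n = lambda_n, lambda_2 = lambda_2, mask = mask),
    class = "nuclei_seg"
  )
}

# compact labels to contiguous 1..L in raster-scan order of first occurrence
relabel <- function(labels) {
  labs <- unique(labels[labels > 0L])
  if (length(labs) == 0L) return(labels)
  remap <- integer(max(labs)); remap[labs] <- seq_along(labs)
  labels[labels > 0L] <- remap[labels[labels > 0L]]
  labels
}

#' @export
print.nuclei_seg <- function(x, ...) {
  cat("Nuclei segmentation:", nrow(x$records), "nuclei\n")
  cat("  lambda_n =", x$lambda_n, " lambda_2 =", x$lambda_2, "\n")
  cat("  T_lambda = [", x$filter$t_lambda[1], ",", x$filter$t_lambda[2],
      "]  T_c =", round(x$filter$t_c, 3), "\n")
  invisible(x)
}

#' Tidy a nuclei segmentation into its per-nucleus record table
#' @param x A `nuclei_seg` object.
#' @param ... Unused.
#' @export
tidy.nuclei_seg <- function(x, ...) x$records

#' One-row summary of a nuclei segmentation
#' @param x A `nuclei_seg` object.
#' @param ... Unused.
#' @export
glance.nuclei_seg <- function(x, ...) {
  tibble(
    n_nuclei = nrow(x$records),
    lambda_n = x$lambda_n, lambda_2 = x$lambda_2,
    t_lambda_lo = x$filter$t_lambda[1], t_lambda_hi = x$filter$t_lambda[2],
    t_c = x$filter$t_c,
    mean_area = mean(x$records$area),
    mean_circularity = mean(x$records$circularity)
  )
}
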