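#' Specification for a synthetic H&E phantom
#'
#' Describes a synthetic histology scene: dark purplish elliptical nuclei on
#' pinkish stroma, bright elliptical lumina ringed by nuclei (tubules),
#' bright bare gaps with no ring, per-image stain shift and pixel noise.
#' Values are chosen to emulate the red channel of H&E-stained breast tissue
#' at the magnification where nuclei are a few pixels in radius; the G and B
#' channels are filled for visual plausibility only.
#'
#' @param width,height Canvas size in pixels.
#' @param n_nuclei Number of free (non-ring) nuclei.
#' @param nucleus_radius_mean,nucleus_radius_sd Nucleus equivalent radius
#'   distribution (px).
#' @param nucleus_eccentricity_max Maximum ellipse axis ratio (>= 1);
#'   per-nucleus ratios are drawn uniformly in `[1, max]`.
#' @param clump_fraction Fraction of free nuclei placed fused to a neighbour
#'   (centre distance `0.95 * (r1 + r2)`).
#' @param n_tubules Number of planted tubules (lumina + nucleus ring).
#' @param tubule_lumina_radius Lumina equivalent radius (px); lumina are
#'   ellipses of axis ratio 1.3 at random orientation.
#' @param ring_count Nuclei per tubule ring.
#' @param ring_symmetry_noise Angular jitter of ring nuclei in `[0, 1]`
#'   (fraction of the even angular spacing).
#' @param n_bare_gaps Bright circular gaps without a nucleus ring.
#' @param n_white_patches Irregular white inter-tissue regions (slide
#'   background, fat, tears). Real H&E sections always contain such unstained
#'   space; it dominates the bright tail of the connective tissue and keeps
#'   its mean intensity well above the stroma mode.
#' @param white_patch_radius Characteristic radius of a white patch (px).
#' @param stain Named vector: `nucleus`, `stroma`, `lumina` mean red values
#'   and `shift_sd`, the per-image stain shift s.d.
#' @param nucleus_jitter_sd Per-nucleus stain jitter s.d.
#' @param noise_sigma Additive Gaussian pixel noise s.d.
#' @param grade Optional grade label (`"healthy"`, `"G1"`, `"G2"`, `"G3"`).
#' @param seed Integer seed; generation is fully deterministic given the
#'   spec.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(width = 384, height = 384,
                         n_nuclei = 110,
                         nucleus_radius_mean = 4, nucleus_radius_sd = 0.5,
                         nucleus_eccentricity_max = 1.2,
                         clump_fraction = 0,
                         n_tubules = 0, tubule_lumina_radius = 10,
                         ring_count = 10, ring_symmetry_noise = 0.15,
                         n_bare_gaps = 0,
                         n_white_patches = 16, white_patch_radius = 15,
                         stain = c(nucleus = 125, stroma = 200, lumina = 255,
                                   shift_sd = 5),
                         nucleus_jitter_sd = 6,
                         noise_sigma = 4,
                         grade = NA_character_, seed = 1) {
  stopifnot(width >= 32, height >= 32, n_nuclei >= 0, n_tubules >= 0,
            n_bare_gaps >= 0, clump_fraction >= 0, clump_fraction <= 1,
            nucleus_eccentricity_max >= 1,
            stain[["nucleus"]] < stain[["stroma"]],
            stain[["stroma"]] < stain[["lumina"]])
  structure(as.list(environment()), class = "phantom_spec")
}

#' Grade presets for phantom generation
#'
#' Encodes the structural trends of the Nottingham grading system: from
#' healthy tissue to grade 3, nuclear size and pleomorphism (radius spread,
#' eccentricity) increase, nuclei darken (hyperchromasia proxy), clumping
#' increases, and tubule formation decreases to none.
#'
#' @param grade One of `"healthy"`, `"G1"`, `"G2"`, `"G3"`.
#' @param ... Overrides passed to [phantom_spec()] (e.g. `seed`).
#' @return A `phantom_spec`.
#' @export
grade_preset <- function(grade = c("healthy", "G1", "G2", "G3"), ...) {
  grade <- match.arg(grade)
  base <- switch(grade,
    healthy = list(n_nuclei = 110, nucleus_radius_mean = 4,
                   nucleus_radius_sd = 0.4, nucleus_eccentricity_max = 1.15,
                   clump_fraction = 0, n_tubules = 8, n_bare_gaps = 2,
                   stain = c(nucleus = 125, stroma = 200, lumina = 255,
                             shift_sd = 5)),
    G1 = list(n_nuclei = 110, nucleus_radius_mean = 4.2,
              nucleus_radius_sd = 0.7, nucleus_eccentricity_max = 1.35,
              clump_fraction = 0.08, n_tubules = 7, n_bare_gaps = 2,
              stain = c(nucleus = 110, stroma = 200, lumina = 255,
                        shift_sd = 5)),
    G2 = list(n_nuclei = 110, nucleus_radius_mean = 4.8,
              nucleus_radius_sd = 1.1, nucleus_eccentricity_max = 1.6,
              clump_fraction = 0.14, n_tubules = 4, n_bare_gaps = 3,
              stain = c(nucleus = 95, stroma = 200, lumina = 255,
                        shift_sd = 5)),
    G3 = list(n_nuclei = 110, nucleus_radius_mean = 5.4,
              nucleus_radius_sd = 1.6, nucleus_eccentricity_max = 1.9,
              clump_fraction = 0.2, n_tubules = 0, n_bare_gaps = 6,
              stain = c(nucleus = 80, stroma = 200, lumina = 255,
                        shift_sd = 5))
  )
  args <- utils::modifyList(c(base, list(grade = grade)), list(...))
  do.call(phantom_spec, args)
}

#' Generate a synthetic H&E phantom with exact ground truth
#'
#' Places tubules (elliptical bright lumina ringed by `ring_count` nuclei),
#' bare bright gaps and free nuclei by dart throwing with minimum-separation
#' constraints (bounded retries), rasterizes them over noisy stroma, and
#' returns the image together with exact truth structures.
#'
#' @param spec A [phantom_spec()] (or [grade_preset()]).
#' @return A list of class `phantom`: `rgb` (H x W x 3 array in `[0,255]`),
#'   `red` (matrix), `nuclei_truth` (label map over all planted nuclei),
#'   `nuclei` (tibble: centre, axes, angle, rasterized area, stain value,
#'   `ring` = tubule id or `NA`), `tubules` and `gaps` (tibbles with centres
#'   and lumina geometry), `lumina_truth` (label map: tubule lumina then
#'   gaps), `grade`, `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  withr::with_seed(as.integer(spec$seed), generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  h <- spec$height; w <- spec$width
  st <- spec$stain
  shift <- stats::rnorm(1, 0, st[["shift_sd"]])
  r_ecc <- sqrt(1.3)  # lumina axis ratio 1.3

  lum_a <- spec$tubule_lumina_radius * r_ecc
  ring_r <- spec$nucleus_radius_mean
  foot <- lum_a + 2 * ring_r + 3  # tubule footprint radius
  margin <- foot + 3

  # --- tubule sites
  tub <- dart_throw(spec$n_tubules, h, w, margin = margin,
                    min_sep = 2 * foot + 4)
  if (nrow(tub) < spec$n_tubules) {
    stop("infeasible packing: placed ", nrow(tub), " of ", spec$n_tubules,
         " tubules")
  }
  # --- bare gaps (same brightness, no ring)
  gap_r <- spec$tubule_lumina_radius
  occupied <- dplyr::mutate(tub, r = foot)
  gaps <- dart_throw(spec$n_bare_gaps, h, w, margin = gap_r + 4,
                     min_sep = 2 * gap_r + 6, avoid = occupied,
                     avoid_pad = gap_r + 4)
  if (nrow(gaps) < spec$n_bare_gaps) {
    stop("infeasible packing: placed ", nrow(gaps), " of ", spec$n_bare_gaps,
         " bare gaps")
  }

  # --- white inter-tissue space (unstained slide background / fat)
  wp_r <- spec$white_patch_radius
  avoid_white <- dplyr::bind_rows(
    if (nrow(tub) > 0) dplyr::mutate(tub[, c("row", "col")], r = foot) else NULL,
    if (nrow(gaps) > 0) dplyr::mutate(gaps[, c("row", "col")], r = gap_r + 2)
    else NULL
  )
  white <- dart_throw(spec$n_white_patches, h, w, margin = 2,
                      min_sep = wp_r, avoid = avoid_white,
                      avoid_pad = wp_r + 4)

  # --- nuclei: ring nuclei first (part of tubules), then free nuclei
  nuclei <- list()
  if (spec$n_tubules > 0) {
    for (t in seq_len(spec$n_tubules)) {
      ang0 <- stats::runif(1, 0, 2 * pi)
      lang <- stats::runif(1, 0, pi)  # lumina orientation
      step <- 2 * pi / spec$ring_count
      for (i in seq_len(spec$ring_count)) {
        a_i <- ang0 + (i - 1) * step +
          stats::runif(1, -0.5, 0.5) * spec$ring_symmetry_noise * step
        rr <- stats::rnorm(1, spec$nucleus_radius_mean,
                           spec$nucleus_radius_sd / 2)
        rr <- max(2.5, rr)
        # ring centre on the lumina ellipse offset outward by the nucleus
        da <- lum_a + rr + 1.5
        db <- spec$tubule_lumina_radius / r_ecc + rr + 1.5
        ex <- da * cos(a_i); ey <- db * sin(a_i)
        row <- tub$row[t] + ex * sin(lang) + ey * cos(lang)
        col <- tub$col[t] + ex * cos(lang) - ey * sin(lang)
        nuclei[[length(nuclei) + 1L]] <- tibble(
          row = row, col = col, radius = rr, ecc = 1.1,
          angle = stats::runif(1, 0, pi), ring = t
        )
      }
      tub$lumina_angle[t] <- lang
    }
  }
  ring_df <- dplyr::bind_rows(nuclei)

  n_clump <- round(spec$clump_fraction * spec$n_nuclei)
  n_free <- spec$n_nuclei - n_clump
  avoid <- dplyr::bind_rows(
    dplyr::mutate(tub[, c("row", "col")], r = foot),
    if (nrow(gaps) > 0) dplyr::mutate(gaps[, c("row", "col")], r = gap_r + 1)
    else NULL,
    if (nrow(white) > 0) dplyr::mutate(white[, c("row", "col")], r = wp_r + 2)
    else NULL
  )
  rmax <- spec$nucleus_radius_mean + 3 * spec$nucleus_radius_sd
  free <- dart_throw(n_free, h, w, margin = rmax + 2,
                     min_sep = 2 * spec$nucleus_radius_mean + 3,
                     avoid = avoid, avoid_pad = rmax + 2)
  if (nrow(free) < n_free) {
    stop("infeasible packing: placed ", nrow(free), " of ", n_free,
         " free nuclei")
  }
  free$lumina_angle <- NULL
  free$radius <- pmax(2, stats::rnorm(n_free, spec$nucleus_radius_mean,
                                      spec$nucleus_radius_sd))
  free$ecc <- stats::runif(n_free, 1, spec$nucleus_eccentricity_max)
  free$angle <- stats::runif(n_free, 0, pi)
  free$ring <- NA_integer_

  clumped <- NULL
  if (n_clump > 0) {
    hosts <- sample.int(nrow(free), n_clump, replace = FALSE)
    clumped <- purrr::map(seq_len(n_clump), function(i) {
      hostrow <- free[hosts[i], ]
      rr <- max(2, stats::rnorm(1, spec$nucleus_radius_mean,
                                spec$nucleus_radius_sd))
      dd <- 0.95 * (hostrow$radius + rr)
      aa <- stats::runif(1, 0, 2 * pi)
      tibble(row = hostrow$row + dd * sin(aa), col = hostrow$col + dd * cos(aa),
             radius = rr, ecc = stats::runif(1, 1, spec$nucleus_eccentricity_max),
             angle = stats::runif(1, 0, pi), ring = NA_integer_)
    }) |> dplyr::bind_rows()
    # keep partners inside the canvas
    clumped$row <- pmin(pmax(clumped$row, rmax + 2), h - rmax - 2)
    clumped$col <- pmin(pmax(clumped$col, rmax + 2), w - rmax - 2)
  }
  all_nuclei <- dplyr::bind_rows(ring_df, free, clumped)
  if (nrow(all_nuclei) > 0) {
    all_nuclei$label <- seq_len(nrow(all_nuclei))
    all_nuclei$intensity <- pmin(pmax(
      st[["nucleus"]] + shift + stats::rnorm(nrow(all_nuclei), 0,
                                             spec$nucleus_jitter_sd), 0), 255)
  }

  # --- rasterize
  red <- matrix(st[["stroma"]] + shift, h, w) +
    matrix(stats::rnorm(h * w, 0, spec$noise_sigma), h, w)
  if (nrow(white) > 0) {
    for (p in seq_len(nrow(white))) {
      # irregular patch: union of three jittered discs
      for (kk in 1:3) {
        pr <- white$row[p] + stats::runif(1, -0.4, 0.4) * wp_r
        pc <- white$col[p] + stats::runif(1, -0.4, 0.4) * wp_r
        rad <- wp_r * stats::runif(1, 0.55, 0.95)
        px <- ellipse_pixels(pr, pc, rad, rad, 0, h, w)
        red[px] <- st[["lumina"]] + stats::rnorm(length(px), 0,
                                                 spec$noise_sigma)
      }
    }
  }
  lumina_truth <- matrix(0L, h, w)
  if (nrow(tub) > 0) {
    for (t in seq_len(nrow(tub))) {
      px <- ellipse_pixels(tub$row[t], tub$col[t], lum_a,
                           spec$tubule_lumina_radius / r_ecc,
                           tub$lumina_angle[t], h, w)
      # lumina are unstained cavities: no per-image stain shift
      red[px] <- st[["lumina"]] + stats::rnorm(length(px), 0, spec$noise_sigma)
      lumina_truth[px] <- t
    }
  }
  if (nrow(gaps) > 0) {
    for (g in seq_len(nrow(gaps))) {
      px <- ellipse_pixels(gaps$row[g], gaps$col[g], gap_r, gap_r, 0, h, w)
      red[px] <- st[["lumina"]] + stats::rnorm(length(px), 0, spec$noise_sigma)
      lumina_truth[px] <- nrow(tub) + g
    }
  }
  nuclei_truth <- matrix(0L, h, w)
  if (nrow(all_nuclei) > 0) {
    for (i in seq_len(nrow(all_nuclei))) {
      nn <- all_nuclei[i, ]
      a <- nn$radius * sqrt(nn$ecc); b <- nn$radius / sqrt(nn$ecc)
      px <- ellipse_pixels(nn$row, nn$col, a, b, nn$angle, h, w)
      red[px] <- nn$intensity + stats::rnorm(length(px), 0, spec$noise_sigma)
      nuclei_truth[px] <- nn$label
    }
    all_nuclei$area <- tabulate(nuclei_truth[nuclei_truth > 0L],
                                nbins = nrow(all_nuclei))
  }
  red <- round(pmin(pmax(red, 0), 255))

  rgb <- array(0, c(h, w, 3))
  rgb[, , 1] <- red
  rgb[, , 2] <- round(pmax(red - 60, 0))          # pink stroma, dark nuclei
  rgb[, , 3] <- round(pmin(0.85 * red + 40, 255)) # purplish cast on nuclei

  tub_out <- if (nrow(tub) > 0) {
    tibble(id = seq_len(nrow(tub)), row = tub$row, col = tub$col,
           lumina_major = 2 * lum_a,
           lumina_minor = 2 * spec$tubule_lumina_radius / r_ecc,
           lumina_angle = tub$lumina_angle, ring_count = spec$ring_count)
  } else {
    tibble(id = integer(), row = numeric(), col = numeric(),
           lumina_major = numeric(), lumina_minor = numeric(),
           lumina_angle = numeric(), ring_count = integer())
  }
  gap_out <- if (nrow(gaps) > 0) {
    tibble(id = nrow(tub) + seq_len(nrow(gaps)), row = gaps$row,
           col = gaps$col, radius = gap_r)
  } else {
    tibble(id = integer(), row = numeric(), col = numeric(), radius = numeric())
  }

  structure(
    list(rgb = rgb, red = red, nuclei_truth = nuclei_truth,
         nuclei = all_nuclei, tubules = tub_out, gaps = gap_out,
         white = white[, c("row", "col")],
         lumina_truth = lumina_truth, grade = spec$grade, spec = spec),
    class = "phantom"
  )
}

#' @export
print.phantom <- function(x, ...) {
  cat("H&E phantom", ncol(x$red), "x", nrow(x$red),
      if (!is.na(x$grade)) paste0("(", x$grade, ")") else "", "\n")
  cat(" ", nrow(x$nuclei), "nuclei,", nrow(x$tubules), "tubules,",
      nrow(x$gaps), "bare gaps\n")
  invisible(x)
}

# dart throwing with minimum separation and optional exclusion discs;
# bounded retries (1000 per structure)
dart_throw <- function(n, h, w, margin, min_sep, avoid = NULL, avoid_pad = 0) {
  rows <- numeric(0); cols <- numeric(0)
  if (n == 0) {
    return(tibble(row = rows, col = cols, lumina_angle = numeric(0)))
  }
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(1000L)) {
      r <- stats::runif(1, margin, h - margin)
      cc <- stats::runif(1, margin, w - margin)
      ok <- TRUE
      if (length(rows) > 0 &&
          any((rows - r)^2 + (cols - cc)^2 < min_sep^2)) ok <- FALSE
      if (ok && !is.null(avoid) && nrow(avoid) > 0 &&
          any((avoid$row - r)^2 + (avoid$col - cc)^2 <
                (avoid$r + avoid_pad)^2)) ok <- FALSE
      if (ok) {
        rows <- c(rows, r); cols <- c(cols, cc); placed <- TRUE; break
      }
    }
    if (!placed) break
  }
  tibble(row = rows, col = cols, lumina_angle = NA_real_)
}

# linear indices of pixels whose centres fall inside a rotated ellipse
# (1-based matrix indexing; centre in 1-based fractional coordinates)
ellipse_pixels <- function(row, col, a, b, angle, h, w) {
  r0 <- max(1L, floor(row - a)); r1 <- min(h, ceiling(row + a))
  c0 <- max(1L, floor(col - a)); c1 <- min(w, ceiling(col + a))
  if (r0 > r1 || c0 > c1) return(integer(0))
  rr <- r0:r1; cc <- c0:c1
  dy <- matrix(rr - row, length(rr), length(cc))
  dx <- matrix(rep(cc - col, each = length(rr)), length(rr), length(cc))
  ca <- cos(angle); sa <- sin(angle)
  xr <- dx * ca + dy * sa
  yr <- -dx * sa + dy * ca
  sel <- (xr / a)^2 + (yr / b)^2 <= 1
  idx <- which(sel)
  ri <- rr[(idx - 1L) %% length(rr) + 1L]
  ci <- cc[(idx - 1L) %/% length(rr) + 1L]
  ri + (ci - 1L) * h
}
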