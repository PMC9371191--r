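#' Detect lumina candidates
#'
#' Lumina (the bright interior cavities of tubules) are extracted from the
#' connective tissue remaining after nuclei segmentation: the mean intensity
#' of the connective tissue is taken as a threshold, and each connected
#' bright component is screened by three criteria — minimum area
#' `U_a = 2 * mean nucleus area`, intensity mode at or above the candidate
#' mean (mottled connective patches have a low mode), and no contact with
#' the image border (incomplete elements).
#'
#' @param img_red Red-channel gray matrix.
#' @param nuclei_labels Final nucleus label map from [segment_nuclei()].
#' @param nuclei_records Per-nucleus record tibble (needs `area`).
#' @return A list with `labels` (candidate label map) and `candidates`
#'   (tibble with geometry, intensities, `touches_border` and `status`:
#'   `"active"` or one of the `rejected_*` codes).
#' @export
lumina_candidates <- function(img_red, nuclei_labels, nuclei_records) {
  if (is.null(nuclei_records) || nrow(nuclei_records) == 0L) {
    stop("no nuclei records: mean nucleus area (U_a) is undefined")
  }
  connective <- nuclei_labels == 0L
  thr <- mean(img_red[connective])
  cand_mask <- connective & img_red > thr
  labels <- label_components(cand_mask, connectivity = 8)
  u_a <- 2 * mean(nuclei_records$area)
  if (max(labels) == 0L) {
    return(list(labels = labels,
                candidates = tibble(label = integer(), area = numeric(),
                                    perimeter = numeric(), centroid_row = numeric(),
                                    centroid_col = numeric(), mean_intensity = numeric(),
                                    intensity_mode = numeric(), touches_border = logical(),
                                    status = character()),
                threshold = thr, u_a = u_a))
  }
  # area criterion first: full descriptors only for components that pass it
  areas <- tabulate(labels[labels > 0L], nbins = max(labels))
  big <- which(areas >= u_a)
  labels_big <- labels
  labels_big[!(labels %in% big)] <- 0L
  recs <- region_properties(labels_big, img_red, circularity = FALSE)
  border_labs <- unique(c(labels[1, ], labels[nrow(labels), ],
                          labels[, 1], labels[, ncol(labels)]))
  recs$touches_border <- recs$label %in% border_labs[border_labs > 0L]
  recs$status <- dplyr::case_when(
    recs$intensity_mode < recs$mean_intensity ~ "rejected_mode",
    recs$touches_border ~ "rejected_border",
    TRUE ~ "active"
  )
  small_labs <- setdiff(seq_along(areas), big)
  cand <- dplyr::bind_rows(
    recs |>
      dplyr::select("label", "area", "perimeter", "centroid_row", "centroid_col",
                    "mean_intensity", "intensity_mode", "touches_border", "status"),
    tibble(label = small_labs, area = as.numeric(areas[small_labs]),
           perimeter = NA_real_, centroid_row = NA_real_,
           centroid_col = NA_real_, mean_intensity = NA_real_,
           intensity_mode = NA_real_, touches_border = NA,
           status = "rejected_area")
  ) |> dplyr::arrange(.data$label)
  list(labels = labels, candidates = cand, threshold = thr, u_a = u_a)
}

#' Grow glandular context around a lumina candidate
#'
#' The candidate mask is dilated by unit disks; after each step the
#' coefficient of variation `CV = sd/mean` of the image intensities inside
#' the grown region is computed. Growth stops at the first CV decrease after
#' at least one increase (nuclei absorbed raise CV; once only bright tissue
#' is added it falls), or at a cap of `3 * lambda_n` steps. The candidate is
#' kept iff the final CV exceeds `d = mu_gamma - mu_l` (normalized means of
#' the added annulus and the lumina), which prunes candidates whose
#' surroundings are brighter than themselves.
#'
#' @param cand_mask Logical mask of the active lumina candidate.
#' @param img_red Red-channel gray matrix.
#' @param nuclei_records Per-nucleus record tibble (centroids, ellipse axes).
#' @param lambda_n Nucleus scale (sets the dilation cap).
#' @param perimeter Lumina perimeter `p_l` in pixels.
#' @return A list (class `gland_region`): `region` mask at the stop step,
#'   `cv_history`, `final_cv`, `mu_l`, `mu_gamma`, `d`, `kept`,
#'   `nuclei` (records with centroid inside the region), `d_n`, `d_min`,
#'   `t_n`.
#' @export
retrieve_gland <- function(cand_mask, img_red, nuclei_records, lambda_n,
                           perimeter = NULL) {
  stopifnot(any(cand_mask))
  if (is.null(perimeter)) {
    perimeter <- sum(cpp_inner_boundary(
      matrix(as.integer(cand_mask), nrow(cand_mask), ncol(cand_mask))))
  }
  mu_l <- mean(img_red[cand_mask]) / .GRAY_MAX
  region <- cand_mask
  cv <- sd_pop(img_red[region]) / mean(img_red[region])
  cv_history <- cv
  rose <- FALSE
  best_region <- region
  cap <- max(1L, as.integer(3 * lambda_n))
  for (step in seq_len(cap)) {
    grown <- dilate(matrix(as.numeric(region), nrow(region), ncol(region)), 1) > 0
    vals <- img_red[grown]
    cv_t <- sd_pop(vals) / mean(vals)
    cv_history <- c(cv_history, cv_t)
    if (cv_t < cv_history[length(cv_history) - 1L] && rose) {
      break  # previous region was the CV peak
    }
    if (cv_t > cv_history[length(cv_history) - 1L]) rose <- TRUE
    region <- grown
    best_region <- grown
  }
  final_cv <- sd_pop(img_red[best_region]) / mean(img_red[best_region])
  annulus <- best_region & !cand_mask
  mu_gamma <- if (any(annulus)) mean(img_red[annulus]) / .GRAY_MAX else mu_l
  d <- mu_gamma - mu_l
  kept <- final_cv > d

  inside <- rep(FALSE, nrow(nuclei_records))
  if (nrow(nuclei_records) > 0L) {
    ri <- pmin(pmax(round(nuclei_records$centroid_row) + 1L, 1L), nrow(best_region))
    ci <- pmin(pmax(round(nuclei_records$centroid_col) + 1L, 1L), ncol(best_region))
    inside <- best_region[cbind(ri, ci)]
  }
  gl_nuclei <- nuclei_records[inside, , drop = FALSE]
  d_n <- if (nrow(gl_nuclei) > 0) {
    mean((gl_nuclei$ellipse_major + gl_nuclei$ellipse_minor) / 2)
  } else {
    2 * lambda_n
  }
  d_min <- if (nrow(gl_nuclei) >= 2) {
    min(stats::dist(cbind(gl_nuclei$centroid_row, gl_nuclei$centroid_col)))
  } else {
    d_n  # fallback: prevents division blow-up in T_n
  }
  t_n <- (perimeter / 2) / (d_n + d_min)

  structure(
    list(region = best_region, cv_history = cv_history, final_cv = final_cv,
         mu_l = mu_l, mu_gamma = mu_gamma, d = d, kept = kept,
         nuclei = gl_nuclei, d_n = d_n, d_min = d_min, t_n = t_n),
    class = "gland_region"
  )
}

#' Score a gland region as a tubule
#'
#' Builds the convex hull `EC` of the gland nuclei centroids plus the lumina
#' centroid, fits moments ellipses to the filled hull and to the lumina mask,
#' and combines four terms into the tubule-likelihood score
#' `Cs = penalty + l_cdis + l_theta + l_A`:
#' centroid distance (px), orientation difference (degrees, 0 for
#' near-circular ellipses whose orientation is undefined), asymmetry
#' `l_A = (1 - S) * 100` with `S = min(N_u, N_l)/max(N_u, N_l)` counting
#' nuclei on either side of the EC major axis, and a penalty of 10 when the
#' gland holds fewer nuclei than `T_n`. Scores at or below `cs_threshold`
#' classify as tubule.
#'
#' @param gland A `gland_region` from [retrieve_gland()].
#' @param lumina_mask Logical mask of the lumina candidate.
#' @param cs_threshold Decision threshold on `Cs` (default 60).
#' @param scale Rescales `l_cdis` for magnifications other than the one the
#'   threshold was calibrated at (default 1).
#' @return A one-row tibble: nuclei count, `t_n`, `penalty`, `l_cdis`,
#'   `l_theta`, `n_u`, `n_l`, `s`, `l_a`, `cs`, `is_tubule`,
#'   `lumina_in_hull`.
#' @export
assess_tubule <- function(gland, lumina_mask, cs_threshold = 60, scale = 1) {
  lrec <- region_properties(label_components(lumina_mask), lumina_mask * 0,
                            circularity = FALSE)
  lum_ctr <- c(lrec$centroid_row[1], lrec$centroid_col[1])
  lum_ell <- list(center = lum_ctr, major = lrec$ellipse_major[1],
                  minor = lrec$ellipse_minor[1], angle = lrec$ellipse_angle[1])
  nuc <- gland$nuclei
  pts <- rbind(cbind(nuc$centroid_row, nuc$centroid_col),
               matrix(lum_ctr, 1, 2))
  n_nuc <- nrow(nuc)
  penalty <- if (n_nuc < gland$t_n) 10 else 0

  degenerate_hull <- nrow(unique(round(pts, 6))) < 3 || n_nuc < 3
  if (degenerate_hull) {
    return(tibble(
      n_nuclei = n_nuc, t_n = gland$t_n, penalty = penalty,
      l_cdis = 0, l_theta = 0, n_u = 0L, n_l = 0L, s = 0, l_a = 100,
      cs = penalty + 100, is_tubule = (penalty + 100) <= cs_threshold,
      lumina_in_hull = FALSE
    ))
  }

  hull_idx <- grDevices::chull(pts[, 2], pts[, 1])  # x = col, y = row
  hull <- pts[hull_idx, , drop = FALSE]
  ec <- hull_ellipse(hull)
  l_cdis <- scale * sqrt(sum((ec$center - lum_ctr)^2))
  l_theta <- angle_difference(ec, lum_ell)

  # side of each nucleus centroid w.r.t. the EC major axis
  theta <- ec$angle * pi / 180
  # axis direction in (row, col): angle is CCW from x-axis with y (rows) down
  u <- c(-sin(theta), cos(theta))  # (drow, dcol)
  rel <- cbind(nuc$centroid_row - ec$center[1], nuc$centroid_col - ec$center[2])
  sd_signed <- rel[, 1] * u[2] - rel[, 2] * u[1]  # perpendicular component
  off_axis <- abs(sd_signed) >= 0.5
  n_u <- sum(sd_signed > 0 & off_axis)
  n_l <- sum(sd_signed < 0 & off_axis)
  s <- if (max(n_u, n_l) == 0) 0 else min(n_u, n_l) / max(n_u, n_l)
  l_a <- (1 - s) * 100

  cs <- penalty + l_cdis + l_theta + l_a
  tibble(
    n_nuclei = n_nuc, t_n = gland$t_n, penalty = penalty,
    l_cdis = l_cdis, l_theta = l_theta,
    n_u = as.integer(n_u), n_l = as.integer(n_l), s = s, l_a = l_a,
    cs = cs, is_tubule = cs <= cs_threshold,
    lumina_in_hull = point_in_hull(lum_ctr, hull)
  )
}

# moments ellipse of the filled convex hull polygon (rasterized at integer
# pixel centres over the hull bounding box)
hull_ellipse <- function(hull) {
  r0 <- floor(min(hull[, 1])); r1 <- ceiling(max(hull[, 1]))
  c0 <- floor(min(hull[, 2])); c1 <- ceiling(max(hull[, 2]))
  g <- expand.grid(row = r0:r1, col = c0:c1)
  keep <- apply(g, 1, function(p) point_in_hull(c(p[["row"]], p[["col"]]), hull))
  if (sum(keep) < 3) keep <- rep(TRUE, nrow(g))
  ell <- moments_ellipse(g$row[keep], g$col[keep])
  list(center = c(mean(g$row[keep]), mean(g$col[keep])),
       major = ell$major, minor = ell$minor, angle = ell$angle)
}

# point-in-convex-polygon by consistent cross-product sign (hull vertices in
# chull order); boundary counts as inside
point_in_hull <- function(p, hull, tol = 1e-9) {
  n <- nrow(hull)
  sgn <- 0
  for (i in seq_len(n)) {
    a <- hull[i, ]; b <- hull[if (i == n) 1L else i + 1L, ]
    cr <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    if (abs(cr) < tol) next
    if (sgn == 0) sgn <- sign(cr)
    else if (sign(cr) != sgn) return(FALSE)
  }
  TRUE
}

# Absolute orientation difference in [0, 90]. The orientation of a weakly
# anisotropic moment ellipse is statistically unstable (a few pixels of
# vertex jitter can swing it arbitrarily), so below an axis ratio of 1.2
# the orientation carries no signal and the term contributes 0.
angle_difference <- function(e1, e2, ratio_min = 1.2) {
  r1 <- if (e1$minor > 0) e1$major / e1$minor else Inf
  r2 <- if (e2$minor > 0) e2$major / e2$minor else Inf
  if (r1 < ratio_min || r2 < ratio_min) return(0)
  d <- abs(e1$angle - e2$angle) %% 180
  min(d, 180 - d)
}

#' Detect and score tubules in an H&E image
#'
#' Runs the full chain: nuclei segmentation, lumina candidate detection,
#' CV-stopped gland growth and geometric scoring. The tubule count is the
#' number of assessments with `Cs` at or below the threshold.
#'
#' @param img RGB array (or gray matrix).
#' @param cs_threshold Decision threshold on `Cs` (default 60).
#' @param nuclei Optional precomputed `nuclei_seg` for this image.
#' @param ... Passed to [segment_nuclei()].
#' @return An object of class `tubule_result`: list with `assessments`
#'   (tibble; one row per candidate, including rejected ones with `NA`
#'   scores), `tubule_count`, `nuclei`, `lumina`.
#' @export
detect_tubules <- function(img, cs_threshold = 60, nuclei = NULL, ...) {
  seg <- if (is.null(nuclei)) segment_nuclei(img, ...) else nuclei
  red <- if (length(dim(img)) == 3L) red_channel(img) else as_gray_matrix(img)
  lum <- lumina_candidates(red, seg$labels, seg$records)
  cand <- lum$candidates
  assessments <- dplyr::bind_cols(
    cand[, c("label", "status", "area", "perimeter",
             "centroid_row", "centroid_col")],
    empty_assessment()[rep(1L, nrow(cand)), ]
  )
  active <- which(cand$status == "active")
  scored <- purrr::map(active, function(i) {
    cmask <- lum$labels == cand$label[i]
    gl <- retrieve_gland(cmask, red, seg$records, seg$lambda_n,
                         perimeter = cand$perimeter[i])
    if (!gl$kept) {
      return(tibble(label = cand$label[i], status = "rejected_cv"))
    }
    a <- assess_tubule(gl, cmask, cs_threshold = cs_threshold)
    dplyr::bind_cols(tibble(label = cand$label[i], status = "assessed"),
                     a, tibble(final_cv = gl$final_cv, d = gl$d))
  })
  if (length(scored) > 0) {
    upd <- dplyr::bind_rows(scored)
    upd$is_tubule[is.na(upd$is_tubule)] <- FALSE
    assessments <- dplyr::rows_update(assessments, upd, by = "label")
  }
  count <- if (nrow(assessments) > 0) {
    sum(assessments$is_tubule, na.rm = TRUE)
  } else 0L
  structure(
    list(assessments = assessments, tubule_count = as.integer(count),
         nuclei = seg, lumina = lum),
    class = "tubule_result"
  )
}

empty_assessment <- function() {
  tibble(n_nuclei = NA_integer_, t_n = NA_real_, penalty = NA_real_,
         l_cdis = NA_real_, l_theta = NA_real_, n_u = NA_integer_,
         n_l = NA_integer_, s = NA_real_, l_a = NA_real_, cs = NA_real_,
         is_tubule = FALSE, lumina_in_hull = NA,
         final_cv = NA_real_, d = NA_real_)
}

#' @export
print.tubule_result <- function(x, ...) {
  cat("Tubule detection:", nrow(x$assessments), "lumina candidates,",
      x$tubule_count, "tubules (Cs <= threshold)\n")
  invisible(x)
}

#' Tidy a tubule result into its assessment table
#' @param x A `tubule_result` object.
#' @param ... Unused.
#' @export
tidy.tubule_result <- function(x, ...) x$assessments

#' Plot tubule-likelihood scores
#'
#' Dot plot of the `Cs` score of each assessed lumina candidate with the
#' decision threshold.
#'
#' @param object A `tubule_result` object.
#' @param cs_threshold Threshold line to draw (default 60).
#' @param ... Unused.
#' @export
autoplot.tubule_result <- function(object, cs_threshold = 60, ...) {
  df <- object$assessments |> dplyr::filter(!is.na(.data$cs))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$label), y = .data$cs,
                                   colour = .data$is_tubule)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_hline(yintercept = cs_threshold, linetype = 2) +
    ggplot2::labs(x = "lumina candidate", y = expression(C[s]),
                  colour = "tubule") +
    ggplot2::theme_minimal()
}
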