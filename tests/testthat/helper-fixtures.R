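# Shared raster fixtures and oracles, plus a per-session cache for the
# expensive phantom pipeline runs (several test files reuse the same
# segmentations).

draw_disk <- function(r, pad = 3, value = 1) {
  n <- 2 * (r + pad) + 1
  ctr <- r + pad + 1
  m <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    if ((i - ctr)^2 + (j - ctr)^2 <= r^2) m[i, j] <- value
  }
  m
}

# pixel-centre rasterized ellipse (semi-axes a >= b, angle in radians)
draw_ellipse <- function(a, b, angle = 0, pad = 3, value = 1) {
  n <- 2 * ceiling(a + pad) + 1
  ctr <- ceiling(a + pad) + 1
  m <- matrix(0, n, n)
  ca <- cos(angle); sa <- sin(angle)
  for (i in 1:n) for (j in 1:n) {
    x <- j - ctr; y <- i - ctr
    xr <- x * ca + y * sa; yr <- -x * sa + y * ca
    if ((xr / a)^2 + (yr / b)^2 <= 1) m[i, j] <- value
  }
  m
}

# place several disks on one canvas at given (row, col) centres
draw_disks_at <- function(h, w, centres, r, value = 1) {
  m <- matrix(0, h, w)
  for (k in seq_len(nrow(centres))) {
    r0 <- max(1, floor(centres[k, 1] - r)); r1 <- min(h, ceiling(centres[k, 1] + r))
    c0 <- max(1, floor(centres[k, 2] - r)); c1 <- min(w, ceiling(centres[k, 2] + r))
    for (i in r0:r1) for (j in c0:c1) {
      if ((i - centres[k, 1])^2 + (j - centres[k, 2])^2 <= r^2) m[i, j] <- value
    }
  }
  m
}

# Brute-force binary opening oracle built from explicit translations:
# a translate position is admissible iff every SE offset lands on foreground
# (pixels beyond the image edge count as foreground, matching the erosion
# border convention); the opening is the union of admissible translates.
shift_mask <- function(mask, dr, dc, pad) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(pad, h, w)
  rs <- max(1, 1 - dr):min(h, h - dr)
  cs <- max(1, 1 - dc):min(w, w - dc)
  if (length(rs) > 0 && length(cs) > 0) {
    out[rs, cs] <- mask[rs + dr, cs + dc]
  }
  out
}

oracle_opening <- function(mask, lambda) {
  se <- disk_offsets(lambda)
  admissible <- matrix(1, nrow(mask), ncol(mask))
  for (t in seq_len(se$n)) {
    admissible <- admissible * shift_mask(mask, se$dr[t], se$dc[t], pad = 1)
  }
  out <- matrix(0, nrow(mask), ncol(mask))
  for (t in seq_len(se$n)) {
    out <- pmax(out, shift_mask(admissible, -se$dr[t], -se$dc[t], pad = 0))
  }
  out
}

# ---- phantom pipeline cache ------------------------------------------------

.phantom_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .phantom_cache)) {
    assign(key, force(expr), envir = .phantom_cache)
  }
  get(key, envir = .phantom_cache)
}

healthy_phantom <- function(seed) {
  cached(paste0("ph_healthy_", seed),
         generate_phantom(grade_preset("healthy", seed = seed)))
}

healthy_seg <- function(seed) {
  cached(paste0("seg_healthy_", seed),
         segment_nuclei(healthy_phantom(seed)$rgb))
}

grade_phantom <- function(grade, seed) {
  cached(paste0("ph_", grade, "_", seed),
         generate_phantom(grade_preset(grade, seed = seed)))
}

grade_seg <- function(grade, seed) {
  cached(paste0("seg_", grade, "_", seed),
         segment_nuclei(grade_phantom(grade, seed)$rgb))
}

# mixed scene used for tubule classification: planted positives and negatives
mix_phantom <- function(seed) {
  cached(paste0("ph_mix_", seed),
         generate_phantom(phantom_spec(n_tubules = 6, n_bare_gaps = 5,
                                       n_nuclei = 60, seed = seed)))
}

mix_tubules <- function(seed) {
  cached(paste0("tub_mix_", seed), detect_tubules(mix_phantom(seed)$rgb))
}

grade_tubules <- function(grade, seed) {
  cached(paste0("tub_", grade, "_", seed),
         detect_tubules(grade_phantom(grade, seed)$rgb,
                        nuclei = grade_seg(grade, seed)))
}

# match planted bright structures (tubules/gaps) to detector output;
# returns logical "classified as tubule" per truth row
match_planted <- function(ph, result, max_dist = 15) {
  a <- result$assessments
  a <- a[!is.na(a$centroid_row), , drop = FALSE]
  truth <- rbind(
    cbind(ph$tubules$row, ph$tubules$col, 1),
    cbind(ph$gaps$row, ph$gaps$col, 0)
  )
  pred <- logical(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    d <- sqrt((a$centroid_row - (truth[i, 1] - 1))^2 +
                (a$centroid_col - (truth[i, 2] - 1))^2)
    j <- which.min(d)
    pred[i] <- length(j) == 1 && d[j] < max_dist &&
      isTRUE(a$is_tubule[j])
  }
  list(is_tubule_true = truth[, 3] == 1, is_tubule_pred = pred)
}

# centroid-match recovery rate of planted nuclei (2 px tolerance by default)
nucleus_recovery <- function(ph, seg, tol = 2, exclude_clumped = TRUE) {
  truth <- ph$nuclei
  rec <- seg$records
  if (nrow(rec) == 0) return(0)
  hits <- vapply(seq_len(nrow(truth)), function(i) {
    d <- sqrt((rec$centroid_row - (truth$row[i] - 1))^2 +
                (rec$centroid_col - (truth$col[i] - 1))^2)
    min(d) <= tol
  }, logical(1))
  mean(hits)
}
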