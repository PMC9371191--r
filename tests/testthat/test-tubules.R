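# deterministic tubule fixture: elliptical/circular bright lumina at the
# centre of a quiet stroma, optionally ringed by nucleus disks
tubule_fixture <- function(ring = "even", n_ring = 10, lumina_r = 10,
                           ring_gap = 4, nucleus_r = 4, size = 121,
                           stroma = 200, nucleus = 110, lumina = 255) {
  ctr <- (size + 1) / 2
  red <- matrix(stroma, size, size)
  lum_mask <- draw_disks_at(size, size, cbind(ctr, ctr), r = lumina_r) > 0
  red[lum_mask] <- lumina
  ring_r <- lumina_r + ring_gap + nucleus_r
  centres <- NULL
  if (ring == "even") {
    ang <- (seq_len(n_ring) - 1) * 2 * pi / n_ring + 0.3
    centres <- cbind(ctr + ring_r * sin(ang), ctr + ring_r * cos(ang))
  } else if (ring == "one_sided") {
    centres <- cbind(rep(ctr - lumina_r - 14, n_ring),
                     ctr + (seq_len(n_ring) - (n_ring + 1) / 2) * 9)
  }
  nuc_mask <- matrix(0, size, size)
  if (!is.null(centres)) {
    nuc_mask <- draw_disks_at(size, size, centres, r = nucleus_r)
    red[nuc_mask > 0] <- nucleus
  }
  labels <- label_components(nuc_mask > 0)
  records <- region_properties(labels, red, circularity = FALSE)
  list(red = red, lum_mask = lum_mask, labels = labels, records = records)
}

test_that("lumina screening applies area, mode and border criteria", {
  # scene: stroma 150, one genuine lumina, one bright speck, one mottled patch
  red <- matrix(150, 100, 100)
  red[draw_disks_at(100, 100, cbind(30, 30), r = 10) > 0] <- 250   # lumina
  red[50:52, 70:72] <- 250                                        # speck
  patch <- draw_disks_at(100, 100, cbind(75, 30), r = 9) > 0      # mottled
  vals <- rep(c(205, 205, 230), length.out = sum(patch))
  red[patch] <- vals
  nuc <- draw_disks_at(100, 100, cbind(c(10, 90), c(80, 85)), r = 4)
  labels <- label_components(nuc > 0)
  recs <- region_properties(labels, red, circularity = FALSE)

  lum <- lumina_candidates(red, labels, recs)
  cand <- lum$candidates
  status_at <- function(r, c) cand$status[cand$label == lum$labels[r, c]]
  expect_equal(status_at(30, 30), "active")
  expect_equal(status_at(51, 71), "rejected_area")
  expect_equal(status_at(75, 30), "rejected_mode")
  expect_error(lumina_candidates(red, labels, recs[0, ]), "U_a")
})

test_that("border-touching lumina candidates are rejected", {
  red <- matrix(150, 80, 80)
  red[draw_disks_at(80, 80, cbind(3, 40), r = 8) > 0] <- 250
  nuc <- draw_disks_at(80, 80, cbind(60, 60), r = 4)
  labels <- label_components(nuc > 0)
  recs <- region_properties(labels, red, circularity = FALSE)
  lum <- lumina_candidates(red, labels, recs)
  expect_true("rejected_border" %in% lum$candidates$status)
})

test_that("gland growth absorbs the nucleus ring with a rise-then-fall CV", {
  fx <- tubule_fixture()
  gl <- retrieve_gland(fx$lum_mask, fx$red, fx$records, lambda_n = 4)
  expect_true(gl$kept)
  expect_equal(nrow(gl$nuclei), 10)
  peak <- which.max(gl$cv_history)
  expect_gt(peak, 1)                       # CV rose
  expect_gt(max(gl$cv_history), gl$cv_history[1])
  expect_gt(gl$t_n, 0)
})

test_that("candidates brighter-ringed than themselves fail the CV test", {
  # a dull patch (210) inside much brighter surroundings (250)
  red <- matrix(250, 80, 80)
  patch <- draw_disks_at(80, 80, cbind(40, 40), r = 8) > 0
  red[patch] <- 210
  gl <- retrieve_gland(patch, red, tibble::tibble(
    centroid_row = numeric(), centroid_col = numeric(),
    ellipse_major = numeric(), ellipse_minor = numeric()
  ), lambda_n = 4)
  expect_false(gl$kept)
})

test_that("an ideal symmetric tubule scores as a tubule", {
  fx <- tubule_fixture()
  gl <- retrieve_gland(fx$lum_mask, fx$red, fx$records, lambda_n = 4)
  a <- assess_tubule(gl, fx$lum_mask)
  expect_equal(a$s, 1)
  expect_equal(a$l_a, 0)
  expect_lte(a$l_cdis, 2)
  expect_equal(a$penalty, 0)
  expect_lte(a$cs, 60)
  expect_true(a$is_tubule)
  expect_true(a$lumina_in_hull)
})

test_that("a one-sided nucleus arrangement is not a tubule", {
  fx <- tubule_fixture(ring = "one_sided")
  gl <- retrieve_gland(fx$lum_mask, fx$red, fx$records, lambda_n = 4)
  a <- assess_tubule(gl, fx$lum_mask)
  expect_equal(a$s, 0)
  expect_equal(a$l_a, 100)
  expect_gt(a$cs, 60)
  expect_false(a$is_tubule)
})

test_that("symmetry arithmetic follows the min/max split", {
  lum <- draw_disks_at(61, 61, cbind(31, 31), r = 6) > 0
  make_gland <- function(rows, cols) {
    list(nuclei = tibble::tibble(
      centroid_row = rows, centroid_col = cols,
      ellipse_major = 8, ellipse_minor = 8),
      t_n = 1)
  }
  # wide horizontal hull: major axis horizontal through the centre
  g33 <- make_gland(c(20, 20, 20, 40, 40, 40), c(10, 30, 50, 10, 30, 50))
  a33 <- assess_tubule(g33, lum)
  expect_equal(a33$s, 1)
  expect_equal(a33$l_a, 0)
  g24 <- make_gland(c(20, 20, 40, 40, 40, 40), c(10, 50, 10, 25, 35, 50))
  a24 <- assess_tubule(g24, lum)
  expect_equal(a24$s, 0.5)
  expect_equal(a24$l_a, 50)
  # fewer than three nuclei: degenerate hull, still assessed
  g2 <- make_gland(c(20, 40), c(30, 30))
  a2 <- assess_tubule(g2, lum)
  expect_equal(a2$s, 0)
  expect_equal(a2$l_a, 100)
  expect_false(a2$is_tubule)
})

test_that("the score decomposes exactly into its four terms", {
  for (s in 1:2) {
    a <- mix_tubules(s)$assessments
    a <- a[a$status == "assessed", ]
    expect_gt(nrow(a), 0)
    expect_equal(a$cs, a$penalty + a$l_cdis + a$l_theta + a$l_a)
    expect_true(all((a$cs <= 60) == a$is_tubule))
  }
})

test_that("the score is monotone in asymmetry and centroid distance", {
  base <- list(penalty = 0, l_cdis = 3, l_theta = 10)
  cs_of <- function(s, l_cdis) base$penalty + l_cdis + base$l_theta +
    (1 - s) * 100
  s_grid <- seq(0, 1, by = 0.25)
  expect_true(all(diff(vapply(s_grid, cs_of, numeric(1),
                              l_cdis = 3)) <= 0))
  d_grid <- seq(0, 30, by = 5)
  expect_true(all(diff(vapply(d_grid, function(d) cs_of(0.5, d),
                              numeric(1))) >= 0))
})

test_that("the tubule score is stable under 90-degree rotation", {
  fx <- tubule_fixture(n_ring = 9)  # odd ring, less symmetric
  gl <- retrieve_gland(fx$lum_mask, fx$red, fx$records, lambda_n = 4)
  a <- assess_tubule(gl, fx$lum_mask)
  rot <- function(m) t(m)[ncol(m):1, ]
  red_r <- rot(fx$red)
  lum_r <- rot(fx$lum_mask)
  labels_r <- label_components(rot(fx$labels) > 0)
  recs_r <- region_properties(labels_r, red_r, circularity = FALSE)
  gl_r <- retrieve_gland(lum_r, red_r, recs_r, lambda_n = 4)
  a_r <- assess_tubule(gl_r, lum_r)
  expect_lte(abs(a$cs - a_r$cs), 5)
})

test_that("planted bare gaps are never classified as tubules", {
  for (s in 1:2) {
    ph <- mix_phantom(s)
    m <- match_planted(ph, mix_tubules(s))
    expect_true(all(!m$is_tubule_pred[!m$is_tubule_true]))
  }
})

test_that("tubule-free high-grade phantoms yield at most one detection", {
  tr <- grade_tubules("G3", 1)
  expect_lte(tr$tubule_count, 1)
})
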