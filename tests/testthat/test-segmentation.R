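test_that("component scale is the inscribed-disk radius", {
  expect_equal(component_scale(draw_disk(4)), 4)
  line <- matrix(0, 5, 24); line[3, 3:22] <- 1
  expect_equal(component_scale(line), 1)
})

test_that("size partition routes specks, singles and fusions correctly", {
  m <- matrix(0, 60, 120)
  m <- pmax(m, draw_disks_at(60, 120, cbind(20, 20), r = 4))        # single
  m[50, 50] <- 1; m[50, 51] <- 1; m[51, 50] <- 1                    # speck
  m <- pmax(m, draw_disks_at(60, 120, cbind(c(30, 30, 30), c(80, 87, 94)),
                             r = 4))                                # 3 fused
  p <- partition_by_size(m > 0, lambda_n = 4)
  expect_equal(sort(unique(p$sizes$class)), c("clump", "medium", "small"))
  expect_equal(sum(p$sizes$class == "medium"), 1)
  expect_equal(sum(p$sizes$class == "small"), 1)
  expect_equal(sum(p$sizes$class == "clump"), 1)
  # the three maps partition the foreground
  expect_equal((p$small > 0) + (p$medium > 0) + (p$clumps > 0),
               (m > 0) * 1)
})

test_that("watershed splits k-fused disks into k basins", {
  # nuclei slightly above the image scale (lambda_n = 4), fused with 1 px
  # of overlap: the h = lambda_n/2 suppression keeps each disk one basin
  r <- 6; gap <- 11
  for (k in 2:4) {
    centres <- cbind(rep(30, k), 30 + gap * (seq_len(k) - 1))
    m <- draw_disks_at(60, 60 + k * 16, centres, r = r)
    expect_equal(max(label_components(m > 0)), 1)  # genuinely fused
    ws <- split_clumps(m > 0, lambda_n = 4)
    expect_equal(max(ws$labels), k)
    expect_equal(ws$basins$n_basins, k)
    # basins stay inside the clump
    expect_true(all(m[ws$labels > 0] > 0))
  }
})

test_that("a single convex blob is not split", {
  m <- draw_disk(7)
  ws <- split_clumps(m > 0, lambda_n = 4)
  expect_equal(max(ws$labels), 1)
})

test_that("nuclei segmentation recovers a healthy phantom", {
  ph <- healthy_phantom(1)
  seg <- healthy_seg(1)
  n_planted <- nrow(ph$nuclei)
  expect_lt(abs(nrow(seg$records) - n_planted) / n_planted, 0.1)
  ev <- evaluate_segmentation(seg$labels > 0, ph$nuclei_truth > 0)
  expect_gte(ev$sdc, 0.8)
  # every retained element satisfies the published filter
  expect_true(all(seg$records$scale >= seg$filter$t_lambda[1] &
                    seg$records$scale <= seg$filter$t_lambda[2]))
  expect_true(all(seg$records$circularity >= seg$filter$t_c))
  # filtering only removes pixels present in the binarization
  expect_true(all(seg$mask[seg$labels > 0]))
})

test_that("elongated artifacts are filtered out by the circularity threshold", {
  ph <- healthy_phantom(2)
  red <- ph$red
  # paint a long thin dark artifact (a fold or scratch)
  red[180:186, 40:140] <- 95
  seg <- segment_nuclei(red)
  if (nrow(seg$records) > 0) {
    overlap <- seg$labels[182:184, 50:130]
    covered <- mean(overlap > 0)
    expect_lt(covered, 0.2)
  }
  expect_lt(seg$filter$t_c, 1)
})

test_that("empty images give an empty, warned segmentation", {
  expect_warning(seg <- segment_nuclei(matrix(30, 100, 100), lambda_n = 4,
                                       lambda_2 = 8),
                 "empty|no ")
  expect_equal(nrow(seg$records), 0)
})
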