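test_that("masking touches exactly the half-label plus plug, all set to 0 HU", {
  ph <- std_phantom()
  seg <- std_segmentation()
  masked <- mask_half_trachea(ph$ct, seg$trachea, "right")
  delta <- which(masked$voxels != ph$ct$voxels)
  expect_gt(length(delta), 0)
  expect_true(all(masked$voxels[delta] == 0))
  # untouched voxels are bit-identical
  expect_identical(masked$voxels[-delta], ph$ct$voxels[-delta])
  # the masked trachea half lies on the left of the centroid plane
  w <- which(seg$trachea$label, arr.ind = TRUE)
  split_i <- floor(mean(w[, 1]) + 0.5)
  half <- arrayInd(delta, dim(ph$ct$voxels))
  in_label <- seg$trachea$label[delta]
  expect_true(all(half[in_label, 1] > split_i))
  # input volume unmodified
  expect_identical(ph$ct$voxels[1:10], std_phantom()$ct$voxels[1:10])
})

test_that("the plug fully blocks the opposite main bronchus", {
  ph <- std_phantom()
  seg <- std_segmentation()
  masked <- mask_half_trachea(ph$ct, seg$trachea, "right")
  lab <- grow_region(masked, seg$trachea$right_seed, -950)
  # no grown voxel belongs to the left gen-1/gen-2 subtree interior
  b <- ph$truth$graph$branches
  lb <- b[b$side == "L" & b$generation >= 1, ]
  for (r in seq_len(nrow(lb))) {
    mid <- round((c(lb$x0[r] + lb$x1[r], lb$y0[r] + lb$y1[r],
                    lb$z0[r] + lb$z1[r]) / 2) / ph$ct$spacing) + 1
    expect_false(lab[mid[1], mid[2], mid[3]],
                 label = sprintf("left branch %d reached", lb$id[r]))
  }
})

test_that("growth through the unmasked half reaches a supra-carinal branch", {
  sp <- phantom_spec(supra_carinal = TRUE)
  ph <- rasterize_phantom(sp)
  tr <- segment_trachea_stage(ph$ct, ph$truth$seed_ijk)
  expect_lte(abs(tr$carina_k - ph$truth$carina_slice), 1)
  masked <- mask_half_trachea(ph$ct, tr, "right")
  lab <- grow_region(masked, tr$right_seed, -950)
  acc <- ph$truth$graph$branches
  acc <- acc[acc$type == "accessory", ]
  mid <- round((c(acc$x0 + acc$x1, acc$y0 + acc$y1, acc$z0 + acc$z1) / 2) /
                 sp$spacing) + 1
  expect_true(lab[mid[1], mid[2], mid[3]])
})

test_that("lung thresholds stay in range and respect the budget", {
  seg <- std_segmentation()
  for (side in c("right", "left")) {
    lr <- seg[[side]]
    expect_true(lr$threshold_hu >= -1100 && lr$threshold_hu <= -800)
    acc <- lr$trace$steps[lr$trace$steps$accepted, ]
    expect_true(all(acc$n_voxels <= lr$budget))
    # voxel counts never decrease along accepted steps
    expect_true(all(diff(acc$n_voxels) >= 0))
  }
  expect_error(segment_lung(std_phantom()$ct, c(1, 1, 1), 0), "budget")
})

test_that("a wall defect triggers a rejected step; the label stays in budget", {
  segd <- defect_segmentation()
  st <- segd$left$trace$steps
  expect_true(any(!st$accepted & st$reason %in% c("leak_ratio", "leak_budget")))
  expect_lte(sum(segd$left$label), segd$left$budget)
  expect_true(segd$left$threshold_hu < -800)   # stopped short of the cap
})

test_that("corrupting one lung leaves the other's result bit-identical", {
  seg0 <- std_segmentation()
  segd <- defect_segmentation()
  expect_identical(segd$right$label, seg0$right$label)
  expect_identical(segd$right$threshold_hu, seg0$right$threshold_hu)
  # while the left side did change behaviour
  expect_false(identical(segd$left$trace$steps, seg0$left$trace$steps))
})

test_that("merge_and_close unions, fills and connects", {
  a <- array(FALSE, c(12, 12, 12)); a[2:4, 2:4, 2:4] <- TRUE
  b <- array(FALSE, c(12, 12, 12)); b[8:10, 8:10, 8:10] <- TRUE
  cfg <- airway_config(dilate_radius_vox = 0)
  expect_warning(
    m <- merge_and_close(a, b, array(FALSE, c(12, 12, 12)), cfg),
    "disconnected")
  expect_equal(sum(m$merged), sum(a) + sum(b))   # disjoint union

  # one-voxel gap bridged by dilation
  g1 <- array(FALSE, c(12, 12, 12)); g1[2:5, 5, 5] <- TRUE
  g2 <- array(FALSE, c(12, 12, 12)); g2[7:10, 5, 5] <- TRUE
  suppressWarnings(
    m2 <- merge_and_close(g1, g2, array(FALSE, c(12, 12, 12)),
                          airway_config(dilate_radius_vox = 1)))
  cc <- airwayseg:::cc_label(m2$merged, 26)
  expect_equal(max(cc), 1)
  # merged always contains the union of its parts
  expect_true(all(m2$merged[g1 | g2]))
  expect_error(merge_and_close(a, b, array(FALSE, c(5, 5, 5))), "match")
})
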