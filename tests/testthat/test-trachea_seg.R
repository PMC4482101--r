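test_that("initial crop takes full width, ~40 mm length, fractional height", {
  ct <- as_ct(array(-800, c(120, 120, 100)), spacing = c(0.7, 0.7, 0.7))
  seed <- c(60, 60, 10)
  cr <- initial_crop(ct, seed)
  expect_equal(cr$lo[1], 1); expect_equal(cr$hi[1], 120)   # full width
  jext <- cr$hi[2] - cr$lo[2] + 1
  expect_true(abs(jext - ceiling(40 / 0.7)) <= 1)          # ~58 voxels
  expect_equal(cr$lo[3], 10)
  expect_equal(cr$hi[3], 10 + floor(0.85 * 90))
  expect_true(airwayseg:::contains_point(cr, seed))

  # seed at the anterior edge: window clipped at 1
  cr2 <- initial_crop(ct, c(60, 1, 10))
  expect_equal(cr2$lo[2], 1)
  expect_lte(cr2$hi[2] - cr2$lo[2] + 1, ceiling(40 / 0.7) + 1)
  expect_true(airwayseg:::contains_point(cr2, c(60, 1, 10)))
})

test_that("trachea schedule starts at -900, steps by 10/20/50, ends in range", {
  ph <- small_phantom()
  seed <- ph$truth$seed_ijk
  cr <- initial_crop(ph$ct, seed)
  tr <- segment_trachea(ph$ct, cr, seed)
  expect_equal(tr$steps$threshold_hu[1], -900)
  expect_true(tr$final_threshold_hu > -1024 && tr$final_threshold_hu <= -800)
  dthr <- abs(diff(tr$steps$threshold_hu))
  expect_true(all(dthr %in% c(10, 20, 50)))
  expect_equal(tr$final_threshold_hu,
               tr$steps$threshold_hu[max(which(tr$steps$accepted))])
  # re-running is bit-identical
  tr2 <- segment_trachea(ph$ct, cr, seed)
  expect_identical(tr$steps, tr2$steps)
  expect_identical(tr$final_label, tr2$final_label)
})

test_that("a label exploding across the crop is rejected and recovered at -920", {
  # tube of -1000 HU embedded in -910 HU filler: at -900 the filler floods
  # (geometric leak); at -920 only the tube remains
  arr <- array(-910, c(60, 60, 60))
  arr[28:32, 28:32, ] <- -1000
  ct <- as_ct(arr, spacing = c(1, 1, 1))
  cr <- crop_region(c(1, 10, 5), c(60, 50, 55))
  tr <- segment_trachea(ct, cr, c(30, 30, 5))
  expect_false(tr$steps$accepted[1])
  expect_equal(tr$steps$reason[1], "leak_geometry")
  expect_equal(tr$steps$threshold_hu[1], -900)
  expect_equal(tr$steps$threshold_hu[2], -920)
  expect_lte(tr$final_threshold_hu, -910)
  # the final label is the clean tube, not the flooded crop
  expect_equal(sum(tr$final_label), sum(arr[, 10:50, 5:55] == -1000))
})

test_that("a volume with nothing below the cap fails with a clear error", {
  ct <- as_ct(array(40, c(30, 30, 30)))
  cr <- initial_crop(ct, c(15, 15, 5))
  expect_error(segment_trachea(ct, cr, c(15, 15, 5)), "failed")
})

test_that("carina detection finds the first split and rejects non-splitting labels", {
  ph <- std_phantom()
  seg <- std_segmentation()
  expect_lte(abs(seg$trachea$carina_k - ph$truth$carina_slice), 1)

  # straight cylinder never splits
  cyl <- tube_label(c(20, 20, 40), c(10, 10, 2), c(10, 10, 38), 4)
  expect_error(find_carina(cyl, c(10, 10, 5)), "not found")

  # arms that merge back: the first split slice is returned, not later ones
  y <- array(FALSE, c(30, 30, 40))
  y[14:16, 14:16, 2:10] <- TRUE                  # single column
  y[6:10, 14:16, 11:20] <- TRUE                  # two arms
  y[20:24, 14:16, 11:20] <- TRUE
  y[6:24, 14:16, 21:25] <- TRUE                  # merged again
  y[6:10, 14:16, 26:30] <- TRUE                  # second split
  y[20:24, 14:16, 26:30] <- TRUE
  expect_equal(find_carina(y, c(15, 15, 3)), 11)
})

test_that("crop refinement shortens k and grows j only when the label touches", {
  ct <- as_ct(array(-800, c(60, 60, 60)), spacing = c(1, 1, 1))
  cr <- crop_region(c(1, 20, 5), c(60, 40, 55))
  lab <- array(FALSE, c(60, 60, 60))
  lab[28:32, 28:32, 5:30] <- TRUE                # well inside
  r1 <- refine_crop(ct, cr, 25, lab)
  expect_equal(r1$hi[3], 25 + 3)
  expect_equal(r1$lo[2], cr$lo[2]); expect_equal(r1$hi[2], cr$hi[2])
  expect_equal(r1$lo[1], cr$lo[1]); expect_equal(r1$hi[1], cr$hi[1])

  lab2 <- lab; lab2[28:32, 20:32, 5:30] <- TRUE  # touches anterior j face
  r2 <- refine_crop(ct, cr, 25, lab2)
  expect_lt(r2$lo[2], cr$lo[2])
  expect_equal(r2$hi[2], cr$hi[2])
  # refined crop still contains the label up to carina + margin
  w <- which(lab2[, , 1:r2$hi[3]], arr.ind = TRUE)
  expect_true(all(w[, 2] >= r2$lo[2] & w[, 2] <= r2$hi[2]))
})

test_that("bronchial seeds are component centroids, snapped and ordered", {
  lab <- array(FALSE, c(40, 40, 10))
  lab[5:9, 11:15, 6] <- TRUE                     # right (low i) 5x5 square
  lab[25:29, 21:25, 6] <- TRUE                   # left 5x5 square
  s <- place_bronchial_seeds(lab, 6)
  expect_equal(s$right, c(7, 13, 6))
  expect_equal(s$left, c(27, 23, 6))

  # three components: the two largest win
  lab[35:36, 2:3, 6] <- TRUE
  s2 <- place_bronchial_seeds(lab, 6)
  expect_equal(s2$right, c(7, 13, 6))
  expect_equal(s2$left, c(27, 23, 6))

  # C-shaped component: centroid falls in the concavity, snapped inside
  cc <- array(FALSE, c(40, 40, 10))
  cc[10:20, 10:12, 4] <- TRUE
  cc[10:12, 12:20, 4] <- TRUE
  cc[10:20, 20:22, 4] <- TRUE
  cc[30:32, 30:32, 4] <- TRUE                    # second blob
  s3 <- place_bronchial_seeds(cc, 4)
  expect_true(cc[s3$right[1], s3$right[2], 4])
  expect_true(cc[s3$left[1], s3$left[2], 4])
  expect_error(place_bronchial_seeds(lab, 2), "split")
})

test_that("the full trachea stage yields seeds on opposite sides of the centroid", {
  seg <- std_segmentation()
  tr <- seg$trachea
  w <- which(tr$label, arr.ind = TRUE)
  ci <- mean(w[, 1])
  expect_lt(tr$right_seed[1], ci)
  expect_gt(tr$left_seed[1], ci)
  expect_gt(tr$carina_k, std_phantom()$truth$seed_ijk[3])
  expect_equal(tr$n_trachea, sum(tr$label))
})
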