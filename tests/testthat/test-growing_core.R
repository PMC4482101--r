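test_that("region growing obeys the strict-below inclusion rule", {
  ct <- as_ct(array(-1000, c(5, 5, 5)))
  lab <- grow_region(ct, c(3, 3, 3), -800)
  expect_equal(sum(lab), 125)

  arr <- array(-1000, c(5, 5, 5)); arr[3, 3, 3] <- -700
  expect_equal(sum(grow_region(as_ct(arr), c(3, 3, 3), -800)), 0)

  # a voxel exactly at the threshold is excluded
  arr2 <- array(-850, c(3, 3, 3))
  expect_equal(sum(grow_region(as_ct(arr2), c(2, 2, 2), -850)), 0)
  expect_equal(sum(grow_region(as_ct(arr2), c(2, 2, 2), -849)), 27)
  expect_error(grow_region(ct, matrix(nrow = 0, ncol = 3), -800), "seed")
})

test_that("region growing matches the BFS oracle and is threshold-monotone", {
  set.seed(11)
  for (rep in 1:8) {
    arr <- array(sample(c(-1000, -500), 12^3, replace = TRUE), dim = c(12, 12, 12))
    ct <- as_ct(arr)
    seed <- c(sample(12, 1), sample(12, 1), sample(12, 1))
    for (conn in c(6, 26)) {
      expect_identical(grow_region(ct, seed, -800, conn),
                       bfs_grow_oracle(arr, seed, -800, conn))
    }
    # monotone in threshold and always a subset of the eligible set
    l1 <- grow_region(ct, seed, -900)
    l2 <- grow_region(ct, seed, -400)
    expect_true(all(!l1 | l2))
    expect_true(all(arr[l2] < -400))
  }
})

test_that("growth ratio and its leak rule follow the strict comparator", {
  expect_equal(growth_ratio(1700, 1000), 1.7)
  expect_equal(growth_ratio(1000, 1000), 1.0)
  expect_equal(growth_ratio(1600, 1000), 1.6)
  expect_true(is_ratio_leak(1.7))
  expect_false(is_ratio_leak(1.6))     # boundary not flagged
  expect_false(is_ratio_leak(0.9))
  expect_error(growth_ratio(10, 0), "undefined")
})

test_that("kernel groups classify case-insensitively with a fallback", {
  expect_equal(kernel_group("b30F"), "smooth_std")
  expect_equal(kernel_group("STANDARD"), "smooth_std")
  expect_equal(kernel_group("std"), "smooth_std")
  expect_equal(kernel_group("Lung"), "lung_sharp")
  expect_equal(kernel_group("D"), "very_sharp")
  expect_equal(kernel_group(""), "other")
  expect_equal(kernel_group("MYSTERY"), "other")
})

test_that("the voxel-percentage lookup reproduces every band of the table", {
  cases <- rbind(
    # smooth/standard group: three S bands x three N bands + boundaries
    data.frame(k = "B30f", s = 250, n = c(1e4, 2e4, 3e4, 5e4, 6e4),
               p = c(0.9, 0.9, 0.75, 0.75, 0.5)),
    data.frame(k = "B20f", s = 350, n = c(5e4, 8.5e4, 9e4, 1e5, 2e5),
               p = c(0.9, 0.9, 0.75, 0.75, 0.5)),
    data.frame(k = "Standard", s = 500, n = c(1e5, 14e4, 15e4, 17e4, 18e4),
               p = c(0.9, 0.9, 0.75, 0.75, 0.5)),
    # lung/sharp group: five, four and four N bands
    data.frame(k = "LUNG", s = 250,
               n = c(9e3, 1e4, 2e4, 3.5e4, 5e4, 7.5e4, 8e4, 8.5e4, 9e4),
               p = c(0.8, 0.8, 0.5, 0.5, 0.35, 0.35, 0.3, 0.3, 0.2)),
    data.frame(k = "FC50", s = 350, n = c(8e4, 8.5e4, 9e4, 1e5, 1.1e5, 1.2e5, 1.3e5),
               p = c(0.7, 0.7, 0.5, 0.5, 0.35, 0.35, 0.2)),
    data.frame(k = "B50f", s = 450, n = c(7e4, 8e4, 1e5, 11.5e4, 12e4, 14e4, 15e4),
               p = c(0.75, 0.75, 0.5, 0.5, 0.35, 0.35, 0.2)),
    # very sharp group: two S bands
    data.frame(k = "B70s", s = 250, n = c(2e4, 3e4, 5e4, 6e4, 8e4, 9e4, 1e5),
               p = c(0.8, 0.8, 0.6, 0.6, 0.5, 0.5, 0.35)),
    data.frame(k = "B60f", s = 500, n = c(4e4, 5e4, 7e4, 8e4, 1e5, 12e4, 13e4),
               p = c(0.8, 0.8, 0.6, 0.6, 0.4, 0.4, 0.25)),
    # fallback group
    data.frame(k = "MYSTERY_KERNEL", s = 200, n = c(3e4, 4e4, 8e4, 9e4, 1e5),
               p = c(0.8, 0.8, 0.55, 0.55, 0.35)),
    data.frame(k = "", s = 400, n = c(6e4, 7e4, 1e5, 13e4, 14e4),
               p = c(0.8, 0.8, 0.55, 0.55, 0.3))
  )
  for (r in seq_len(nrow(cases))) {
    expect_equal(trachea_percentage(cases$k[r], cases$s[r], cases$n[r]),
                 cases$p[r],
                 label = sprintf("kernel %s, S=%d, N=%g", cases$k[r],
                                 cases$s[r], cases$n[r]))
  }
  # S-band boundaries are upper-inclusive as well
  expect_equal(trachea_percentage("B30f", 300, 6e4), 0.5)
  expect_equal(trachea_percentage("B30f", 301, 6e4), 0.9)
  expect_equal(trachea_percentage("B70f", 300, 9e4), 0.5)
  expect_equal(trachea_percentage("B70f", 301, 9e4), 0.4)
})

test_that("the per-lung budget is the rounded percentage of trachea voxels", {
  expect_equal(max_voxels_allowed("B30f", 250, 60000), 30000)
  expect_equal(max_voxels_allowed("LUNG", 250, 9000), 7200)
  expect_equal(max_voxels_allowed("B30f", 250, 0), 0)
  expect_equal(max_voxels_allowed("", 100, 0), 0)
})

test_that("label extents match a brute-force bounding-box scan", {
  one <- array(FALSE, c(6, 6, 6)); one[3, 4, 5] <- TRUE
  expect_equal(unname(label_extent(one)), c(1, 1, 1))
  blk <- array(FALSE, c(10, 10, 10)); blk[2:4, 3:6, 1:5] <- TRUE
  expect_equal(unname(label_extent(blk)), c(3, 4, 5))
  # L-shape vs brute force
  L <- array(FALSE, c(12, 12, 12))
  L[2:9, 3, 4] <- TRUE; L[2, 3:8, 4] <- TRUE
  w <- which(L, arr.ind = TRUE)
  brute <- apply(w, 2, function(v) diff(range(v)) + 1)
  expect_equal(unname(label_extent(L)), unname(brute))
  expect_error(label_extent(array(FALSE, c(3, 3, 3))), "empty")
  # window restriction
  expect_equal(unname(label_extent(blk, crop_region(c(3, 4, 2), c(10, 10, 3)))),
               c(2, 3, 2))
})

test_that("hole filling and dilation behave as set operations", {
  shell <- array(FALSE, c(7, 7, 7))
  shell[2:6, 2:6, 2:6] <- TRUE
  shell[3:5, 3:5, 3:5] <- FALSE
  filled <- fill_holes(shell)
  expect_equal(sum(filled), 125)
  expect_identical(fill_holes(filled), filled)

  single <- array(FALSE, c(5, 5, 5)); single[3, 3, 3] <- TRUE
  expect_equal(sum(dilate(single, 1)), 7)           # 6-ball cross
  expect_identical(dilate(single, 0), single)

  set.seed(3)
  for (rep in 1:10) {
    lab <- array(runif(6^3) < 0.3, dim = c(6, 6, 6))
    f1 <- fill_holes(lab)
    expect_identical(fill_holes(f1), f1)            # idempotent
    expect_true(all(!lab | f1))                     # never removes voxels
    expect_gte(sum(dilate(lab, 1)), sum(lab))
  }
})
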