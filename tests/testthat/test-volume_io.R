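test_that("NRRD write/read round-trips voxels, spacing and origin exactly", {
  set.seed(42)
  arr <- array(sample(-1000:400, 16^3, replace = TRUE), dim = c(16, 16, 16))
  ct <- ct_volume(arr, spacing = c(0.7, 0.8, 1.25), origin = c(-5, 3.5, 100))
  f <- tempfile(fileext = ".nrrd")
  write_ct(ct, f)
  ct2 <- read_ct(f)
  expect_identical(dim(ct2$voxels), dim(ct$voxels))
  expect_equal(ct2$voxels, ct$voxels)
  expect_equal(ct2$spacing, ct$spacing)
  expect_equal(ct2$origin, ct$origin)
  expect_equal(ct2$meta$slice_count, 16L)
  expect_identical(ct2$meta$source, "nrrd")
})

test_that("NIfTI header spacing passes through and voxels round-trip", {
  arr <- array(round(rnorm(10 * 12 * 8, -800, 50)), dim = c(10, 12, 8))
  ct <- ct_volume(arr, spacing = c(0.625, 0.625, 1.25))
  f <- tempfile(fileext = ".nii.gz")
  write_ct(ct, f)
  ct2 <- read_ct(f)
  expect_equal(ct2$spacing, c(0.625, 0.625, 1.25), tolerance = 1e-6)
  expect_equal(ct2$voxels, ct$voxels)
})

test_that("unreadable and unsupported inputs raise format errors", {
  d <- tempfile(); dir.create(d)
  expect_error(read_ct(d), "no DICOM")
  file.create(file.path(d, "slice1.dcm"))
  expect_error(read_ct(d), "not supported")
  expect_error(read_ct(tempfile(fileext = ".nrrd")), "not found")
  txt <- tempfile(fileext = ".txt"); writeLines("x", txt)
  expect_error(read_ct(txt), "unrecognized")
  bad <- tempfile(fileext = ".nrrd"); writeLines("not a header", bad)
  expect_error(read_ct(bad), "NRRD")
})

test_that("label maps round-trip and reject mismatched grids", {
  ref <- as_ct(array(-800, c(10, 10, 10)))
  lab <- array(FALSE, c(10, 10, 10))
  lab[sample(1000, 17)] <- TRUE
  f <- tempfile(fileext = ".nrrd")
  write_label(lab, ref, f)
  lab2 <- read_label(f)
  expect_equal(sum(lab2), 17)
  expect_equal(lab2, lab)
  expect_error(write_label(array(FALSE, c(5, 5, 5)), ref, f), "match")
  write_label(array(FALSE, c(10, 10, 10)), ref, f)
  expect_equal(sum(read_label(f)), 0)
})

test_that("fcsv and JSON seed files parse; malformed rows are skipped", {
  f <- tempfile(fileext = ".fcsv")
  writeLines(c("# Markups fiducial file version = 4.11",
               "# CoordinateSystem = LPS",
               "# columns = id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,desc,assoc",
               "F1,0,0,0,0,0,0,1,1,1,0,seed,,"), f)
  s <- read_seeds(f)
  expect_equal(nrow(s), 1)
  expect_equal(unlist(s[1, c("x", "y", "z")]), c(x = 0, y = 0, z = 0))

  # RAS coordinates are negated in x and y on read
  f2 <- tempfile(fileext = ".fcsv")
  writeLines(c("# CoordinateSystem = RAS",
               "F1,10,-20,30,0,0,0,1,1,1,0,a,,"), f2)
  s2 <- read_seeds(f2)
  expect_equal(unlist(s2[1, c("x", "y", "z")]), c(x = -10, y = 20, z = 30))

  # three rows, one malformed: two seeds and a warning
  f3 <- tempfile(fileext = ".fcsv")
  writeLines(c("# CoordinateSystem = LPS",
               "F1,1,2,3,0,0,0,1,1,1,0,a,,",
               "F2,not,a,number,0,0,0,1,1,1,0,b,,",
               "F3,4,5,6,0,0,0,1,1,1,0,c,,"), f3)
  expect_warning(s3 <- read_seeds(f3), "malformed")
  expect_equal(nrow(s3), 2)

  fj <- tempfile(fileext = ".json")
  writeLines('[{"x": 1, "y": 2, "z": 3}, {"x": -4, "y": 0, "z": 9}]', fj)
  sj <- read_seeds(fj)
  expect_equal(nrow(sj), 2)
  expect_equal(sj$x, c(1, -4))      # file order preserved

  fe <- tempfile(fileext = ".json"); writeLines("[]", fe)
  expect_error(read_seeds(fe), "no parsable")
})

test_that("physical/index mapping is self-inverse and k runs inferiorly", {
  ct <- as_ct(array(-800, c(20, 22, 24)), spacing = c(0.6, 0.7, 1.2))
  set.seed(7)
  for (rep in 1:25) {
    ijk <- c(sample(20, 1), sample(22, 1), sample(24, 1))
    xyz <- ijk_to_physical(ct, ijk)
    expect_equal(physical_to_ijk(ct, xyz), as.integer(ijk))
  }
  # moving one slice towards the feet decreases LPS z
  z1 <- ijk_to_physical(ct, c(1, 1, 1))[3]
  z2 <- ijk_to_physical(ct, c(1, 1, 2))[3]
  expect_lt(z2, z1)
})

test_that("volume construction validates spacing and HU range", {
  expect_error(ct_volume(array(0, c(3, 3, 3)), c(1, -1, 1)), "positive")
  expect_error(ct_volume(array(5000, c(3, 3, 3)), c(1, 1, 1)), "HU")
  expect_error(resolve_seed(as_ct(array(0, c(4, 4, 4))), c(9, 1, 1)),
               "outside")
})
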