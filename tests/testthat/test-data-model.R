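# Core containers, intensity normalization and file IO.

test_that("image_slice and slice_pair enforce their invariants", {
  img <- image_slice(matrix(1:12 / 12, 3, 4), spacing = c(1, 2))
  expect_identical(dim(img), c(3L, 4L))
  expect_error(image_slice(matrix(c(1, NA, 3, 4), 2, 2)), "finite")
  expect_error(image_slice(matrix(1, 2, 2), spacing = c(0, 1)), "positive")

  f <- image_slice(matrix(0, 4, 4), modality = "US")
  m <- image_slice(matrix(0, 4, 4), modality = "MR")
  p <- slice_pair(f, m, case_id = "c1", slice_index = 3L)
  expect_s3_class(p, "slice_pair")
  expect_error(slice_pair(m, f), "US")
  expect_error(slice_pair(f, image_slice(matrix(0, 4, 5), modality = "MR")),
               "grid")
  m2 <- image_slice(matrix(0, 4, 4), spacing = c(1, 2), modality = "MR")
  expect_error(slice_pair(f, m2), "spacing")
})

test_that("landmark_set pairs corresponding points and rejects mismatches", {
  lm <- landmark_set(cbind(c(1, 2), c(3, 4)), cbind(c(1.5, 2), c(3, 4.5)))
  expect_identical(length(lm), 2L)
  expect_error(landmark_set(cbind(1, 2), rbind(c(1, 2), c(3, 4))),
               "pairing")
  expect_error(landmark_set(cbind(NA_real_, 1), cbind(1, 1)), "finite")
})

test_that("normalize_intensity maps percentile range onto [0, 1]", {
  img <- image_slice(matrix(0:100, 1, 101))
  out <- normalize_intensity(img, 0, 100)
  expect_equal(out$pixels, matrix(0:100 / 100, 1, 101))

  expect_equal(normalize_intensity(image_slice(matrix(7, 5, 5)))$pixels,
               matrix(0, 5, 5))

  # values below the 1st / above the 99th percentile clip to 0 / 1,
  # checked against a direct sort-based percentile computation
  v <- matrix(0:999, 25, 40)
  out <- normalize_intensity(image_slice(v), 1, 99)
  q <- stats::quantile(v, c(0.01, 0.99), names = FALSE)
  expect_true(all(out$pixels[v <= q[1]] == 0))
  expect_true(all(out$pixels[v >= q[2]] == 1))
  mid <- v > q[1] & v < q[2]
  expect_equal(out$pixels[mid], (v[mid] - q[1]) / (q[2] - q[1]))

  expect_error(normalize_intensity(img, 60, 40), "lo_pct")
})

test_that("normalize_intensity is invariant to positive affine rescaling", {
  set.seed(41)
  v <- matrix(rnorm(400), 20, 20)
  base <- normalize_intensity(image_slice(v))$pixels
  for (ab in list(c(2.5, 1), c(0.03, -7), c(100, 42))) {
    resc <- normalize_intensity(image_slice(ab[1] * v + ab[2]))$pixels
    expect_lt(max(abs(resc - base)), 1e-9)
  }
})

test_that("volume IO round-trips through NIfTI and MetaImage", {
  set.seed(42)
  vol <- volume(array(rnorm(4 * 5 * 6), c(4, 5, 6)),
                spacing = c(1, 1, 1), origin = c(2, -3, 4))
  for (ext in c(".nii", ".nii.gz", ".mha", ".mhd")) {
    path <- tempfile(fileext = ext)
    write_volume(vol, path)
    back <- read_volume(path)
    expect_equal(back$voxels, vol$voxels, tolerance = 1e-6)
    expect_equal(back$spacing, vol$spacing, tolerance = 1e-6)
    expect_equal(back$origin, vol$origin, tolerance = 1e-6)
  }
})

test_that("MetaImage header spacing is honoured", {
  vol <- volume(array(0, c(3, 3, 3)), spacing = c(0.24, 0.24, 0.24))
  path <- tempfile(fileext = ".mha")
  write_volume(vol, path)
  expect_equal(read_volume(path)$spacing, c(0.24, 0.24, 0.24))
})

test_that("read_volume rejects unsupported and missing files", {
  bad <- tempfile(fileext = ".txt")
  writeLines("nope", bad)
  expect_error(read_volume(bad), "unsupported extension")
  expect_error(read_volume(tempfile(fileext = ".nii")), "not found")
})

test_that("extract_slice_pair resamples the moving volume onto the fixed grid", {
  set.seed(7)
  vox <- array(runif(8 * 8 * 8), c(8, 8, 8))
  va <- volume(vox); vb <- volume(vox)
  p <- extract_slice_pair(va, vb, "axial", 4)
  expect_equal(p$fixed$pixels, p$moving$pixels)
  expect_identical(p$fixed$modality, "US")
  expect_identical(p$moving$modality, "MR")

  # moving volume displaced by exactly one voxel along +x: resampling onto
  # the fixed grid shifts its content one pixel with a zero-filled border
  # column (constructed independently by direct array shifting)
  vb2 <- volume(vox, origin = c(0, 0, 1))
  p2 <- extract_slice_pair(va, vb2, "axial", 4)
  expected <- cbind(0, p2$fixed$pixels[, 1:7])
  expect_equal(p2$moving$pixels, expected, tolerance = 1e-12)

  expect_error(extract_slice_pair(va, vb, "axial", 9), "out of range")
  far <- volume(vox, origin = c(1000, 1000, 1000))
  expect_error(extract_slice_pair(va, far, "axial", 4), "overlap")
})

test_that("slice extraction is idempotent on an already co-gridded pair", {
  set.seed(8)
  vox <- array(runif(6 * 6 * 6), c(6, 6, 6))
  p1 <- extract_slice_pair(volume(vox), volume(vox + 0), "coronal", 3)
  va <- volume(array(p1$fixed$pixels, c(1, 6, 6)))
  vb <- volume(array(p1$moving$pixels, c(1, 6, 6)))
  p2 <- extract_slice_pair(va, vb, "axial", 1)
  expect_equal(p2$fixed$pixels, p1$fixed$pixels)
  expect_equal(p2$moving$pixels, p1$moving$pixels, tolerance = 1e-12)
})

test_that("landmark CSV and MNI tag dialects parse and round-trip", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("fixed_y,fixed_x,moving_y,moving_x",
               "10.0,12.0,11.5,13.0"), csv)
  lm <- read_landmarks(csv)
  expect_equal(lm$fixed_points[1, ], c(y_mm = 10, x_mm = 12))
  expect_equal(lm$moving_points[1, ], c(y_mm = 11.5, x_mm = 13))

  tag <- tempfile(fileext = ".tag")
  writeLines(c("MNI Tag Point File", "Volumes = 2;", "% comment",
               "Points =",
               " 1.0 2.0 0.0 1.5 2.5 0.0 \"lm1\"",
               " 3.0 4.0 0.0 3.5 4.5 0.0 \"lm2\";"), tag)
  lt <- read_landmarks(tag)
  expect_identical(length(lt), 2L)
  # tag coordinates are (x, y, z); the set stores (y, x)
  expect_equal(unname(lt$fixed_points[1, ]), c(2, 1))
  expect_equal(unname(lt$moving_points[2, ]), c(4.5, 3.5))

  out <- tempfile(fileext = ".csv")
  write_landmarks(lt, out)
  back <- read_landmarks(out)
  expect_equal(back$fixed_points, lt$fixed_points, tolerance = 1e-6)
  expect_equal(back$moving_points, lt$moving_points, tolerance = 1e-6)

  empty <- tempfile(fileext = ".csv")
  writeLines("fixed_y,fixed_x,moving_y,moving_x", empty)
  expect_error(read_landmarks(empty), "pairing")

  bad <- tempfile(fileext = ".tag")
  writeLines(c("Points =", "1 2 3 4 5;"), bad)
  expect_error(read_landmarks(bad), "multiple of 6")
})
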