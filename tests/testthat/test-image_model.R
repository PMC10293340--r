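test_that("volume round-trips through NIfTI with spacing preserved", {
  set.seed(7)
  v <- volume_image(array(rnorm(10 * 10 * 10), c(10, 10, 10)),
                    spacing = c(1.8, 1.4, 2.5))
  expect_equal(voxel_volume_mm3(v), 1.8 * 1.4 * 2.5)
  f <- tempfile(fileext = ".nii.gz")
  write_volume(v, f)
  v2 <- read_volume(f)
  expect_equal(v2$spacing, v$spacing, tolerance = 1e-6)
  # float32 storage: lossless to single precision
  expect_equal(v2$voxels, v$voxels, tolerance = 1e-6)
  unlink(f)
})

test_that("label maps round-trip exactly as uint8 with the class alphabet", {
  set.seed(8)
  l <- label_map(array(sample(0:4, 4 * 5 * 6, TRUE), c(4, 5, 6)),
                 spacing = c(1, 1, 1))
  f <- tempfile(fileext = ".nii.gz")
  write_labels(l, f)
  l2 <- read_labels(f)
  expect_identical(l2$labels, l$labels)
  expect_identical(l2$class_names, fetal_classes())
  hdr <- RNifti::niftiHeader(f)
  expect_identical(hdr$datatype, 2L)  # DT_UINT8 on disk
  unlink(f)
})

test_that("I/O rejects malformed inputs", {
  expect_error(read_volume(tempfile()), "not found")
  f <- tempfile(fileext = ".nii.gz")
  img <- RNifti::asNifti(matrix(rnorm(16), 4, 4))
  RNifti::writeNifti(img, f)
  expect_error(read_volume(f), "3D")
  unlink(f)
  v <- volume_image(array(0, c(2, 2, 2)), c(1, 1, 1))
  expect_error(write_volume(v, tempdir()), "directory")
  expect_error(volume_image(array(0, c(2, 2, 2)), c(1, -1, 1)), "positive")
  expect_error(label_map(array(9L, c(2, 2, 2)), c(1, 1, 1)), "labels")
})

test_that("class probabilities must sum to one per voxel", {
  p <- array(0.2, dim = c(3, 3, 3, 5))
  expect_s3_class(class_probabilities(p), "class_probabilities")
  p[1, 1, 1, 1] <- 0.5
  expect_error(class_probabilities(p), "sum to 1")
})

test_that("isotropic resampling preserves trivial cases", {
  set.seed(9)
  v <- volume_image(array(rnorm(5 * 6 * 7), c(5, 6, 7)), c(2, 2, 2))
  vi <- resample_isotropic(v, 2)
  expect_identical(dim(vi$voxels), dim(v$voxels))
  expect_equal(vi$voxels, v$voxels)
  vc <- volume_image(array(3.5, c(8, 9, 10)), c(1.8, 1.4, 2.5))
  vr <- resample_isotropic(vc, 1.5)
  expect_equal(range(vr$voxels), c(3.5, 3.5))
  expect_equal(vr$spacing, rep(1.5, 3))
  expect_error(resample_isotropic(v, -1), "positive")
})

test_that("nearest-neighbour resampling of a sphere conserves volume", {
  # binary sphere of radius 10 mm on a 2 mm grid, resampled at 1 mm
  n <- 16L
  cv <- (seq_len(n) - 0.5) * 2
  cc <- n  # centre at 16 mm
  d2 <- outer(outer((cv - cc)^2, (cv - cc)^2, "+"), (cv - cc)^2, "+")
  lab <- array(as.integer(d2 <= 100), c(n, n, n))
  l <- label_map(lab, spacing = c(2, 2, 2))
  v0 <- label_volume_ml(l, 1L)
  lf <- resample_isotropic(l, 1)
  expect_identical(sort(unique(as.vector(lf$labels))), c(0L, 1L))
  v1 <- label_volume_ml(lf, 1L)
  expect_lt(abs(v1 - v0) / v0, 0.05)
})

test_that("resampled masks converge to the analytic ellipsoid volume", {
  semi <- c(9, 7, 8)
  vol_true <- 4 / 3 * pi * prod(semi) / 1000
  err_at <- function(mm) {
    n <- ceiling(24 / mm)
    cv <- (seq_len(n) - 0.5) * mm
    q <- outer(outer(((cv - 12) / semi[1])^2, ((cv - 12) / semi[2])^2, "+"),
               ((cv - 12) / semi[3])^2, "+")
    l <- label_map(array(as.integer(q <= 1), rep(n, 3)), rep(mm, 3))
    abs(label_volume_ml(l, 1L) - vol_true) / vol_true
  }
  expect_lt(err_at(1), err_at(2.5))
  expect_lt(err_at(1), 0.02)
})

test_that("label resampling back to a reference grid inverts cleanly", {
  ph <- generate_phantom(coarse_spec(seed = 4))
  iso <- resample_isotropic(ph$labels, 2)
  back <- resample_to_grid(iso, dim(ph$labels$labels), ph$labels$spacing)
  expect_identical(dim(back$labels), dim(ph$labels$labels))
  expect_gt(dice(back, ph$labels, class_index = 1L), 0.9)
})
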