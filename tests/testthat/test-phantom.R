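test_that("identical specs give bit-identical phantoms", {
  a <- generate_phantom(coarse_spec(seed = 5))
  b <- generate_phantom(coarse_spec(seed = 5))
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$labels$labels, b$labels$labels)
  expect_identical(a$truth$volumes_ml, b$truth$volumes_ml)
  c <- generate_phantom(coarse_spec(seed = 6))
  expect_false(identical(a$volume$voxels, c$volume$voxels))
})

test_that("noiseless phantom intensities equal the nominal class values", {
  ph <- generate_phantom(coarse_spec(seed = 2, noise_sigma = 0,
                                     bias_field_amp = 0))
  nominal <- c(0.2, 0.55, 0.4, 0.5, 1.0)
  expect_equal(max(abs(ph$volume$voxels - nominal[ph$labels$labels + 1L])),
               0)
})

test_that("labels partition the grid and volumes add up", {
  ph <- generate_phantom(phantom_spec(seed = 3))
  counts <- tabulate(ph$labels$labels + 1L, nbins = 5L)
  expect_identical(sum(counts), length(ph$labels$labels))
  total_ml <- sum(vapply(0:4, function(k) label_volume_ml(ph$labels, k),
                         numeric(1)))
  expect_equal(total_ml,
               prod(dim(ph$labels$labels)) * voxel_volume_mm3(ph$labels) /
                 1000)
  # analytic truth is also a partition of the grid
  expect_equal(sum(ph$truth$volumes_ml), total_ml, tolerance = 1e-9)
  expect_true(all(ph$truth$volumes_ml >= 0))
})

test_that("voxelized fetal volume matches the analytic truth within 3%", {
  for (fs in c(0.85, 1.0, 1.25)) {
    ph <- generate_phantom(phantom_spec(seed = 11, fetal_scale = fs))
    vm <- label_volume_ml(ph$labels, 1L)
    tr <- ph$truth$volumes_ml[["fetus"]]
    expect_lt(abs(vm - tr) / tr, 0.03)
  }
})

test_that("discretized fetal volume converges with finer spacing", {
  err_at <- function(mm) {
    shape <- ceiling(c(86.4, 78.4, 100) / mm)
    ph <- generate_phantom(phantom_spec(seed = 1, grid_shape = shape,
                                        spacing = rep(mm, 3)))
    vm <- label_volume_ml(ph$labels, 1L)
    tr <- ph$truth$volumes_ml[["fetus"]]
    abs(vm - tr) / tr
  }
  expect_lt(err_at(1), err_at(2.5))
})

test_that("fetal weight truth is density times analytic volume", {
  ph <- generate_phantom(coarse_spec(seed = 9, fetal_scale = 1.1))
  expect_equal(ph$truth$fetal_weight_g,
               1.04 * ph$truth$volumes_ml[["fetus"]])
})

test_that("oversized fetus triggers a geometry error", {
  expect_error(generate_phantom(coarse_spec(seed = 1, fetal_scale = 1.5)),
               "contained")
  expect_error(phantom_spec(fetal_scale = 2), "0.5, 1.5")
})

test_that("phantom specs serialize to text and back", {
  sp <- coarse_spec(seed = 12, fetal_scale = 1.2, noise_sigma = 0.01)
  f <- tempfile(fileext = ".cfg")
  write_phantom_spec(sp, f)
  sp2 <- read_phantom_spec(f)
  expect_equal(sp2[names(sp)], sp[names(sp)],
               ignore_attr = TRUE)
  unlink(f)
})

test_that("steady flow phantom stores the closed-form Poiseuille flow", {
  f <- generate_flow_phantom(radius_mm = 4, v_max_cm_s = 20, n_phases = 3,
                             noise_sigma = 0)
  expect_equal(f$truth_flow_ml_min, 20 * pi * 0.4^2 / 2 * 60)
  # all phases identical in steady noiseless mode
  expect_equal(f$velocity_maps[, , 1], f$velocity_maps[, , 3])
  expect_error(generate_flow_phantom(v_max_cm_s = 200), "VENC")
  expect_error(generate_flow_phantom(radius_mm = -1))
})

test_that("pulsatile mean peak velocity is exactly 0.75 v_max", {
  f <- generate_flow_phantom(v_max_cm_s = 40, n_phases = 16,
                             mode = "pulsatile", noise_sigma = 0)
  # pixel centres never hit the exact vessel axis, so compare peak
  # velocities per phase relative to the cycle maximum (sin = 1 at k = 4)
  peaks <- apply(f$velocity_maps, 3, max)
  expect_equal(mean(peaks) / max(peaks), 0.75, tolerance = 1e-12)
  expect_equal(f$truth_flow_ml_min, 30 * pi * 0.4^2 / 2 * 60)
})

test_that("integrated phantom flow converges to truth as pixels shrink", {
  rel_err <- function(px) {
    f <- generate_flow_phantom(radius_mm = 4, v_max_cm_s = 25,
                               pixel_mm = px, n_phases = 1,
                               noise_sigma = 0)
    abs(flow_ml_per_min(f)$flow_ml_min - f$truth_flow_ml_min) /
      f$truth_flow_ml_min
  }
  expect_lt(rel_err(1.4), 0.05)
  expect_lt(rel_err(0.35), rel_err(1.4))
})
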