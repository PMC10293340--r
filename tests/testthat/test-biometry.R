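test_that("Hadlock intercepts match the published regression constants", {
  w1 <- suppressWarnings(hadlock_weight(1, biometry_set(AC = 0, FL = 0)))
  expect_equal(suppressWarnings(log10(hadlock_weight(
    1, biometry_set(AC = 0, FL = 0))$grams)), 1.304)
  expect_equal(suppressWarnings(log10(hadlock_weight(
    4, biometry_set(AC = 0, FL = 0, HC = 0, BPD = 0))$grams)), 1.3596)
  expect_identical(w1$source, "hadlock_1")
})

test_that("each formula reproduces an independent evaluation of its printed expression", {
  expect_equal(hadlock_weight(1, biometry_set(AC = 32, FL = 6.5))$grams,
               10^(1.304 + 0.05281 * 32 + 0.1938 * 6.5 - 0.004 * 32 * 6.5))
  set.seed(31)
  for (i in 1:25) {
    AC <- runif(1, 15, 45); FL <- runif(1, 2, 9)
    HC <- runif(1, 15, 40); BPD <- runif(1, 4, 12)
    b <- biometry_set(HC = HC, BPD = BPD, AC = AC, FL = FL)
    oracle <- c(
      10^(1.304 + 0.05281 * AC + 0.1938 * FL - 0.004 * AC * FL),
      10^(1.335 - 0.0034 * AC * FL + 0.0316 * BPD + 0.0457 * AC +
            0.1623 * FL),
      10^(1.326 - 0.00326 * AC * FL + 0.0107 * HC + 0.0438 * AC +
            0.158 * FL),
      10^(1.3596 - 0.00386 * AC * FL + 0.0064 * HC + 0.00061 * BPD * AC +
            0.0424 * AC + 0.174 * FL))
    for (f in 1:4) {
      got <- hadlock_weight(f, b)$grams
      expect_lt(abs(got - oracle[f]) / oracle[f], 1e-9)
    }
  }
})

test_that("missing or invalid biometry is rejected, out-of-range warns", {
  expect_error(hadlock_weight(2, biometry_set(AC = 30, FL = 6)), "BPD")
  expect_error(hadlock_weight(3, biometry_set(AC = 30, FL = 6)), "HC")
  expect_error(hadlock_weight(5, biometry_set(AC = 30, FL = 6)), "formula")
  expect_error(biometry_set(AC = -3), "non-negative")
  expect_warning(hadlock_weight(1, biometry_set(AC = 10, FL = 6)),
                 "physiological range")
  expect_silent(hadlock_weight(1, biometry_set(AC = 30, FL = 6)))
})

test_that("formulas are strictly increasing over the physiological grid", {
  acs <- seq(15, 45, by = 1.5); fls <- seq(2, 9, by = 0.5)
  hcs <- seq(15, 40, by = 2.5); bpds <- seq(4, 12, by = 1)
  g <- expand.grid(AC = acs, FL = fls, HC = hcs, BPD = bpds)
  L <- list(
    `1` = function(d) 1.304 + 0.05281 * d$AC + 0.1938 * d$FL -
      0.004 * d$AC * d$FL,
    `2` = function(d) 1.335 - 0.0034 * d$AC * d$FL + 0.0316 * d$BPD +
      0.0457 * d$AC + 0.1623 * d$FL,
    `3` = function(d) 1.326 - 0.00326 * d$AC * d$FL + 0.0107 * d$HC +
      0.0438 * d$AC + 0.158 * d$FL,
    `4` = function(d) 1.3596 - 0.00386 * d$AC * d$FL + 0.0064 * d$HC +
      0.00061 * d$BPD * d$AC + 0.0424 * d$AC + 0.174 * d$FL)
  eps <- 1e-3
  for (f in 1:4) {
    base_val <- L[[f]](g)
    for (var in c("AC", "FL", "HC", "BPD")) {
      g2 <- g
      g2[[var]] <- g2[[var]] + eps
      # formulas 1-3 ignore some measurements; their derivative is 0 there
      uses <- var %in% switch(f, c("AC", "FL"), c("AC", "FL", "BPD"),
                              c("AC", "FL", "HC"),
                              c("AC", "FL", "HC", "BPD"))
      if (uses) expect_true(all(L[[f]](g2) > base_val))
    }
  }
})

test_that("Ramanujan perimeter is exact for circles and near-exact otherwise", {
  r <- 3.7
  expect_equal(ramanujan_perimeter(r, r), 2 * pi * r)
  # numerical quadrature oracle for semi-axes 5 and 4
  a <- 5; b <- 4
  arc <- integrate(function(t) sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2),
                   0, 2 * pi, rel.tol = 1e-12)$value
  expect_lt(abs(ramanujan_perimeter(a, b) - arc) / arc, 1e-4)
})

test_that("phantom biometry follows the analytic geometry", {
  sp <- phantom_spec(femur_length_mm = 60, fetal_scale = 1)
  b <- phantom_biometry(sp)
  expect_equal(b$FL, 6.0)
  expect_equal(b$BPD, 2 * min(sp$head_axes[1:2]) / 10)
  expect_equal(b$HC,
               ramanujan_perimeter(sp$head_axes[1], sp$head_axes[2]) / 10)
  # everything scales linearly with fetal_scale
  b2 <- phantom_biometry(phantom_spec(femur_length_mm = 60,
                                      fetal_scale = 1.2))
  expect_equal(b2$FL / b$FL, 1.2)
  expect_equal(b2$AC / b$AC, 1.2)
})

test_that("Hadlock and density weights rank identically across fetal size", {
  scales <- seq(0.7, 1.3, by = 0.1)
  dens <- numeric(0); had <- matrix(0, length(scales), 4)
  for (i in seq_along(scales)) {
    sp <- phantom_spec(seed = 1, fetal_scale = scales[i])
    vols <- fetalvol:::phantom_truth_volumes(sp)
    dens[i] <- weight_from_volume(vols[["fetus"]])$grams
    bio <- phantom_biometry(sp)
    for (f in 1:4)
      had[i, f] <- suppressWarnings(hadlock_weight(f, bio)$grams)
  }
  for (f in 1:4)
    expect_equal(cor(dens, had[, f], method = "spearman"), 1)
})
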