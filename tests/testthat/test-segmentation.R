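test_that("fold assignment reproduces the 15/5 split arithmetic", {
  folds <- make_folds(1:20, 4, seed = 3)
  expect_length(folds, 4)
  for (f in folds) {
    expect_length(f$train, 15)
    expect_length(f$val, 5)
    expect_length(intersect(f$train, f$val), 0)
  }
  vals <- sort(unlist(lapply(folds, `[[`, "val")))
  expect_identical(vals, 1:20)  # each id validates exactly once
  expect_identical(make_folds(1:20, 4, seed = 3), folds)
  expect_false(identical(make_folds(1:20, 4, seed = 4), folds))
  singleton <- make_folds(1:5, 5, seed = 1)
  expect_true(all(vapply(singleton, function(f) length(f$val),
                         integer(1)) == 1L))
  expect_error(make_folds(1:3, 4), "exceeds")
  expect_error(make_folds(1:10, 1), "at least 2")
})

test_that("slice extraction and restacking are inverse for every axis", {
  set.seed(61)
  v <- volume_image(array(rnorm(10 * 12 * 14), c(10, 12, 14)), rep(1, 3))
  for (ax in 0:2) {
    sl <- extract_slices(v, ax)
    expect_length(sl, dim(v$voxels)[ax + 1])
    expect_identical(restack_slices(sl, ax), v$voxels)
  }
  sl2 <- extract_slices(v, 2)
  expect_identical(dim(sl2[[1]]), c(10L, 12L))
  expect_error(extract_slices(v, 3), "axis")
})

test_that("untrained network output is a per-voxel distribution", {
  cfg <- tiny_net(seed = 5)
  set.seed(cfg$seed)
  model <- structure(list(params = fetalvol:::unet_init_params(cfg),
                          config = cfg), class = "unet_model")
  set.seed(62)
  v <- volume_image(array(rnorm(9 * 10 * 11), c(9, 10, 11)), rep(3, 3))
  for (ax in 0:2) {
    p <- predict_plane(model, v, ax)
    expect_identical(dim(p$probs), c(dim(v$voxels), cfg$n_classes))
    sums <- apply(p$probs, 1:3, sum)
    expect_lt(max(abs(sums - 1)), 1e-6)
  }
  expect_error(predict_plane(model, v, 5), "axis")
})

test_that("constant input gives identical per-slice outputs", {
  cfg <- tiny_net(seed = 6)
  set.seed(cfg$seed)
  model <- structure(list(params = fetalvol:::unet_init_params(cfg),
                          config = cfg), class = "unet_model")
  v <- volume_image(array(0.7, c(8, 8, 6)), rep(3, 3))
  p <- predict_plane(model, v, 2)
  for (i in 2:6)
    expect_equal(p$probs[, , i, ], p$probs[, , 1, ])
})

test_that("vote fusion equals the brute-force rule on all 125 vote patterns", {
  pat <- expand.grid(a1 = 1:5, a2 = 1:5, a3 = 1:5)
  dims <- c(25, 5, 1)
  p1 <- probs_with_argmax(pat$a1, dims, seed = 1)
  p2 <- probs_with_argmax(pat$a2, dims, seed = 2)
  p3 <- probs_with_argmax(pat$a3, dims, seed = 3)
  fused <- fuse_votes(p1, p2, p3)
  P <- lapply(list(p1, p2, p3), function(p) matrix(p, ncol = 5))
  oracle <- integer(125)
  for (i in 1:125) {
    votes <- c(which.max(P[[1]][i, ]), which.max(P[[2]][i, ]),
               which.max(P[[3]][i, ]))
    cnt <- tabulate(votes, 5)
    if (max(cnt) >= 2) {
      oracle[i] <- which.max(cnt)
    } else {
      s <- P[[1]][i, ] + P[[2]][i, ] + P[[3]][i, ]
      cand <- sort(votes)
      oracle[i] <- cand[which.max(s[cand])]
    }
  }
  expect_identical(as.vector(fused$labels), oracle - 1L)
})

test_that("unanimous votes win regardless of probabilities", {
  set.seed(63)
  for (rep in 1:5) {
    am <- sample(1:5, 60, TRUE)
    dims <- c(5, 4, 3)
    p1 <- probs_with_argmax(am, dims, seed = rep)
    p2 <- probs_with_argmax(am, dims, seed = rep + 10)
    p3 <- probs_with_argmax(am, dims, seed = rep + 20)
    fused <- fuse_votes(p1, p2, p3)
    expect_identical(as.vector(fused$labels), am - 1L)
  }
  expect_error(fuse_votes(probs_with_argmax(1, c(1, 1, 1)),
                          probs_with_argmax(1, c(2, 1, 1)),
                          probs_with_argmax(1, c(1, 1, 1))),
               "shape mismatch")
})

test_that("majority beats a dissenting plane", {
  # votes (fetus, fetus, fluid) must yield fetus
  p1 <- probs_with_argmax(2, c(1, 1, 1), seed = 1)  # fetus
  p2 <- probs_with_argmax(2, c(1, 1, 1), seed = 2)  # fetus
  p3 <- probs_with_argmax(5, c(1, 1, 1), seed = 3)  # fluid
  expect_identical(as.vector(fuse_votes(p1, p2, p3)$labels), 1L)
})

test_that("analytic gradients agree with finite differences", {
  cfg <- net_config(depth = 2, base_channels = 4, n_classes = 3,
                    class_weights = c(1, 1, 2))
  set.seed(64)
  params <- fetalvol:::unet_init_params(cfg)
  x <- matrix(rnorm(64), 8, 8)
  y <- matrix(sample(0:2, 64, TRUE), 8, 8)
  storage.mode(y) <- "integer"
  g <- fetalvol:::cpp_unet_grad(params, x, y, cfg$depth, cfg$class_weights)
  h <- 1e-5
  for (li in c(1, 5, 9, length(params) - 1)) {
    for (rep in 1:3) {
      i <- sample(length(params[[li]]), 1)
      pp <- params; pp[[li]][i] <- pp[[li]][i] + h
      pm <- params; pm[[li]][i] <- pm[[li]][i] - h
      fd <- (fetalvol:::cpp_unet_loss(pp, x, y, cfg$depth,
                                      cfg$class_weights) -
             fetalvol:::cpp_unet_loss(pm, x, y, cfg$depth,
                                      cfg$class_weights)) / (2 * h)
      an <- g$grads[[li]][i]
      expect_lt(abs(fd - an) / max(1e-6, abs(fd) + abs(an)), 1e-5)
    }
  }
})

test_that("training is deterministic and improves on its first epoch", {
  ds <- coarse_dataset(4, seed = 100)
  folds <- make_folds(1:4, 2, seed = 1)
  cv1 <- train_unet(tiny_net(seed = 2, epochs = 3), ds, folds = folds)
  cv2 <- train_unet(tiny_net(seed = 2, epochs = 3), ds, folds = folds)
  expect_identical(cv1$metrics, cv2$metrics)
  expect_equal(cv1$models[[1]]$params, cv2$models[[1]]$params)
  tr <- cv1$metrics[cv1$metrics$split == "train", ]
  for (f in unique(tr$fold)) {
    losses <- tr$loss[tr$fold == f][order(tr$epoch[tr$fold == f])]
    expect_lte(min(losses), losses[1])  # best-so-far no worse than epoch 1
  }
  # no fold leakage: metrics reference exactly the assigned folds
  expect_identical(sort(unique(cv1$metrics$fold)), c(1L, 2L))
  for (f in folds) expect_length(intersect(f$train, f$val), 0)
})

test_that("training validates its inputs", {
  expect_error(train_unet(tiny_net(), list()), "empty")
  expect_error(train_unet(tiny_net(), list(list(volume = 1, labels = 2))),
               "volume_image")
})

test_that("largest-component postprocessing removes stray fetal voxels", {
  m <- array(FALSE, c(8, 8, 8))
  m[2:5, 2:5, 2:5] <- TRUE    # main blob
  m[8, 8, 8] <- TRUE          # spurious disconnected voxel
  keep <- fetalvol:::largest_component_mask(m)
  expect_true(all(keep[2:5, 2:5, 2:5]))
  expect_false(keep[8, 8, 8])
  expect_equal(sum(keep), 64)
  # diagonal touch counts as connected (26-connectivity)
  m2 <- array(FALSE, c(4, 4, 4))
  m2[1, 1, 1] <- TRUE; m2[2, 2, 2] <- TRUE
  expect_equal(sum(fetalvol:::largest_component_mask(m2)), 2)
})

test_that("model checkpoints embed the configuration and round-trip", {
  cfg <- tiny_net(seed = 9)
  set.seed(cfg$seed)
  model <- structure(list(params = fetalvol:::unet_init_params(cfg),
                          config = cfg), class = "unet_model")
  f <- tempfile(fileext = ".rds")
  save_model(model, f)
  m2 <- load_model(f)
  expect_equal(m2$params, model$params)
  expect_equal(m2$config, model$config)
  unlink(f)
})

test_that("segment_volume returns labels on the native grid", {
  ds <- coarse_dataset(3, seed = 200)
  model <- train_unet(tiny_net(seed = 3, epochs = 3), ds)
  ph <- generate_phantom(coarse_spec(seed = 204))
  seg <- segment_volume(model, ph$volume)
  expect_s3_class(seg, "label_map")
  expect_identical(dim(seg$labels), dim(ph$volume$voxels))
  expect_equal(seg$spacing, ph$volume$spacing)
  both <- segment_volume(model, ph$volume, return_planes = TRUE)
  expect_length(both$planes, 3)
  expect_identical(dim(both$planes[[1]]$labels), dim(ph$volume$voxels))
})

test_that("tri-planar voting holds its own against the best single plane", {
  pipe <- trained_pipeline()
  fused_d <- numeric(0); best_plane_d <- numeric(0)
  for (j in seq_along(pipe$test_ids)) {
    truth <- pipe$cohort[[pipe$test_ids[j]]]$labels
    fused_d[j] <- dice(pipe$segs[[j]]$fused, truth, class_index = 1L)
    best_plane_d[j] <- max(vapply(pipe$segs[[j]]$planes, function(p)
      dice(p, truth, class_index = 1L), numeric(1)))
  }
  expect_gte(mean(fused_d), mean(best_plane_d) - 0.02)
})
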