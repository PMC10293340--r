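# Tri-planar (2.5D) segmentation: one small 2D U-net applied slice-by-slice
# along the three orthogonal axes of an isotropically resampled volume, the
# three per-voxel predictions fused by majority voting.

#' Network and training configuration
#'
#' Hyperparameters of the 2D U-net and its training loop. The network itself
#' is deliberately small (depth 3, 8 base channels by default): the smallest
#' net that segments the synthetic phantoms well on a single CPU. One shared
#' net serves all three slicing directions; training pools slices from all
#' axes.
#'
#' @param depth Number of resolution levels (encoder levels), >= 1.
#' @param base_channels Channels at the finest level (doubled per level).
#' @param n_classes Number of output classes (5 for the fetal label model).
#' @param epochs Training epochs.
#' @param learning_rate Adam learning rate.
#' @param batch_size Slices per Adam update.
#' @param seed Seed for weight init, slice sampling, and augmentation.
#' @param iso_mm Isotropic working resolution (mm) used before slicing.
#' @param slices_per_volume Random slices drawn per volume per epoch,
#'   pooled across the three axes.
#' @param class_weights Per-class cross-entropy weights; the default
#'   upweights only the thin umbilical cord, which plain cross-entropy
#'   would otherwise ignore. Upweighting large classes shifts their
#'   decision boundary outward and biases segmented volumes.
#' @param augment Random in-plane flips during training.
#' @return An object of class `net_config`.
#' @export
net_config <- function(depth = 3L, base_channels = 8L, n_classes = 5L,
                       epochs = 12L, learning_rate = 3e-3, batch_size = 4L,
                       seed = 1L, iso_mm = 1.5, slices_per_volume = 24L,
                       class_weights = c(1, 1, 1, 2, 1),
                       augment = FALSE) {
  stopifnot(depth >= 1, base_channels >= 4, n_classes >= 2,
            epochs >= 1, learning_rate > 0, batch_size >= 1,
            iso_mm > 0, slices_per_volume >= 1,
            length(class_weights) == n_classes, all(class_weights > 0))
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 n_classes = as.integer(n_classes),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), iso_mm = iso_mm,
                 slices_per_volume = as.integer(slices_per_volume),
                 class_weights = as.numeric(class_weights),
                 augment = isTRUE(augment)),
            class = "net_config")
}

# Canonical conv-unit sequence; must match the C++ forward pass exactly.
unet_layer_spec <- function(depth, base, n_classes) {
  ch <- base * 2^(seq_len(depth) - 1)
  cin <- integer(0); cout <- integer(0); k <- integer(0)
  for (i in seq_len(depth)) {
    cin <- c(cin, if (i == 1) 1L else ch[i - 1], ch[i])
    cout <- c(cout, ch[i], ch[i])
    k <- c(k, 9L, 9L)
  }
  for (i in rev(seq_len(depth - 1))) {
    cin <- c(cin, ch[i + 1], 2L * ch[i], ch[i])
    cout <- c(cout, ch[i], ch[i], ch[i])
    k <- c(k, 9L, 9L, 9L)
  }
  cin <- c(cin, ch[1]); cout <- c(cout, n_classes); k <- c(k, 1L)
  data.frame(cin = cin, cout = cout, k = k)
}

# He-normal initialization in the canonical flat order W1, b1, W2, b2, ...
unet_init_params <- function(config) {
  spec <- unet_layer_spec(config$depth, config$base_channels,
                          config$n_classes)
  params <- vector("list", 2L * nrow(spec))
  for (i in seq_len(nrow(spec))) {
    fan_in <- spec$cin[i] * spec$k[i]
    params[[2 * i - 1]] <- matrix(
      rnorm(spec$cout[i] * fan_in, 0, sqrt(2 / fan_in)),
      nrow = spec$cout[i])
    params[[2 * i]] <- numeric(spec$cout[i])
  }
  params
}

zero_like <- function(params) {
  lapply(params, function(p) if (is.matrix(p)) p * 0 else p * 0)
}

#' k-fold cross-validation assignment
#'
#' Shuffles the case ids once (deterministically for a given seed) and
#' splits them into `k` validation sets as equal-sized as possible; each id
#' appears in exactly one validation set, and each fold trains on the
#' remainder. With 20 cases and `k = 4` every fold has 15 training and 5
#' validation cases.
#'
#' @param ids Vector of case identifiers.
#' @param k Number of folds (>= 2, <= number of ids).
#' @param seed Shuffle seed.
#' @return A `fold_assignment`: list of `k` elements, each with `train` and
#'   `val` id vectors.
#' @export
make_folds <- function(ids, k, seed = 1L) {
  k <- as.integer(k)
  if (k < 2) stop("`k` must be at least 2")
  if (k > length(ids)) stop("`k` exceeds the number of ids")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  perm <- sample(ids)
  sizes <- rep(length(ids) %/% k, k)
  extra <- length(ids) %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  grp <- rep(seq_len(k), times = sizes)
  folds <- lapply(seq_len(k), function(i)
    list(train = perm[grp != i], val = perm[grp == i]))
  structure(folds, class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  for (i in seq_along(x))
    cat(sprintf("fold %d: %d train / %d val\n", i, length(x[[i]]$train),
                length(x[[i]]$val)))
  invisible(x)
}

#' Extract the 2D slices of a volume along one axis
#'
#' @param v A [volume_image()] or [label_map()] (assumed isotropic for
#'   network use).
#' @param axis Slicing axis, 0, 1, or 2 (0-based, matching voxel axes).
#' @return List of 2D matrices, one per grid position along `axis`;
#'   restacking with [restack_slices()] reproduces the volume exactly.
#' @export
extract_slices <- function(v, axis) {
  arr <- if (inherits(v, "volume_image")) v$voxels
  else if (inherits(v, "label_map")) v$labels
  else if (is.array(v) && length(dim(v)) == 3L) v
  else stop("`v` must be a volume_image, label_map, or 3D array")
  if (!axis %in% 0:2) stop("`axis` must be 0, 1, or 2")
  ax <- axis + 1L
  lapply(seq_len(dim(arr)[ax]), function(i)
    switch(ax, arr[i, , ], arr[, i, ], arr[, , i]))
}

#' Restack slices into a 3D array
#'
#' Inverse of [extract_slices()].
#'
#' @param slices List of equal-shaped 2D matrices.
#' @param axis Axis (0-based) the slices were taken along.
#' @return 3D array.
#' @export
restack_slices <- function(slices, axis) {
  if (!axis %in% 0:2) stop("`axis` must be 0, 1, or 2")
  ax <- axis + 1L
  d2 <- dim(slices[[1]])
  d <- switch(ax, c(length(slices), d2), c(d2[1], length(slices), d2[2]),
              c(d2, length(slices)))
  out <- array(slices[[1]][1] * 0, dim = d)
  for (i in seq_along(slices)) {
    switch(ax,
           out[i, , ] <- slices[[i]],
           out[, i, ] <- slices[[i]],
           out[, , i] <- slices[[i]])
  }
  out
}

pad_multiple <- function(x, m) {
  d <- dim(x)
  dp <- ceiling(d / m) * m
  if (all(dp == d)) return(x)
  out <- matrix(0, dp[1], dp[2])
  out[seq_len(d[1]), seq_len(d[2])] <- x
  out
}

predict_slice_probs <- function(model, x) {
  m <- 2^(model$config$depth - 1)
  d <- dim(x)
  probs <- cpp_unet_predict(model$params, pad_multiple(x, m),
                            model$config$depth)
  probs[seq_len(d[1]), seq_len(d[2]), , drop = FALSE]
}

#' Per-voxel class probabilities from one slicing direction
#'
#' Runs the 2D network over every slice of the volume along one axis and
#' assembles the per-slice softmax outputs into a per-voxel class
#' distribution. Slices whose shape is not a multiple of the network stride
#' are zero-padded symmetrically in effect (pad-then-crop), never rejected.
#'
#' @param model A trained `unet_model` (see [train_unet()]).
#' @param v An isotropically resampled [volume_image()].
#' @param axis Slicing axis 0, 1, or 2.
#' @return A [class_probabilities()] with the volume's spatial shape.
#' @export
predict_plane <- function(model, v, axis) {
  stopifnot(inherits(model, "unet_model"))
  if (!axis %in% 0:2) stop("`axis` must be 0, 1, or 2")
  arr <- v$voxels
  d <- dim(arr)
  K <- model$config$n_classes
  out <- array(NA_real_, dim = c(d, K))
  ax <- axis + 1L
  for (i in seq_len(d[ax])) {
    x <- switch(ax, arr[i, , ], arr[, i, ], arr[, , i])
    p <- predict_slice_probs(model, x)
    switch(ax,
           out[i, , , ] <- p,
           out[, i, , ] <- p,
           out[, , i, ] <- p)
  }
  class_probabilities(out)
}

#' Fuse three directional predictions by voxel-wise voting
#'
#' Each slicing direction casts one hard vote per voxel (its argmax class);
#' a majority of at least two votes wins. A three-way tie is broken by the
#' largest sum of the three directions' probabilities over the tied classes,
#' and any remaining tie by the lowest class index, making the rule fully
#' deterministic.
#'
#' @param p_ax,p_sag,p_cor [class_probabilities()] of identical shape from
#'   the three slicing directions.
#' @param spacing Voxel spacing (mm) for the resulting label map.
#' @param class_names Class alphabet of the output.
#' @return A [label_map()].
#' @export
fuse_votes <- function(p_ax, p_sag, p_cor, spacing = c(1, 1, 1),
                       class_names = fetal_classes()) {
  ps <- list(p_ax, p_sag, p_cor)
  arrs <- lapply(ps, function(p) {
    if (inherits(p, "class_probabilities")) p$probs else p
  })
  d <- dim(arrs[[1]])
  if (!identical(dim(arrs[[2]]), d) || !identical(dim(arrs[[3]]), d))
    stop("shape mismatch between directional predictions")
  K <- d[4]
  N <- prod(d[1:3])
  P <- lapply(arrs, function(a) matrix(a, ncol = K))
  votes <- vapply(P, function(p) max.col(p, ties.method = "first"),
                  integer(N))
  if (!is.matrix(votes)) votes <- matrix(votes, nrow = N)
  cnt <- matrix(0L, N, K)
  for (j in 1:3) {
    idx <- cbind(seq_len(N), votes[, j])
    cnt[idx] <- cnt[idx] + 1L
  }
  winner <- max.col(cnt, ties.method = "first")
  top <- cnt[cbind(seq_len(N), winner)]
  split3 <- which(top == 1L)
  if (length(split3)) {
    S <- P[[1]] + P[[2]] + P[[3]]
    a <- votes[split3, 1]; b <- votes[split3, 2]; c3 <- votes[split3, 3]
    lo <- pmin(a, b, c3)
    hi <- pmax(a, b, c3)
    mid <- a + b + c3 - lo - hi
    vals <- cbind(S[cbind(split3, lo)], S[cbind(split3, mid)],
                  S[cbind(split3, hi)])
    pick <- max.col(vals, ties.method = "first")
    cand <- cbind(lo, mid, hi)
    winner[split3] <- cand[cbind(seq_along(split3), pick)]
  }
  labels <- array(winner - 1L, dim = d[1:3])
  label_map(labels, spacing, class_names = class_names)
}

sample_training_slices <- function(prep, ids, config) {
  m <- 2^(config$depth - 1)
  xs <- list(); ys <- list()
  for (id in ids) {
    vol <- prep[[id]]$vol$voxels
    lab <- prep[[id]]$lab$labels
    d <- dim(vol)
    for (s in seq_len(config$slices_per_volume)) {
      ax <- sample.int(3L, 1L)
      i <- sample.int(d[ax], 1L)
      x <- switch(ax, vol[i, , ], vol[, i, ], vol[, , i])
      y <- switch(ax, lab[i, , ], lab[, i, ], lab[, , i])
      if (config$augment) {
        if (runif(1) < 0.5) { x <- x[rev(seq_len(nrow(x))), ]
                              y <- y[rev(seq_len(nrow(y))), ] }
        if (runif(1) < 0.5) { x <- x[, rev(seq_len(ncol(x)))]
                              y <- y[, rev(seq_len(ncol(y)))] }
      }
      xs[[length(xs) + 1L]] <- pad_multiple(x, m)
      yp <- pad_multiple(y, m)
      storage.mode(yp) <- "integer"
      ys[[length(ys) + 1L]] <- yp
    }
  }
  ord <- sample.int(length(xs))
  list(xs = xs[ord], ys = ys[ord])
}

eval_metrics_row <- function(model, xs, ys, fold, epoch, split) {
  ev <- cpp_unet_eval(model$params, xs, ys, model$config$depth,
                      model$config$class_weights)
  denom <- ev$n_pred + ev$n_true
  dice_k <- ifelse(denom == 0, 1, 2 * ev$intersection / pmax(denom, 1))
  row <- data.frame(fold = fold, epoch = epoch, split = split,
                    loss = mean(ev$losses))
  for (i in seq_along(dice_k))
    row[[paste0("dice_", fetal_classes()[i])]] <- dice_k[i]
  row
}

train_one_model <- function(config, prep, train_ids, val_ids, fold_id,
                            verbose) {
  set.seed(config$seed + 1000L * fold_id)
  params <- unet_init_params(config)
  m_st <- zero_like(params)
  v_st <- zero_like(params)
  t <- 0L
  model <- structure(list(params = params, config = config),
                     class = "unet_model")
  val_set <- NULL
  if (length(val_ids)) {
    sv <- sample_training_slices(prep, val_ids, config)
    val_set <- sv
  }
  metrics <- list()
  for (epoch in seq_len(config$epochs)) {
    tr <- sample_training_slices(prep, train_ids, config)
    res <- cpp_unet_train(model$params, m_st, v_st, t, tr$xs, tr$ys,
                          config$depth, config$learning_rate, 0.9, 0.999,
                          1e-8, config$batch_size, config$class_weights)
    model$params <- res$params
    m_st <- res$m
    v_st <- res$v
    t <- res$t
    metrics[[length(metrics) + 1L]] <-
      data.frame(fold = fold_id, epoch = epoch, split = "train",
                 loss = mean(res$losses))
    if (!is.null(val_set)) {
      row <- eval_metrics_row(model, val_set$xs, val_set$ys, fold_id,
                              epoch, "val")
      metrics[[length(metrics) + 1L]] <- row
      if (verbose)
        message(sprintf("fold %d epoch %d: train loss %.4f, val loss %.4f",
                        fold_id, epoch, mean(res$losses), row$loss))
    } else if (verbose) {
      message(sprintf("fold %d epoch %d: train loss %.4f", fold_id, epoch,
                      mean(res$losses)))
    }
  }
  list(model = model, metrics = metrics)
}

merge_metric_rows <- function(rows) {
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (cn in setdiff(cols, names(r))) r[[cn]] <- NA_real_
    r[cols]
  })
  do.call(rbind, rows)
}

#' Train the tri-planar U-net
#'
#' Trains the shared 2D network on slices pooled from all three axes of the
#' isotropically resampled training volumes, with per-epoch loss logging.
#' With a [make_folds()] assignment, one model is trained per fold and
#' validation loss and per-class Dice are logged on that fold's held-out
#' cases only; with `folds = NULL` a single model is trained on all cases.
#' Fully deterministic for a given configuration seed.
#'
#' @param config A [net_config()].
#' @param dataset List of cases, each a list with elements `volume`
#'   ([volume_image()]) and `labels` ([label_map()]).
#' @param folds Optional [make_folds()] assignment over
#'   `seq_along(dataset)`.
#' @param verbose Print per-epoch progress.
#' @return With folds: a `unet_cv` (list `models`, one `unet_model` per
#'   fold, and `metrics`, a long data frame with columns fold, epoch, split,
#'   loss, and per-class Dice on validation rows). Without: a single
#'   `unet_model` carrying its training `metrics` as attribute.
#' @export
train_unet <- function(config, dataset, folds = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "net_config"))
  if (!length(dataset)) stop("empty dataset")
  for (cs in dataset)
    if (!inherits(cs$volume, "volume_image") ||
        !inherits(cs$labels, "label_map"))
      stop("each case needs a `volume` (volume_image) and `labels` (label_map)")
  prep <- lapply(dataset, function(cs)
    list(vol = resample_isotropic(cs$volume, config$iso_mm),
         lab = resample_isotropic(cs$labels, config$iso_mm)))
  if (is.null(folds)) {
    fit <- train_one_model(config, prep, seq_along(dataset), integer(0),
                           0L, verbose)
    model <- fit$model
    attr(model, "metrics") <- merge_metric_rows(fit$metrics)
    return(model)
  }
  stopifnot(inherits(folds, "fold_assignment"))
  models <- list()
  rows <- list()
  for (fi in seq_along(folds)) {
    if (length(folds[[fi]]$train) < 2)
      stop("fold ", fi, " has fewer than 2 training cases")
    fit <- train_one_model(config, prep, folds[[fi]]$train,
                           folds[[fi]]$val, fi, verbose)
    models[[fi]] <- fit$model
    rows <- c(rows, fit$metrics)
  }
  structure(list(models = models, metrics = merge_metric_rows(rows),
                 folds = folds), class = "unet_cv")
}

#' Save / load a trained model
#'
#' Checkpoints are RDS files (R's standard serialized form) embedding the
#' network configuration alongside the weights.
#'
#' @param model A `unet_model`.
#' @param path Checkpoint path (`.rds`).
#' @return `load_model` returns the `unet_model`; `save_model` returns
#'   `path` invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "unet_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "unet_model"))
  model
}

largest_component_mask <- function(mask) {
  keep <- cpp_largest_component(as.logical(mask), dim(mask))
  array(keep, dim = dim(mask))
}

#' Segment a volume end-to-end
#'
#' The full automatic chain: resample to the isotropic working grid, predict
#' along the three orthogonal slicing directions, fuse by voxel-wise voting,
#' resample the labels back to the input grid (nearest-neighbour), and
#' optionally keep only the largest 26-connected component of the fetus
#' class (stray fetal islands are relabelled to background).
#'
#' @param model A trained `unet_model`.
#' @param v A [volume_image()] on its native (possibly anisotropic) grid.
#' @param postprocess Apply the largest-component rule to the fetus class.
#' @param return_planes Also return the three single-direction label maps
#'   (argmax per direction, resampled back, no postprocessing), for
#'   comparing fused versus per-plane performance.
#' @return A [label_map()] on the input grid, or (with `return_planes`) a
#'   list with elements `fused` and `planes`.
#' @export
segment_volume <- function(model, v, postprocess = TRUE,
                           return_planes = FALSE) {
  stopifnot(inherits(model, "unet_model"), inherits(v, "volume_image"))
  iso <- resample_isotropic(v, model$config$iso_mm)
  p <- lapply(0:2, function(ax) predict_plane(model, iso, ax))
  fused <- fuse_votes(p[[1]], p[[2]], p[[3]], spacing = iso$spacing)
  out <- resample_to_grid(fused, dim(v$voxels), v$spacing)
  if (postprocess) {
    fet <- out$labels == CLASS_FETUS
    if (any(fet)) {
      keep <- largest_component_mask(fet)
      out$labels[fet & !keep] <- CLASS_BACKGROUND
    }
  }
  if (!return_planes) return(out)
  planes <- lapply(p, function(pp) {
    d <- dim(pp$probs)
    lab <- array(max.col(matrix(pp$probs, ncol = d[4]),
                         ties.method = "first") - 1L, dim = d[1:3])
    resample_to_grid(label_map(lab, iso$spacing), dim(v$voxels), v$spacing)
  })
  list(fused = out, planes = planes)
}
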