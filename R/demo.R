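# End-to-end demonstration: phantom cohort -> cross-validated training ->
# tri-planar segmentation -> volume/weight -> Hadlock comparison ->
# Bland-Altman agreement -> flow indexing.

#' Configuration of the end-to-end demonstration run
#'
#' @param seed Root seed; every stage derives its own stream from it.
#' @param n_phantoms Cohort size (default 28).
#' @param n_trainval Cases used for training and validation (default 20,
#'   echoing a 20-train/validation + remainder-test design); the rest are
#'   held out for testing.
#' @param folds Cross-validation folds over the train/validation cases.
#' @param out_dir Output directory (created if missing).
#' @param net A [net_config()]; its seed is overridden by `seed`.
#' @param phantom_args Named list of [phantom_spec()] overrides applied to
#'   every case (e.g. `noise_sigma`).
#' @param scale_range Range of `fetal_scale` sampled across the cohort,
#'   emulating a span of fetal sizes.
#' @param dice_threshold,volume_error_threshold Acceptance bounds the
#'   summary checks on the test cases: mean fetal Dice at least
#'   `dice_threshold` and every per-case relative volume error within
#'   `volume_error_threshold`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_phantoms = 28L, n_trainval = 20L,
                       folds = 4L, out_dir = tempfile("fetalvol_demo_"),
                       net = net_config(), phantom_args = list(),
                       scale_range = c(0.85, 1.25),
                       dice_threshold = 0.85,
                       volume_error_threshold = 0.10) {
  n_phantoms <- as.integer(n_phantoms)
  n_trainval <- as.integer(n_trainval)
  folds <- as.integer(folds)
  if (n_trainval >= n_phantoms)
    stop("`n_trainval` must leave at least one test case")
  if (folds < 2) stop("`folds` must be at least 2")
  if (folds > n_trainval)
    stop("`folds` exceeds the number of train/validation cases")
  structure(list(seed = as.integer(seed), n_phantoms = n_phantoms,
                 n_trainval = n_trainval, folds = folds, out_dir = out_dir,
                 net = net, phantom_args = phantom_args,
                 scale_range = scale_range,
                 dice_threshold = dice_threshold,
                 volume_error_threshold = volume_error_threshold),
            class = "run_config")
}

#' Generate a deterministic phantom cohort
#'
#' One phantom per case, with `fetal_scale` spread uniformly (seeded) over
#' `scale_range` to emulate a cohort spanning a range of fetal sizes.
#'
#' @param n Number of cases.
#' @param seed Root seed.
#' @param scale_range Range of `fetal_scale`.
#' @param phantom_args Named [phantom_spec()] overrides.
#' @return List of phantoms as returned by [generate_phantom()].
#' @export
generate_cohort <- function(n, seed = 1L, scale_range = c(0.85, 1.25),
                            phantom_args = list()) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  scales <- runif(n, scale_range[1], scale_range[2])
  lapply(seq_len(n), function(i) {
    args <- c(list(seed = seed + i, fetal_scale = scales[i]), phantom_args)
    sp <- do.call(phantom_spec, args)
    ph <- generate_phantom(sp)
    attr(ph, "spec") <- sp
    ph
  })
}

stage_msg <- function(verbose, stage, t0) {
  if (verbose)
    message(sprintf("[%s] done in %.1f s", stage,
                    as.numeric(Sys.time()) - t0))
}

#' Run the end-to-end demonstration
#'
#' Executes the whole pipeline on synthetic data and writes every
#' intermediate product under `config$out_dir`: phantoms (NIfTI + truth
#' CSV), fold assignments, per-fold checkpoints and training metrics,
#' test-set segmentations, quantification and agreement CSVs, a flow CSV,
#' and a plain-text summary. The fold model with the lowest final
#' validation loss segments the held-out test cases. Deterministic for a
#' given seed.
#'
#' @param config A [run_config()].
#' @param verbose Log per-stage progress and wall time.
#' @return Invisibly, a list with the summary statistics, file paths, and a
#'   `passed` flag indicating whether the test-set thresholds were met.
#' @export
run_demo <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  for (d in file.path(out, c("phantoms", "models", "segmentations",
                             "reports")))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  if (verbose) message("seed: ", config$seed)

  t0 <- as.numeric(Sys.time())
  cohort <- generate_cohort(config$n_phantoms, seed = config$seed,
                            scale_range = config$scale_range,
                            phantom_args = config$phantom_args)
  for (i in seq_along(cohort)) {
    write_volume(cohort[[i]]$volume,
                 file.path(out, "phantoms", sprintf("case%02d.nii.gz", i)))
    write_labels(cohort[[i]]$labels,
                 file.path(out, "phantoms", sprintf("case%02d_gt.nii.gz", i)))
    write_phantom_truth(cohort[[i]]$truth,
                        file.path(out, "phantoms",
                                  sprintf("case%02d_truth.csv", i)))
  }
  stage_msg(verbose, "phantoms", t0)

  trainval_ids <- seq_len(config$n_trainval)
  test_ids <- setdiff(seq_len(config$n_phantoms), trainval_ids)
  folds <- make_folds(trainval_ids, config$folds, seed = config$seed)
  fold_df <- do.call(rbind, lapply(seq_along(folds), function(i)
    data.frame(fold = i, id = c(folds[[i]]$train, folds[[i]]$val),
               split = rep(c("train", "val"),
                           c(length(folds[[i]]$train),
                             length(folds[[i]]$val))))))
  write.csv(fold_df, file.path(out, "folds.csv"), row.names = FALSE)

  t0 <- as.numeric(Sys.time())
  net <- config$net
  net$seed <- config$seed
  dataset <- lapply(cohort[trainval_ids], function(p)
    list(volume = p$volume, labels = p$labels))
  cv <- train_unet(net, dataset, folds = folds, verbose = verbose)
  write.csv(cv$metrics, file.path(out, "models", "training_metrics.csv"),
            row.names = FALSE)
  for (i in seq_along(cv$models))
    save_model(cv$models[[i]],
               file.path(out, "models", sprintf("fold%d.rds", i)))
  final_val <- cv$metrics[cv$metrics$split == "val" &
                            cv$metrics$epoch == max(cv$metrics$epoch), ]
  best_fold <- final_val$fold[which.min(final_val$loss)]
  model <- cv$models[[best_fold]]
  stage_msg(verbose, "training", t0)

  t0 <- as.numeric(Sys.time())
  rows <- list()
  for (id in test_ids) {
    ph <- cohort[[id]]
    seg <- segment_volume(model, ph$volume)
    write_labels(seg, file.path(out, "segmentations",
                                sprintf("case%02d_seg.nii.gz", id)))
    vol_auto <- label_volume_ml(seg, CLASS_FETUS)
    vol_true <- ph$truth$volumes_ml[["fetus"]]
    w_auto <- weight_from_volume(vol_auto)
    rows[[length(rows) + 1L]] <- data.frame(
      id = id,
      dice_fetus = dice(seg$labels, ph$labels$labels,
                        class_index = CLASS_FETUS),
      volume_auto_ml = vol_auto, volume_true_ml = vol_true,
      rel_volume_error = (vol_auto - vol_true) / vol_true,
      weight_auto_g = w_auto$grams,
      weight_true_g = ph$truth$fetal_weight_g)
  }
  quant <- do.call(rbind, rows)
  write.csv(quant, file.path(out, "reports", "quantification.csv"),
            row.names = FALSE)
  stage_msg(verbose, "segmentation", t0)

  agree <- agreement_table(quant$volume_auto_ml, quant$volume_true_ml,
                           labels = quant$id)
  write_agreement_csv(agree, file.path(out, "reports", "agreement.csv"))
  report <- attr(agree, "report")

  # Hadlock comparison on the test cohort, using the analytic phantom
  # biometry.
  had <- do.call(rbind, lapply(test_ids, function(id) {
    sp <- attr(cohort[[id]], "spec")
    bio <- phantom_biometry(sp)
    data.frame(id = id,
               hadlock1_g = suppressWarnings(hadlock_weight(1, bio)$grams),
               hadlock2_g = suppressWarnings(hadlock_weight(2, bio)$grams),
               hadlock3_g = suppressWarnings(hadlock_weight(3, bio)$grams),
               hadlock4_g = suppressWarnings(hadlock_weight(4, bio)$grams))
  }))
  write.csv(had, file.path(out, "reports", "hadlock.csv"),
            row.names = FALSE)

  flow_rows <- do.call(rbind, lapply(seq_along(test_ids), function(j) {
    id <- test_ids[j]
    fp <- generate_flow_phantom(v_max_cm_s = 20 + 2 * j, mode = "pulsatile",
                                seed = config$seed + 500L + id)
    w <- weight_from_volume(quant$volume_auto_ml[j])
    fr <- flow_ml_per_min(fp, weight = if (w$grams > 0) w)
    data.frame(id = id, flow_ml_min = fr$flow_ml_min,
               truth_flow_ml_min = fp$truth_flow_ml_min,
               indexed_ml_min_kg = if (w$grams > 0) fr$indexed_ml_min_kg
               else NA_real_)
  }))
  write.csv(flow_rows, file.path(out, "reports", "flow.csv"),
            row.names = FALSE)

  mean_dice <- mean(quant$dice_fetus)
  max_err <- max(abs(quant$rel_volume_error))
  passed <- mean_dice >= config$dice_threshold &&
    max_err <= config$volume_error_threshold
  summary_lines <- c(
    sprintf("seed: %d", config$seed),
    sprintf("cohort: %d phantoms (%d train/val, %d test)",
            config$n_phantoms, config$n_trainval, length(test_ids)),
    sprintf("best fold by final validation loss: %d", best_fold),
    sprintf("test mean fetal Dice: %.4f (threshold %.2f)", mean_dice,
            config$dice_threshold),
    sprintf("test max |relative volume error|: %.4f (threshold %.2f)",
            max_err, config$volume_error_threshold),
    sprintf("volume agreement: bias %.3f ml, 95%% LoA [%.3f, %.3f] ml",
            report$bias, report$loa_low, report$loa_high),
    sprintf("thresholds met: %s", ifelse(passed, "yes", "no")))
  writeLines(summary_lines, file.path(out, "reports", "summary.txt"))
  if (verbose) message(paste(summary_lines, collapse = "\n"))

  invisible(list(out_dir = out, mean_dice = mean_dice,
                 max_rel_volume_error = max_err, agreement = report,
                 quantification = quant, flow = flow_rows, hadlock = had,
                 best_fold = best_fold, passed = passed))
}
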