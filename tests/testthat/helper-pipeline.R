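# The scaled-down end-to-end analog of the clinical validation: a fixed
# 28-phantom cohort (20 train/validation, 8 held-out test), one shared
# tri-planar model, and segmentations of the test cases. Trained once per
# test session and cached, because several test files assert different
# properties of the same run.

.pipeline_cache <- new.env(parent = emptyenv())

trained_pipeline <- function() {
  if (!is.null(.pipeline_cache$res)) return(.pipeline_cache$res)
  cohort <- generate_cohort(28, seed = 1)
  dataset <- lapply(cohort[1:20], function(p)
    list(volume = p$volume, labels = p$labels))
  model <- train_unet(net_config(seed = 1), dataset)
  test_ids <- 21:28
  segs <- lapply(test_ids, function(id)
    segment_volume(model, cohort[[id]]$volume, return_planes = TRUE))
  .pipeline_cache$res <- list(cohort = cohort, model = model,
                              test_ids = test_ids, segs = segs)
  .pipeline_cache$res
}
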