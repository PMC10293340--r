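#' Cardiac-phase-resolved velocity map series
#'
#' Container for phase-contrast flow data: one signed in-plane velocity map
#' (cm/s) per cardiac phase, the pixel area, the cardiac cycle duration, and
#' the velocity-encoding limit (VENC). Velocities must not exceed the VENC
#' in magnitude (aliasing is not modelled).
#'
#' @param velocity_maps 3D array (rows x cols x phases) or list of matrices
#'   of signed velocities in cm/s.
#' @param pixel_area_mm2 Pixel area in square millimetres.
#' @param rr_ms Cardiac cycle duration in milliseconds.
#' @param venc_cm_s Velocity-encoding limit in cm/s (default 150).
#' @param truth_flow_ml_min Optional analytic ground-truth mean flow
#'   (phantoms only).
#' @param roi Optional logical matrix marking the vessel lumen.
#' @return An object of class `flow_series`.
#' @export
flow_series <- function(velocity_maps, pixel_area_mm2, rr_ms,
                        venc_cm_s = 150, truth_flow_ml_min = NULL,
                        roi = NULL) {
  if (is.list(velocity_maps)) {
    stopifnot(length(velocity_maps) >= 1)
    velocity_maps <- array(unlist(velocity_maps),
                           dim = c(dim(velocity_maps[[1]]),
                                   length(velocity_maps)))
  }
  if (length(dim(velocity_maps)) == 2L)
    dim(velocity_maps) <- c(dim(velocity_maps), 1L)
  stopifnot(length(dim(velocity_maps)) == 3L, dim(velocity_maps)[3] >= 1,
            pixel_area_mm2 > 0, rr_ms > 0, venc_cm_s > 0)
  if (max(abs(velocity_maps)) > venc_cm_s + 1e-9)
    stop("velocities exceed the VENC of ", venc_cm_s, " cm/s")
  structure(list(velocity_maps = velocity_maps,
                 pixel_area_mm2 = pixel_area_mm2, rr_ms = rr_ms,
                 venc_cm_s = venc_cm_s,
                 truth_flow_ml_min = truth_flow_ml_min, roi = roi),
            class = "flow_series")
}

#' @export
print.flow_series <- function(x, ...) {
  d <- dim(x$velocity_maps)
  cat(sprintf("flow_series: %d x %d pixels, %d phases, RR %g ms, VENC %g cm/s\n",
              d[1], d[2], d[3], x$rr_ms, x$venc_cm_s))
  invisible(x)
}

#' Quantify blood flow over a vessel ROI
#'
#' Integrates the velocity map over the region of interest for every cardiac
#' phase and averages over the cycle (all phases weighted equally, the
#' retrospective cine convention). Instantaneous flow per phase is
#' `sum_roi(v_cm_s * pixel_area_mm2) * 0.01` ml/s; the cycle average times
#' 60 gives ml/min. Negative (reversed-flow) velocities subtract.
#'
#' @param f A [flow_series()].
#' @param roi Logical matrix matching the map shape; defaults to the series'
#'   own `roi` field when present.
#' @param weight Optional `weight_estimate` (see [weight_from_volume()],
#'   [hadlock_weight()]); when given, flow is also indexed to fetal weight.
#' @return A `flow_result`: list with `flow_ml_min` and, when `weight` is
#'   supplied, `indexed_ml_min_kg`.
#' @export
flow_ml_per_min <- function(f, roi = NULL, weight = NULL) {
  stopifnot(inherits(f, "flow_series"))
  if (is.null(roi)) roi <- f$roi
  if (is.null(roi)) stop("no ROI supplied and the series carries none")
  roi <- as.matrix(roi)
  d <- dim(f$velocity_maps)
  if (!identical(dim(roi), d[1:2]))
    stop("ROI shape ", paste(dim(roi), collapse = "x"),
         " does not match velocity maps ", paste(d[1:2], collapse = "x"))
  if (!any(roi)) stop("ROI is empty")
  per_phase <- apply(f$velocity_maps, 3, function(m) sum(m[roi]))
  flow <- mean(per_phase) * f$pixel_area_mm2 * 0.01 * 60
  res <- list(flow_ml_min = flow, indexed_ml_min_kg = NULL)
  if (!is.null(weight))
    res$indexed_ml_min_kg <- index_flow(flow, weight)
  structure(res, class = "flow_result")
}

#' @export
print.flow_result <- function(x, ...) {
  cat(sprintf("flow_result: %.1f ml/min", x$flow_ml_min))
  if (!is.null(x$indexed_ml_min_kg))
    cat(sprintf(" (%.1f ml/min/kg)", x$indexed_ml_min_kg))
  cat("\n")
  invisible(x)
}

#' Index blood flow to fetal weight
#'
#' Absolute flow depends on fetal size; dividing by weight (in kg) gives a
#' physiologically comparable quantity across fetuses.
#'
#' @param flow_ml_min Flow in ml/min.
#' @param weight A `weight_estimate` or weight in grams.
#' @return Indexed flow in ml/min/kg.
#' @export
index_flow <- function(flow_ml_min, weight) {
  grams <- if (inherits(weight, "weight_estimate")) weight$grams
  else as.numeric(weight)
  if (!is.finite(grams) || grams <= 0)
    stop("weight must be positive to index flow")
  flow_ml_min / (grams / 1000)
}

#' Write / read a flow series as NIfTI plus a CSV sidecar
#'
#' The velocity maps are stored as a 3D NIfTI (two spatial axes plus the
#' phase axis); acquisition metadata (`pixel_area_mm2`, `rr_ms`,
#' `venc_cm_s`) travels in a small CSV sidecar next to it.
#'
#' @param f A [flow_series()].
#' @param path Output NIfTI path; the sidecar gets extension `.csv`.
#' @return `read_flow_series` returns a [flow_series()];
#'   `write_flow_series` returns `path` invisibly.
#' @export
write_flow_series <- function(f, path) {
  stopifnot(inherits(f, "flow_series"))
  img <- RNifti::asNifti(f$velocity_maps)
  px <- sqrt(f$pixel_area_mm2)
  RNifti::pixdim(img) <- c(px, px, 1)
  RNifti::writeNifti(img, path, datatype = "float")
  side <- data.frame(pixel_area_mm2 = f$pixel_area_mm2, rr_ms = f$rr_ms,
                     venc_cm_s = f$venc_cm_s)
  write.csv(side, paste0(sub("\\.nii(\\.gz)?$", "", path), "_meta.csv"),
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_flow_series
#' @export
read_flow_series <- function(path) {
  img <- RNifti::readNifti(path)
  side <- read.csv(paste0(sub("\\.nii(\\.gz)?$", "", path), "_meta.csv"))
  flow_series(unclass(img)[, , , drop = FALSE],
              pixel_area_mm2 = side$pixel_area_mm2, rr_ms = side$rr_ms,
              venc_cm_s = side$venc_cm_s)
}
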