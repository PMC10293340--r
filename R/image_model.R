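#' 3D scalar image with voxel spacing
#'
#' The basic container for an MRI slab: a 3D numeric array plus the physical
#' voxel spacing in millimetres per axis. Only axis-aligned grids are
#' supported; world coordinates are cell-centred, voxel `(i,j,k)` (1-based)
#' sitting at `origin + (c(i,j,k) - 0.5) * spacing`.
#'
#' @param voxels 3D numeric array of intensities (arbitrary units).
#' @param spacing Numeric length-3, mm per axis; all strictly positive.
#' @param origin Numeric length-3, mm offset of the grid (default 0).
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(voxels, spacing, origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive values (mm)")
  structure(list(voxels = voxels, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "volume_image")
}

#' Integer label map on an image grid
#'
#' Voxel-wise tissue classification paired with a [volume_image()]. Labels
#' are integers `0..length(class_names)-1`; see [fetal_classes()] for the
#' fixed class order.
#'
#' @param labels 3D integer array of class indices.
#' @param spacing Numeric length-3, mm per axis.
#' @param class_names Ordered class names; defaults to [fetal_classes()].
#' @param origin Numeric length-3 mm offset.
#' @return An object of class `label_map`.
#' @export
label_map <- function(labels, spacing, class_names = fetal_classes(),
                      origin = c(0, 0, 0)) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array")
  storage.mode(labels) <- "integer"
  rng <- range(labels)
  if (rng[1] < 0L || rng[2] >= length(class_names))
    stop("labels outside 0..", length(class_names) - 1L)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 positive values (mm)")
  structure(list(labels = labels, spacing = spacing,
                 class_names = class_names, origin = as.numeric(origin)),
            class = "label_map")
}

#' Soft per-voxel class probabilities
#'
#' A 4D array (three spatial axes by classes) of class probabilities, the
#' soft output of one slicing direction of the network before vote fusion.
#' Each voxel's probabilities must sum to 1 within `1e-6`.
#'
#' @param probs 4D numeric array, last dimension indexing classes.
#' @return An object of class `class_probabilities`.
#' @export
class_probabilities <- function(probs) {
  if (!is.array(probs) || length(dim(probs)) != 4L)
    stop("`probs` must be a 4D array (x, y, z, class)")
  if (any(probs < -1e-9) || any(probs > 1 + 1e-9))
    stop("probabilities must lie in [0, 1]")
  s <- apply_class_sum(probs)
  if (max(abs(s - 1)) > 1e-6)
    stop("per-voxel probabilities must sum to 1 (max deviation ",
         format(max(abs(s - 1))), ")")
  structure(list(probs = probs), class = "class_probabilities")
}

apply_class_sum <- function(probs) {
  d <- dim(probs)
  rowSums(matrix(probs, ncol = d[4]))
}

#' Physical volume of one voxel
#'
#' @param x A `volume_image`, `label_map`, or numeric spacing vector.
#' @return Voxel volume in cubic millimetres.
#' @export
voxel_volume_mm3 <- function(x) {
  s <- if (is.numeric(x)) x else x$spacing
  prod(s)
}

#' @export
print.volume_image <- function(x, ...) {
  cat("volume_image:", paste(dim(x$voxels), collapse = " x "),
      "voxels @", paste(signif(x$spacing, 4), collapse = " x "), "mm\n")
  invisible(x)
}

#' @export
print.label_map <- function(x, ...) {
  cat("label_map:", paste(dim(x$labels), collapse = " x "),
      "voxels @", paste(signif(x$spacing, 4), collapse = " x "), "mm\n")
  tab <- tabulate(x$labels + 1L, nbins = length(x$class_names))
  cat(paste0("  ", format(x$class_names), ": ", tab, collapse = "\n"), "\n")
  invisible(x)
}

# ---- NIfTI I/O -------------------------------------------------------------

nifti_spacing <- function(img) {
  px <- RNifti::pixdim(img)
  as.numeric(px[seq_len(3)])
}

#' Read a 3D volume from a NIfTI-1 file
#'
#' @param path Path to a `.nii` or `.nii.gz` file holding a 3D scalar image.
#' @return A [volume_image()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected a 3D NIfTI image, got ", length(dim(img)), " dimensions")
  volume_image(unclass(img)[, , , drop = FALSE], nifti_spacing(img))
}

#' Write a volume to a NIfTI-1 file
#'
#' Intensities are stored as 32-bit float, the conventional NIfTI type for
#' scalar MRI data; round-trips are lossless to single precision.
#'
#' @param v A [volume_image()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "volume_image"))
  if (dir.exists(path)) stop("`path` is a directory: ", path)
  img <- RNifti::asNifti(v$voxels)
  RNifti::pixdim(img) <- v$spacing
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Read a label map from a NIfTI-1 file
#'
#' @param path Path to an integer-valued NIfTI file.
#' @param class_names Class alphabet; defaults to [fetal_classes()].
#' @return A [label_map()].
#' @export
read_labels <- function(path, class_names = fetal_classes()) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected a 3D NIfTI label image")
  arr <- unclass(img)[, , , drop = FALSE]
  if (max(abs(arr - round(arr))) > 1e-6)
    stop("label file contains non-integer values")
  label_map(round(arr), nifti_spacing(img), class_names = class_names)
}

#' Write a label map to a NIfTI-1 file
#'
#' Labels are stored as unsigned 8-bit integers; round-trips are exact.
#'
#' @param l A [label_map()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_labels <- function(l, path) {
  stopifnot(inherits(l, "label_map"))
  if (dir.exists(path)) stop("`path` is a directory: ", path)
  img <- RNifti::asNifti(l$labels)
  RNifti::pixdim(img) <- l$spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

# ---- Resampling ------------------------------------------------------------

# Map target cell centres onto continuous (1-based) source indices for one
# axis, preserving physical extent.
axis_index <- function(n_new, new_mm, old_mm) {
  ((seq_len(n_new) - 0.5) * new_mm) / old_mm + 0.5
}

resample_core <- function(arr, spacing, target, mode) {
  d <- dim(arr)
  n_new <- pmax(1L, as.integer(round(d * spacing / target)))
  ux <- axis_index(n_new[1], target[1], spacing[1])
  uy <- axis_index(n_new[2], target[2], spacing[2])
  uz <- axis_index(n_new[3], target[3], spacing[3])
  if (mode == "nearest") {
    ix <- pmin(pmax(round(ux), 1L), d[1])
    iy <- pmin(pmax(round(uy), 1L), d[2])
    iz <- pmin(pmax(round(uz), 1L), d[3])
    out <- arr[ix, iy, iz, drop = FALSE]
    dim(out) <- n_new
    return(out)
  }
  # trilinear with edge clamping
  cl <- function(u, n) pmin(pmax(u, 1), n)
  ux <- cl(ux, d[1]); uy <- cl(uy, d[2]); uz <- cl(uz, d[3])
  x0 <- pmin(floor(ux), d[1] - 1L); x0 <- pmax(x0, 1L); fx <- ux - x0
  y0 <- pmin(floor(uy), d[2] - 1L); y0 <- pmax(y0, 1L); fy <- uy - y0
  z0 <- pmin(floor(uz), d[3] - 1L); z0 <- pmax(z0, 1L); fz <- uz - z0
  if (d[1] == 1L) { x0 <- rep(1L, n_new[1]); fx <- rep(0, n_new[1]) }
  if (d[2] == 1L) { y0 <- rep(1L, n_new[2]); fy <- rep(0, n_new[2]) }
  if (d[3] == 1L) { z0 <- rep(1L, n_new[3]); fz <- rep(0, n_new[3]) }
  g <- function(ix, iy, iz) arr[cbind(rep(ix, times = length(iy) * length(iz)),
                                      rep(rep(iy, each = length(ix)),
                                          times = length(iz)),
                                      rep(iz, each = length(ix) * length(iy)))]
  FX <- rep(fx, times = n_new[2] * n_new[3])
  FY <- rep(rep(fy, each = n_new[1]), times = n_new[3])
  FZ <- rep(fz, each = n_new[1] * n_new[2])
  x1 <- pmin(x0 + 1L, d[1]); y1 <- pmin(y0 + 1L, d[2]); z1 <- pmin(z0 + 1L, d[3])
  out <- g(x0, y0, z0) * (1 - FX) * (1 - FY) * (1 - FZ) +
         g(x1, y0, z0) * FX * (1 - FY) * (1 - FZ) +
         g(x0, y1, z0) * (1 - FX) * FY * (1 - FZ) +
         g(x1, y1, z0) * FX * FY * (1 - FZ) +
         g(x0, y0, z1) * (1 - FX) * (1 - FY) * FZ +
         g(x1, y0, z1) * FX * (1 - FY) * FZ +
         g(x0, y1, z1) * (1 - FX) * FY * FZ +
         g(x1, y1, z1) * FX * FY * FZ
  dim(out) <- n_new
  out
}

#' Resample a volume or label map onto an isotropic grid
#'
#' The acquired grid is anisotropic (typically 1.8 x 1.4 x 2.5 mm) while the
#' tri-planar network treats all three axes equivalently, so volumes are
#' resampled to a common isotropic spacing before slicing. Physical extent is
#' preserved to within one voxel per axis; label maps must use
#' `mode = "nearest"`, which preserves the label alphabet.
#'
#' @param v A [volume_image()] or [label_map()].
#' @param target_mm Positive isotropic target spacing in mm (default 1.5, near
#'   the finest acquired in-plane resolution).
#' @param mode `"linear"` (default for volumes) or `"nearest"` (forced for
#'   label maps).
#' @return Object of the same class as `v` on the isotropic grid.
#' @export
resample_isotropic <- function(v, target_mm = 1.5,
                               mode = c("linear", "nearest")) {
  if (!is.numeric(target_mm) || length(target_mm) != 1L || target_mm <= 0)
    stop("`target_mm` must be a single positive number")
  target <- rep(target_mm, 3)
  if (inherits(v, "label_map")) {
    out <- resample_core(v$labels, v$spacing, target, "nearest")
    return(label_map(out, target, class_names = v$class_names,
                     origin = v$origin))
  }
  mode <- match.arg(mode)
  stopifnot(inherits(v, "volume_image"))
  out <- resample_core(v$voxels, v$spacing, target, mode)
  volume_image(out, target, origin = v$origin)
}

#' Resample a label map onto a reference grid
#'
#' Nearest-neighbour mapping of labels onto another grid's shape and spacing,
#' used to carry a segmentation computed on the isotropic working grid back
#' to the native acquisition grid.
#'
#' @param l A [label_map()].
#' @param ref_shape Integer length-3 target grid shape.
#' @param ref_spacing Numeric length-3 target spacing (mm).
#' @return A [label_map()] on the reference grid.
#' @export
resample_to_grid <- function(l, ref_shape, ref_spacing) {
  stopifnot(inherits(l, "label_map"))
  d <- dim(l$labels)
  ix <- pmin(pmax(round(axis_index(ref_shape[1], ref_spacing[1], l$spacing[1])), 1L), d[1])
  iy <- pmin(pmax(round(axis_index(ref_shape[2], ref_spacing[2], l$spacing[2])), 1L), d[2])
  iz <- pmin(pmax(round(axis_index(ref_shape[3], ref_spacing[3], l$spacing[3])), 1L), d[3])
  out <- l$labels[ix, iy, iz, drop = FALSE]
  dim(out) <- as.integer(ref_shape)
  label_map(out, ref_spacing, class_names = l$class_names, origin = l$origin)
}
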