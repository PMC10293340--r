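#' Volume of one tissue class in a label map
#'
#' Counts voxels carrying the class label and multiplies by the physical
#' voxel volume.
#'
#' @param l A [label_map()].
#' @param class_index Integer class index (0-based, see [fetal_classes()]).
#' @return Volume in millilitres.
#' @export
label_volume_ml <- function(l, class_index) {
  stopifnot(inherits(l, "label_map"))
  class_index <- as.integer(class_index)
  if (length(class_index) != 1L || class_index < 0L ||
      class_index >= length(l$class_names))
    stop("unknown class index ", class_index)
  sum(l$labels == class_index) * voxel_volume_mm3(l) / 1000
}

#' Convert a segmented volume to fetal weight
#'
#' Weight in grams is volume in millilitres multiplied by the fetal tissue
#' density of 1.04 g/ml (see [fetal_density_g_ml()]).
#'
#' @param volume_ml Non-negative fetal volume (ml).
#' @return A `weight_estimate`: list with `grams` and `source = "mri_volume"`.
#' @export
weight_from_volume <- function(volume_ml) {
  if (!is.numeric(volume_ml) || length(volume_ml) != 1L ||
      !is.finite(volume_ml) || volume_ml < 0)
    stop("`volume_ml` must be a single non-negative number")
  structure(list(grams = fetal_density_g_ml() * volume_ml,
                 source = "mri_volume"),
            class = "weight_estimate")
}

#' @export
print.weight_estimate <- function(x, ...) {
  cat(sprintf("weight_estimate: %.1f g (%s)\n", x$grams, x$source))
  invisible(x)
}

as_class_mask <- function(x, class_index) {
  if (inherits(x, "label_map")) return(x$labels == class_index)
  if (is.logical(x)) return(x)
  if (is.array(x) || is.numeric(x)) {
    if (is.null(class_index)) stop("`class_index` required for label arrays")
    return(x == class_index)
  }
  stop("cannot interpret segmentation input of class ", class(x)[1])
}

#' Dice similarity coefficient
#'
#' Overlap between two segmentations of the same grid, `2|A n B| /
#' (|A| + |B|)`. When both sets are empty the coefficient is defined as 1
#' (perfect agreement on absence; the raw formula is 0/0).
#'
#' @param a,b [label_map()]s, label arrays, or logical masks on the same
#'   grid.
#' @param class_index Class evaluated when `a`/`b` are label maps or label
#'   arrays; ignored for logical masks.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b, class_index = NULL) {
  ma <- as_class_mask(a, class_index)
  mb <- as_class_mask(b, class_index)
  if (!identical(dim(ma), dim(mb)))
    stop("shape mismatch: ", paste(dim(ma), collapse = "x"), " vs ",
         paste(dim(mb), collapse = "x"))
  na <- sum(ma); nb <- sum(mb)
  if (na + nb == 0) return(1)
  2 * sum(ma & mb) / (na + nb)
}
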