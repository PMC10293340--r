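# Hadlock ultrasound biometry formulas, as printed in the clinical
# literature: log10(weight [g]) as a linear expression in HC, BPD, AC, FL,
# all in cm.

HADLOCK_RANGES <- list(AC = c(15, 45), FL = c(2, 9), HC = c(15, 40),
                       BPD = c(4, 12))

HADLOCK_REQUIRED <- list(`1` = c("AC", "FL"),
                         `2` = c("AC", "FL", "BPD"),
                         `3` = c("AC", "FL", "HC"),
                         `4` = c("AC", "FL", "HC", "BPD"))

#' Fetal biometry measurements
#'
#' Container for the four standard biometric measurements, in centimetres:
#' head circumference (HC), biparietal diameter (BPD), abdominal
#' circumference (AC), and femur length (FL). A measurement a chosen Hadlock
#' formula does not need may be left `NA`. Values outside the physiological
#' ranges (AC 15-45, FL 2-9, HC 15-40, BPD 4-12 cm) are allowed; the
#' formulas warn rather than fail there because they are known to be less
#' reliable for very small and very large fetuses.
#'
#' @param HC,BPD,AC,FL Measurements in cm (`NA` when absent).
#' @return An object of class `biometry_set`.
#' @export
biometry_set <- function(HC = NA_real_, BPD = NA_real_, AC = NA_real_,
                         FL = NA_real_) {
  vals <- c(HC = HC, BPD = BPD, AC = AC, FL = FL)
  for (k in names(vals)) {
    v <- vals[[k]]
    if (!is.na(v) && (!is.numeric(v) || v < 0))
      stop(k, " must be a non-negative measurement in cm")
  }
  structure(as.list(vals), class = "biometry_set")
}

#' @export
print.biometry_set <- function(x, ...) {
  cat("biometry_set (cm):",
      paste(names(x), vapply(x, function(v) format(v, digits = 4),
                             character(1)),
            sep = "=", collapse = "  "), "\n")
  invisible(x)
}

hadlock_log10 <- function(formula, HC, BPD, AC, FL) {
  switch(as.character(formula),
    `1` = 1.304 + 0.05281 * AC + 0.1938 * FL - 0.004 * AC * FL,
    `2` = 1.335 - 0.0034 * AC * FL + 0.0316 * BPD + 0.0457 * AC +
          0.1623 * FL,
    `3` = 1.326 - 0.00326 * AC * FL + 0.0107 * HC + 0.0438 * AC +
          0.158 * FL,
    `4` = 1.3596 - 0.00386 * AC * FL + 0.0064 * HC + 0.00061 * BPD * AC +
          0.0424 * AC + 0.174 * FL,
    stop("`formula` must be 1, 2, 3, or 4"))
}

#' Hadlock fetal weight estimation
#'
#' Evaluates one of Hadlock's four log-linear regression formulas for fetal
#' weight from biometry. Formula 1 uses AC and FL; formula 2 adds BPD;
#' formula 3 adds HC; formula 4 uses all four. Inputs are in cm, the result
#' in grams (`10^L` with `L` the fitted log10 weight).
#'
#' @param formula Integer 1-4 selecting the regression.
#' @param b A [biometry_set()] providing the required measurements.
#' @return A `weight_estimate` with `source = "hadlock_<formula>"`.
#' @export
#' @examples
#' hadlock_weight(1, biometry_set(AC = 32, FL = 6.5))
hadlock_weight <- function(formula, b) {
  stopifnot(inherits(b, "biometry_set"))
  formula <- as.integer(formula)
  if (!formula %in% 1:4) stop("`formula` must be 1, 2, 3, or 4")
  need <- HADLOCK_REQUIRED[[as.character(formula)]]
  for (k in need) {
    v <- b[[k]]
    if (is.na(v))
      stop("Hadlock ", formula, " requires ", k)
    if (v < 0) stop(k, " must be non-negative")
    r <- HADLOCK_RANGES[[k]]
    if (v < r[1] || v > r[2])
      warning(k, " = ", v, " cm is outside the physiological range [",
              r[1], ", ", r[2], "] cm; Hadlock formulas are less reliable ",
              "there", call. = FALSE)
  }
  L <- hadlock_log10(formula, HC = b$HC, BPD = b$BPD, AC = b$AC, FL = b$FL)
  structure(list(grams = 10^L, source = paste0("hadlock_", formula)),
            class = "weight_estimate")
}

#' Ramanujan approximation to an ellipse perimeter
#'
#' `pi (3(a+b) - sqrt((3a+b)(a+3b)))`; exact for circles and accurate to
#' better than 1e-4 relative error for moderate eccentricities.
#'
#' @param a,b Semi-axes (same units as the result).
#' @return Approximate perimeter.
#' @export
ramanujan_perimeter <- function(a, b) {
  pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
}

#' Analytic biometry of a phantom fetus
#'
#' Closed-form stand-ins for the manual measurements: BPD is the head's
#' minor axial diameter; HC and AC are Ramanujan perimeters of the head's
#' and trunk's axial (z-normal) cross-sections; FL is the femur segment
#' length. All scale with `fetal_scale` and are returned in cm.
#'
#' @param spec A [phantom_spec()].
#' @return A [biometry_set()].
#' @export
phantom_biometry <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  fs <- spec$fetal_scale
  hx <- spec$head_axes[1] * fs
  hy <- spec$head_axes[2] * fs
  tx <- spec$trunk_axes[1] * fs
  ty <- spec$trunk_axes[2] * fs
  biometry_set(
    HC = ramanujan_perimeter(hx, hy) / 10,
    BPD = 2 * min(hx, hy) / 10,
    AC = ramanujan_perimeter(tx, ty) / 10,
    FL = spec$femur_length_mm * fs / 10
  )
}
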