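# Synthetic gravid-uterus phantom.
#
# Geometry (all in mm, axis-aligned):
#   * uterus        : ellipsoid filling most of the grid; interior is
#                     amniotic fluid.
#   * placenta      : spherical-shell sector on the uterine wall, i.e. the
#                     region with 0.8 <= |q| <= 1 in normalized ellipsoid
#                     coordinates q = (p - centre)/semi_axes, restricted to a
#                     cone around +y.
#   * fetus         : trunk ellipsoid + coaxially overlapping head ellipsoid
#                     + four cylindrical limbs (two arms along x, two legs
#                     along z, one of which is the femur segment).
#   * umbilical cord: quadratic Bezier tube from the fetal trunk surface to
#                     the inner placental surface.
# Ground-truth volumes use closed forms for single solids and deterministic
# fine-grid numerical integration for the (small) pairwise overlaps, so the
# truth error is orders of magnitude below the voxelization tolerance that
# tests assert.

PHANTOM_INTENSITY <- c(background = 0.2, fetus = 0.55, placenta = 0.4,
                       umbilical_cord = 0.5, amniotic_fluid = 1.0)

#' Specification of a synthetic gravid-uterus phantom
#'
#' Defines the deterministic geometry and noise of one synthetic case.
#' Identical specs produce bit-identical phantoms. The default grid emulates
#' the acquired 3D bSSFP resolution (1.8 x 1.4 x 2.5 mm) on a miniaturized
#' uterus so that the full pipeline stays CPU-friendly.
#'
#' @param seed Integer seed driving noise and bias-field phases.
#' @param grid_shape Integer length-3 voxel counts.
#' @param spacing Numeric length-3 voxel spacing (mm).
#' @param fetal_scale Isotropic scale factor for all fetal solids, in
#'   `[0.5, 1.5]`; emulates a range of fetal sizes.
#' @param noise_sigma SD of additive Gaussian intensity noise (intensity
#'   units, class intensities being O(1)).
#' @param bias_field_amp Amplitude of the smooth multiplicative bias field
#'   (0.05 = +/-5 percent shading).
#' @param head_axes,trunk_axes Semi-axes (mm) of the head and trunk
#'   ellipsoids before scaling.
#' @param femur_length_mm Length (mm) of the femur limb segment before
#'   scaling.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(seed = 1L,
                         grid_shape = c(48L, 56L, 40L),
                         spacing = c(1.8, 1.4, 2.5),
                         fetal_scale = 1.0,
                         noise_sigma = 0.02,
                         bias_field_amp = 0.05,
                         head_axes = c(8.8, 7.7, 9.0),
                         trunk_axes = c(12.0, 10.5, 18.0),
                         femur_length_mm = 22.0) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L),
            length(spacing) == 3L, all(spacing > 0),
            length(head_axes) == 3L, all(head_axes > 0),
            length(trunk_axes) == 3L, all(trunk_axes > 0),
            femur_length_mm > 0, noise_sigma >= 0, bias_field_amp >= 0)
  if (fetal_scale < 0.5 || fetal_scale > 1.5)
    stop("`fetal_scale` must lie in [0.5, 1.5]")
  structure(list(seed = as.integer(seed), grid_shape = grid_shape,
                 spacing = as.numeric(spacing),
                 fetal_scale = fetal_scale, noise_sigma = noise_sigma,
                 bias_field_amp = bias_field_amp,
                 head_axes = as.numeric(head_axes),
                 trunk_axes = as.numeric(trunk_axes),
                 femur_length_mm = femur_length_mm),
            class = "phantom_spec")
}

# Fixed, spec-independent geometry constants (mm / radians).
PHANTOM_GEOM <- list(
  uterus_frac = c(0.44, 0.435, 0.46),  # semi-axes as fraction of extent
  placenta_inner = 0.8,                # inner shell radius in |q|
  placenta_half_angle = 55 * pi / 180, # cone half-angle around +y
  fetus_offset = c(0, -2, 2),          # fetus anchor relative to centre
  head_overlap = 4,                    # head/trunk coaxial overlap depth
  arm_radius = 3, arm_length = 18, arm_embed = 3, arm_z_offset = 8,
  leg_radius = 3.5, leg_length = 16, leg_embed = 3, leg_x_offset = 6,
  cord_radius = 2.5,
  cord_exit_dir = c(0, 0.93, 0.368),   # unit normal on trunk surface
  cord_target_dir = c(0.25, 0.899, 0.36),  # |q|-direction into the sector
  cord_bow = c(10, 2, -10)             # control-point offset (mm)
)

# Resolve spec -> explicit solids in world mm. Everything downstream (raster,
# truth, biometry) derives from this single description.
phantom_geometry <- function(spec) {
  g <- PHANTOM_GEOM
  extent <- spec$grid_shape * spec$spacing
  centre <- extent / 2
  U <- g$uterus_frac * extent
  fs <- spec$fetal_scale
  A <- centre + g$fetus_offset * fs

  trunk <- list(centre = A, semi = spec$trunk_axes * fs)
  head_off <- spec$trunk_axes[3] + spec$head_axes[3] - g$head_overlap
  head <- list(centre = A + c(0, 0, head_off * fs),
               semi = spec$head_axes * fs)

  # Arms along +/-x, starting arm_embed inside the trunk surface at height
  # arm_z_offset above the trunk centre.
  dz <- g$arm_z_offset
  half_x <- spec$trunk_axes[1] * sqrt(max(0, 1 - (dz / spec$trunk_axes[3])^2))
  arms <- lapply(c(1, -1), function(sgn) {
    x0 <- sgn * (half_x - g$arm_embed)
    list(axis = 1L, radius = g$arm_radius * fs,
         a0 = A + c(x0 * fs, 0, dz * fs),
         length = g$arm_length * fs, dir = sgn)
  })
  # Legs along -z, starting leg_embed inside the lower trunk surface at
  # +/- leg_x_offset; the -x leg is the femur segment.
  dxl <- g$leg_x_offset
  half_z <- spec$trunk_axes[3] * sqrt(max(0, 1 - (dxl / spec$trunk_axes[1])^2))
  make_leg <- function(sgn, len) {
    z0 <- -(half_z - g$leg_embed)
    list(axis = 3L, radius = g$leg_radius * fs,
         a0 = A + c(sgn * dxl * fs, 0, z0 * fs),
         length = len * fs, dir = -1)
  }
  femur <- make_leg(-1, spec$femur_length_mm)
  leg2 <- make_leg(1, g$leg_length)

  # Umbilical cord: quadratic Bezier from the trunk surface to the inner
  # placental surface.
  n0 <- g$cord_exit_dir / sqrt(sum(g$cord_exit_dir^2))
  p0 <- A + 0.98 * n0 * trunk$semi
  w <- g$cord_target_dir / sqrt(sum(g$cord_target_dir^2))
  p2 <- centre + g$placenta_inner * U * w
  p1 <- (p0 + p2) / 2 + g$cord_bow

  list(extent = extent, centre = centre, uterus = U,
       placenta_inner = g$placenta_inner,
       placenta_cos = cos(g$placenta_half_angle),
       trunk = trunk, head = head,
       limbs = list(arm_r = arms[[1]], arm_l = arms[[2]],
                    femur = femur, leg = leg2),
       cord = list(p0 = p0, p1 = p1, p2 = p2,
                   radius = g$cord_radius * fs))
}

# ---- solid predicates (vectorized over coordinate arrays) -----------------

inside_ellipsoid <- function(xv, yv, zv, centre, semi) {
  ax <- ((xv - centre[1]) / semi[1])^2
  ay <- ((yv - centre[2]) / semi[2])^2
  az <- ((zv - centre[3]) / semi[3])^2
  outer(outer(ax, ay, "+"), az, "+") <= 1
}

inside_cylinder <- function(xv, yv, zv, cyl) {
  a0 <- cyl$a0
  lo <- if (cyl$dir > 0) a0[cyl$axis] else a0[cyl$axis] - cyl$length
  hi <- if (cyl$dir > 0) a0[cyl$axis] + cyl$length else a0[cyl$axis]
  r2 <- cyl$radius^2
  if (cyl$axis == 1L) {
    xin <- xv >= lo & xv <= hi
    M <- outer((yv - a0[2])^2, (zv - a0[3])^2, "+") <= r2
    outer(xin, M, "&")
  } else if (cyl$axis == 3L) {
    M <- outer((xv - a0[1])^2, (yv - a0[2])^2, "+") <= r2
    outer(M, zv >= lo & zv <= hi, "&")
  } else {
    stop("unsupported cylinder axis")
  }
}

bezier_points <- function(cord, ts) {
  b <- function(t, i) (1 - t)^2 * cord$p0[i] + 2 * t * (1 - t) * cord$p1[i] +
    t^2 * cord$p2[i]
  cbind(b(ts, 1), b(ts, 2), b(ts, 3))
}

bezier_arclength <- function(cord) {
  dp <- function(t, i) 2 * (1 - t) * (cord$p1[i] - cord$p0[i]) +
    2 * t * (cord$p2[i] - cord$p1[i])
  integrate(function(t) sqrt(dp(t, 1)^2 + dp(t, 2)^2 + dp(t, 3)^2),
            0, 1, rel.tol = 1e-10)$value
}

# ---- overlap corrections ---------------------------------------------------

# Deterministic midpoint-grid volume of {A and B} over a bounding box.
overlap_volume <- function(in_a, in_b, lo, hi, n = 80L) {
  if (any(hi <= lo)) return(0)
  step <- (hi - lo) / n
  xv <- lo[1] + (seq_len(n) - 0.5) * step[1]
  yv <- lo[2] + (seq_len(n) - 0.5) * step[2]
  zv <- lo[3] + (seq_len(n) - 0.5) * step[3]
  m <- in_a(xv, yv, zv) & in_b(xv, yv, zv)
  mean(m) * prod(hi - lo)
}

ellipsoid_bbox <- function(e) list(lo = e$centre - e$semi, hi = e$centre + e$semi)

cylinder_bbox <- function(cyl) {
  a0 <- cyl$a0
  lo <- a0 - cyl$radius
  hi <- a0 + cyl$radius
  if (cyl$dir > 0) hi[cyl$axis] <- a0[cyl$axis] + cyl$length
  else lo[cyl$axis] <- a0[cyl$axis] - cyl$length
  list(lo = lo, hi = hi)
}

bbox_intersect <- function(a, b) list(lo = pmax(a$lo, b$lo), hi = pmin(a$hi, b$hi))

# Analytic (closed-form + fine-grid overlap) volumes in ml for every class.
phantom_truth_volumes <- function(spec) {
  geo <- phantom_geometry(spec)
  v_ell <- function(s) 4 / 3 * pi * prod(s)
  v_uterus <- v_ell(geo$uterus)
  v_placenta <- v_uterus * (1 - geo$placenta_inner^3) *
    (1 - geo$placenta_cos) / 2

  tr <- geo$trunk; hd <- geo$head
  in_trunk <- function(x, y, z) inside_ellipsoid(x, y, z, tr$centre, tr$semi)
  in_head <- function(x, y, z) inside_ellipsoid(x, y, z, hd$centre, hd$semi)
  bb <- bbox_intersect(ellipsoid_bbox(tr), ellipsoid_bbox(hd))
  v_head_trunk <- overlap_volume(in_trunk, in_head, bb$lo, bb$hi)

  v_limbs <- 0
  for (cyl in geo$limbs) {
    v_limbs <- v_limbs + pi * cyl$radius^2 * cyl$length
    bb <- bbox_intersect(ellipsoid_bbox(tr), cylinder_bbox(cyl))
    v_limbs <- v_limbs - overlap_volume(
      in_trunk, function(x, y, z) inside_cylinder(x, y, z, cyl),
      bb$lo, bb$hi)
  }
  v_fetus <- v_ell(tr$semi) + v_ell(hd$semi) - v_head_trunk + v_limbs
  v_cord <- pi * geo$cord$radius^2 * bezier_arclength(geo$cord)
  v_fluid <- v_uterus - v_placenta - v_fetus - v_cord
  v_total <- prod(geo$extent)
  vols <- c(background = v_total - v_uterus, fetus = v_fetus,
            placenta = v_placenta, umbilical_cord = v_cord,
            amniotic_fluid = v_fluid)
  vols / 1000
}

# Surface sampling of the fetal solids, used for containment checks.
fetus_surface_points <- function(geo, n = 24L) {
  th <- seq(0, pi, length.out = n)
  ph <- seq(0, 2 * pi, length.out = 2 * n)
  gr <- expand.grid(th = th, ph = ph)
  ell_pts <- function(e) {
    cbind(e$centre[1] + e$semi[1] * sin(gr$th) * cos(gr$ph),
          e$centre[2] + e$semi[2] * sin(gr$th) * sin(gr$ph),
          e$centre[3] + e$semi[3] * cos(gr$th))
  }
  cyl_pts <- function(cyl) {
    ts <- seq(0, 1, length.out = n)
    ang <- seq(0, 2 * pi, length.out = n)
    gc <- expand.grid(t = ts, a = ang)
    a0 <- cyl$a0
    axpos <- a0[cyl$axis] + cyl$dir * gc$t * cyl$length
    u <- cyl$radius * cos(gc$a)
    v <- cyl$radius * sin(gc$a)
    if (cyl$axis == 1L) cbind(axpos, a0[2] + u, a0[3] + v)
    else cbind(a0[1] + u, a0[2] + v, axpos)
  }
  pts <- rbind(ell_pts(geo$trunk), ell_pts(geo$head))
  for (cyl in geo$limbs) pts <- rbind(pts, cyl_pts(cyl))
  pts
}

#' Generate a synthetic gravid-uterus phantom
#'
#' Builds a 3D bSSFP-like volume, the matching five-class label map, and the
#' analytic ground truth (per-class volumes, biometry, density-based fetal
#' weight). Class intensities are fixed constants in fluid-brightest order
#' (fluid 1.0, fetus 0.55, cord 0.5, placenta 0.4, background 0.2); a smooth
#' multiplicative bias field and additive Gaussian noise are applied on top.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `volume` ([volume_image()]), `labels`
#'   ([label_map()]), and `truth` (class `phantom_truth`: per-class
#'   `volumes_ml`, analytic `biometry`, and `fetal_weight_g`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  geo <- phantom_geometry(spec)

  # Containment: every fetal solid must sit inside the uterus and clear of
  # the placental sector.
  pts <- fetus_surface_points(geo)
  q <- sweep(sweep(pts, 2, geo$centre, "-"), 2, geo$uterus, "/")
  qn <- sqrt(rowSums(q^2))
  if (any(qn > 1))
    stop("fetus is not contained in the uterus (max |q| = ",
         format(max(qn), digits = 4), "); reduce fetal_scale or geometry")
  in_sector <- qn >= geo$placenta_inner &
    (q[, 2] / pmax(qn, 1e-12)) >= geo$placenta_cos
  if (any(in_sector))
    stop("fetus intersects the placental sector")

  d <- spec$grid_shape
  xv <- (seq_len(d[1]) - 0.5) * spec$spacing[1]
  yv <- (seq_len(d[2]) - 0.5) * spec$spacing[2]
  zv <- (seq_len(d[3]) - 0.5) * spec$spacing[3]

  qx <- ((xv - geo$centre[1]) / geo$uterus[1])^2
  qy <- ((yv - geo$centre[2]) / geo$uterus[2])^2
  qz <- ((zv - geo$centre[3]) / geo$uterus[3])^2
  Q2 <- outer(outer(qx, qy, "+"), qz, "+")
  labels <- array(CLASS_BACKGROUND, dim = d)
  labels[Q2 <= 1] <- CLASS_FLUID

  qyv <- (yv - geo$centre[2]) / geo$uterus[2]
  QY <- qyv[slice.index(Q2, 2L)]
  Qn <- sqrt(Q2)
  placenta <- Q2 <= 1 & Qn >= geo$placenta_inner &
    (QY / pmax(Qn, 1e-12)) >= geo$placenta_cos
  labels[placenta] <- CLASS_PLACENTA

  # Cord: voxels within cord_radius of the Bezier centre line.
  cord <- geo$cord
  cpts <- bezier_points(cord, seq(0, 1, length.out = 200L))
  lo <- apply(cpts, 2, min) - cord$radius - 1
  hi <- apply(cpts, 2, max) + cord$radius + 1
  ix <- which(xv >= lo[1] & xv <= hi[1])
  iy <- which(yv >= lo[2] & yv <= hi[2])
  iz <- which(zv >= lo[3] & zv <= hi[3])
  if (length(ix) && length(iy) && length(iz)) {
    gx <- xv[ix]; gy <- yv[iy]; gz <- zv[iz]
    nb <- c(length(ix), length(iy), length(iz))
    d2 <- array(Inf, dim = nb)
    GX <- gx[slice.index(d2, 1L)]
    GY <- gy[slice.index(d2, 2L)]
    GZ <- gz[slice.index(d2, 3L)]
    for (k in seq_len(nrow(cpts))) {
      dk <- (GX - cpts[k, 1])^2 + (GY - cpts[k, 2])^2 + (GZ - cpts[k, 3])^2
      d2 <- pmin(d2, dk)
    }
    sub <- labels[ix, iy, iz, drop = FALSE]
    sub[d2 <= cord$radius^2] <- CLASS_CORD
    labels[ix, iy, iz] <- sub
  }

  fetus <- inside_ellipsoid(xv, yv, zv, geo$trunk$centre, geo$trunk$semi) |
    inside_ellipsoid(xv, yv, zv, geo$head$centre, geo$head$semi)
  for (cyl in geo$limbs) fetus <- fetus | inside_cylinder(xv, yv, zv, cyl)
  labels[fetus] <- CLASS_FETUS

  intens <- PHANTOM_INTENSITY[labels + 1L]
  dim(intens) <- d

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)
  if (spec$bias_field_amp > 0) {
    phase <- runif(3, 0, 2 * pi)
    bx <- cos(pi * xv / geo$extent[1] + phase[1])
    by <- cos(pi * yv / geo$extent[2] + phase[2])
    bz <- cos(pi * zv / geo$extent[3] + phase[3])
    bias <- 1 + spec$bias_field_amp * outer(outer(bx, by), bz)
    intens <- intens * bias
  } else {
    runif(3)  # keep the noise stream aligned across bias settings
  }
  if (spec$noise_sigma > 0)
    intens <- intens + rnorm(length(intens), 0, spec$noise_sigma)
  dim(intens) <- d

  truth_vols <- phantom_truth_volumes(spec)
  truth <- structure(list(
    volumes_ml = truth_vols,
    biometry = phantom_biometry(spec),
    fetal_weight_g = weight_from_volume(truth_vols[["fetus"]])$grams
  ), class = "phantom_truth")

  list(volume = volume_image(intens, spec$spacing),
       labels = label_map(labels, spec$spacing),
       truth = truth)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat("phantom_truth: fetal weight", round(x$fetal_weight_g, 1), "g\n")
  v <- x$volumes_ml
  cat(paste0("  ", format(names(v)), ": ", signif(v, 5), " ml",
             collapse = "\n"), "\n")
  invisible(x)
}

#' Serialize / restore a phantom spec as plain text
#'
#' Key=value text, one field per line; vectors comma-separated.
#'
#' @param spec A [phantom_spec()].
#' @param path File path.
#' @return `read_phantom_spec` returns a [phantom_spec()];
#'   `write_phantom_spec` returns `path` invisibly.
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  lines <- vapply(names(spec), function(k)
    paste0(k, "=", paste(spec[[k]], collapse = ",")), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- lapply(kv, function(p) as.numeric(strsplit(p[2], ",")[[1]]))
  names(vals) <- vapply(kv, `[[`, character(1), 1)
  do.call(phantom_spec, vals)
}

#' Write per-class ground-truth volumes as CSV
#'
#' @param truth A `phantom_truth` object.
#' @param path Output CSV path (columns `class`, `volume_ml`).
#' @return `path`, invisibly.
#' @export
write_phantom_truth <- function(truth, path) {
  df <- data.frame(class = names(truth$volumes_ml),
                   volume_ml = as.numeric(truth$volumes_ml))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# ---- flow phantom ----------------------------------------------------------

#' Generate a Poiseuille vessel flow phantom
#'
#' Produces a cardiac-phase-resolved series of in-plane velocity maps with a
#' parabolic (Poiseuille) profile `v(r) = v_peak(t) (1 - r^2/R^2)` inside a
#' circular vessel and zero outside. In `"steady"` mode the peak velocity is
#' constant at `v_max_cm_s`; in `"pulsatile"` mode it is modulated as
#' `v_max (0.75 + 0.25 sin(2 pi k/n))` over the cycle, whose exact time mean
#' is `0.75 v_max` for equally spaced phases. The analytic mean flow
#' `Q = mean_t[v_peak] * pi R^2 / 2` (ml/min) is stored as ground truth.
#'
#' @param radius_mm Vessel radius (mm).
#' @param v_max_cm_s Peak centreline velocity (cm/s); must not exceed `venc`.
#' @param n_phases Number of cardiac phases (>= 1).
#' @param pixel_mm In-plane pixel size (mm); default matches the acquired
#'   phase-contrast resolution.
#' @param rr_ms Cardiac cycle duration (ms); default ~110 bpm fetal rate.
#' @param seed Seed for the noise stream.
#' @param noise_sigma SD of additive velocity noise (cm/s).
#' @param mode `"steady"` or `"pulsatile"`.
#' @param venc_cm_s Velocity-encoding limit (cm/s); velocities are clipped to
#'   it and `v_max` beyond it is rejected (no aliasing model).
#' @return A [flow_series()] whose `roi` field holds the vessel-lumen mask
#'   and whose `truth_flow_ml_min` holds the analytic mean flow.
#' @export
generate_flow_phantom <- function(radius_mm = 4, v_max_cm_s = 27,
                                  n_phases = 20L, pixel_mm = 1.4,
                                  rr_ms = 545, seed = 1L, noise_sigma = 0,
                                  mode = c("steady", "pulsatile"),
                                  venc_cm_s = 150) {
  mode <- match.arg(mode)
  stopifnot(radius_mm > 0, pixel_mm > 0, rr_ms > 0, n_phases >= 1)
  if (v_max_cm_s <= 0) stop("`v_max_cm_s` must be positive")
  if (v_max_cm_s > venc_cm_s)
    stop("`v_max_cm_s` exceeds VENC (", venc_cm_s,
         " cm/s); aliasing is not modelled")
  half <- radius_mm + 3 * pixel_mm
  n <- 2L * ceiling(half / pixel_mm)
  cv <- (seq_len(n) - (n + 1) / 2) * pixel_mm
  R2 <- outer(cv^2, cv^2, "+")
  profile <- pmax(0, 1 - R2 / radius_mm^2)
  roi <- R2 <= radius_mm^2
  k <- seq_len(n_phases) - 1L
  vpeak <- if (mode == "steady") rep(v_max_cm_s, n_phases)
  else v_max_cm_s * (0.75 + 0.25 * sin(2 * pi * k / n_phases))

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  maps <- array(0, dim = c(n, n, n_phases))
  for (p in seq_len(n_phases)) {
    m <- vpeak[p] * profile
    if (noise_sigma > 0) m <- m + rnorm(length(m), 0, noise_sigma)
    maps[, , p] <- pmin(pmax(m, -venc_cm_s), venc_cm_s)
  }
  q_true <- mean(vpeak) * pi * (radius_mm / 10)^2 / 2 * 60  # ml/min
  flow_series(velocity_maps = maps, pixel_area_mm2 = pixel_mm^2,
              rr_ms = rr_ms, venc_cm_s = venc_cm_s,
              truth_flow_ml_min = q_true, roi = roi)
}
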