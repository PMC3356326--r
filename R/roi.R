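#' VOI masks and dose information
#'
#' `voi_mask()` wraps a 3D logical array aligned to a [dynamic_image()],
#' with provenance describing how it was derived.
#'
#' @param mask 3D logical array.
#' @param provenance Free-text description (seed geometry, threshold
#'   fraction, frame used).
#' @return An object of class `voi_mask`.
#' @export
voi_mask <- function(mask, provenance = "manual") {
  if (length(dim(mask)) != 3L) stop("`mask` must be a 3D array")
  structure(list(mask = array(as.logical(mask), dim(mask)),
                 provenance = provenance),
            class = "voi_mask")
}

#' @export
print.voi_mask <- function(x, ...) {
  cat(sprintf("<voi_mask> %d voxels [%s]\n", sum(x$mask), x$provenance))
  invisible(x)
}

#' @rdname voi_mask
#' @param dim_xyz Image dimensions.
#' @param center,radius Sphere center (1-based voxel indices) and radius
#'   in voxels, for a quick ellipsoid-style seed VOI.
#' @export
sphere_mask <- function(dim_xyz, center, radius) {
  m <- region_masks(structure(list(
    dim_xyz = as.integer(dim_xyz),
    regions = list(s = list(shape = "sphere", center = center,
                            radius = radius))), class = "phantom_spec"))$s
  voi_mask(m, sprintf("sphere c=(%s) r=%g",
                      paste(center, collapse = ","), radius))
}

check_alignment <- function(img, mask) {
  if (!inherits(img, "dynamic_image")) stop("`img` must be a `dynamic_image`")
  if (!inherits(mask, "voi_mask")) stop("`mask` must be a `voi_mask`")
  if (!identical(dim(img$data)[1:3], dim(mask$mask))) {
    stop("mask dimensions do not match image spatial dimensions")
  }
  invisible(TRUE)
}

#' Fractional-maximum voxel screen
#'
#' Refines a seed VOI by keeping only voxels whose value on a chosen
#' frame is at least `fraction` times the maximum value inside the seed
#' VOI on that frame. This is the standard screen against tumor
#' heterogeneity and irregular VOI placement; the reference frame
#' defaults to the last frame of the dynamic sequence.
#'
#' @param img A [dynamic_image()].
#' @param seed_voi A [voi_mask()] seed region.
#' @param fraction Threshold fraction in `[0, 1)`; default 0.30.
#' @param frame Frame index used for thresholding; default last frame.
#' @return A [voi_mask()].
#' @export
threshold_mask <- function(img, seed_voi, fraction = 0.30,
                           frame = n_frames(img$schedule)) {
  check_alignment(img, seed_voi)
  if (fraction < 0 || fraction >= 1) stop("`fraction` must be in [0, 1)")
  if (frame < 1 || frame > n_frames(img$schedule)) stop("invalid frame index")
  if (!any(seed_voi$mask)) stop("seed VOI is empty")
  vol <- array(img$data[, , , frame], dim(img$data)[1:3])
  peak <- max(vol[seed_voi$mask])
  keep <- seed_voi$mask & (vol >= fraction * peak)
  if (!any(keep)) {
    stop(sprintf("no voxels survive the %.0f%%-of-max screen on frame %d",
                 100 * fraction, frame))
  }
  voi_mask(keep, sprintf("%s | >=%.0f%% of max on frame %d",
                         seed_voi$provenance, 100 * fraction, frame))
}

#' Extract a mean TAC from a dynamic image
#'
#' Per-frame arithmetic mean over the masked voxels, in kBq/ml.
#'
#' @inheritParams threshold_mask
#' @param mask A non-empty [voi_mask()].
#' @return A [tac()] in kBq/ml.
#' @export
extract_tac <- function(img, mask) {
  check_alignment(img, mask)
  idx <- which(mask$mask)
  if (length(idx) == 0L) stop("mask is empty")
  nf <- n_frames(img$schedule)
  nvox <- prod(dim(img$data)[1:3])
  flat <- matrix(img$data, nrow = nvox, ncol = nf)
  tac(img$schedule, colMeans(flat[idx, , drop = FALSE]), "kBq/ml")
}

#' Injected dose and calibration
#'
#' @param dose_mbq Injected dose in MBq; the studies this package
#'   emulates inject ~3.7 MBq per mouse.
#' @param density_g_ml Tissue density, g/ml (default 1).
#' @param calibration Multiplicative factor converting image units to
#'   kBq/ml (default 1, i.e. images already calibrated).
#' @return An object of class `dose_info`.
#' @export
dose_info <- function(dose_mbq = 3.7, density_g_ml = 1, calibration = 1) {
  if (dose_mbq <= 0) stop("injected dose must be > 0")
  if (density_g_ml <= 0) stop("density must be > 0")
  structure(list(dose_mbq = dose_mbq, density_g_ml = density_g_ml,
                 calibration = calibration),
            class = "dose_info")
}

#' Convert a TAC to percent injected dose per gram
#'
#' `%ID/g = activity [kBq/g] / dose [kBq] * 100`, assuming the
#' configured tissue density (default 1 g/ml).
#'
#' @param x A [tac()] in kBq/ml.
#' @param dose A [dose_info()].
#' @return A [tac()] in %ID/g.
#' @export
to_percent_id_per_g <- function(x, dose) {
  if (!inherits(x, "pet_tac")) stop("`x` must be a `pet_tac`")
  if (!inherits(dose, "dose_info")) stop("`dose` must be a `dose_info`")
  if (x$units != "kBq/ml") stop("input TAC must be in kBq/ml")
  dose_kbq <- dose$dose_mbq * 1000
  tac(x$schedule,
      x$value * dose$calibration / dose_kbq * 100 / dose$density_g_ml,
      "%ID/g")
}

#' Image-derived input function from a blood-pool VOI
#'
#' Delineates the left-ventricle VOI on an early frame (by default the
#' second frame, the 0.5-min image, when the blood pool is hottest)
#' using the fractional-maximum screen, freezes that mask, and applies
#' it to every frame.
#'
#' @inheritParams threshold_mask
#' @param lv_seed A [voi_mask()] seeding the left ventricle.
#' @param frame Frame on which to delineate; default 2.
#' @param fraction Threshold fraction; default 0.30. Set to 0 to use the
#'   seed VOI unscreened.
#' @return A list with `tac` (a [tac()], the blood proxy for Cp) and
#'   `mask` (the frozen [voi_mask()]).
#' @export
image_derived_input <- function(img, lv_seed, frame = 2L, fraction = 0.30) {
  mask <- if (fraction > 0) {
    threshold_mask(img, lv_seed, fraction = fraction, frame = frame)
  } else {
    lv_seed
  }
  list(tac = extract_tac(img, mask), mask = mask)
}

#' Static uptake from the last frame
#'
#' Tissue uptake of the 60-min "static" image, defined as the masked
#' mean of the final dynamic frame converted to %ID/g.
#'
#' @inheritParams extract_tac
#' @param dose A [dose_info()].
#' @return A single %ID/g value.
#' @export
last_frame_uptake <- function(img, mask, dose) {
  full <- to_percent_id_per_g(extract_tac(img, mask), dose)
  full$value[n_frames(img$schedule)]
}
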