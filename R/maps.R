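#' Parametric maps from voxel-wise Logan analysis
#'
#' `map_vt()` applies plasma-input Logan graphical analysis to every
#' voxel TAC inside a body mask, producing a V_T image; `map_bp()` uses
#' the reference-tissue form and reports `slope - 1` (Bp_ND), clamped
#' below at -1 (DVR >= 0) to suppress pathological noise voxels. Both
#' use the same transformed coordinates and closed-form OLS as the
#' region-level fits, so a spatially uniform noise-free region yields
#' voxel values identical to the region-level slope. Voxels with fewer
#' than 3 usable late points (non-positive tissue values are dropped,
#' as in [logan_plasma()]) are flagged failed and given the fill value.
#'
#' @param img A [dynamic_image()].
#' @param input Plasma/blood [tac()] for `map_vt()`.
#' @param tstar Linearization time, minutes.
#' @param body_mask A [voi_mask()], or `NULL` to use voxels whose
#'   last-frame value is at least `body_fraction` of the image maximum.
#' @param body_fraction Fraction for the default body mask.
#' @param fill Value written to unfitted voxels.
#' @return An object of class `parametric_map`: `values` (3D array),
#'   `flags` (3D integer: 0 masked-out, 1 fitted, 2 failed),
#'   `parameter`, `tstar`, `fill`, `n_clamped` (Bp maps).
#' @export
map_vt <- function(img, input, tstar = 30, body_mask = NULL,
                   body_fraction = 0.01, fill = 0) {
  voxelwise_logan(img, input, tstar, body_mask, body_fraction, fill,
                  parameter = "V_T")
}

#' @rdname map_vt
#' @param ref Reference-tissue [tac()] for `map_bp()`.
#' @export
map_bp <- function(img, ref, tstar = 30, body_mask = NULL,
                   body_fraction = 0.01, fill = 0) {
  voxelwise_logan(img, ref, tstar, body_mask, body_fraction, fill,
                  parameter = "Bp_ND")
}

voxelwise_logan <- function(img, driver, tstar, body_mask, body_fraction,
                            fill, parameter) {
  if (!inherits(img, "dynamic_image")) stop("`img` must be a `dynamic_image`")
  if (!inherits(driver, "pet_tac")) stop("driver curve must be a `pet_tac`")
  sched <- img$schedule
  if (n_frames(sched) != n_frames(driver$schedule)) {
    stop("driver TAC schedule does not match the image")
  }
  d <- dim(img$data)[1:3]
  nf <- n_frames(sched)
  if (is.null(body_mask)) {
    last <- array(img$data[, , , nf], d)
    body <- last >= body_fraction * max(last)
  } else {
    check_alignment(img, body_mask)
    body <- body_mask$mask
  }
  idx <- which(body)
  if (length(idx) == 0L) stop("body mask is empty")

  mid <- frame_midpoints(sched)
  durs <- frame_durations(sched)
  late <- which(mid > tstar)
  if (length(late) < 3L) stop("fewer than 3 frame midpoints after t*")

  flat <- matrix(img$data, nrow = prod(d), ncol = nf)
  V <- flat[idx, , drop = FALSE]

  # vectorized frame-exact running integral at midpoints
  A <- sweep(V, 2, durs, `*`)
  U <- upper.tri(diag(nf), diag = TRUE) * 1  # row-wise cumulative sum
  cumT <- A %*% U - A / 2
  cumD <- cumint_frames(durs, driver$value)

  Vl <- V[, late, drop = FALSE]
  valid <- Vl > 0
  X <- sweep(1 / Vl, 2, cumD[late], `*`)
  Y <- cumT[, late, drop = FALSE] / Vl
  X[!valid] <- NA_real_
  Y[!valid] <- NA_real_

  n <- rowSums(valid)
  sx <- rowSums(X, na.rm = TRUE)
  sy <- rowSums(Y, na.rm = TRUE)
  sxx <- rowSums(X * X, na.rm = TRUE)
  sxy <- rowSums(X * Y, na.rm = TRUE)
  den <- sxx - sx * sx / n
  slope <- (sxy - sx * sy / n) / den
  ok <- n >= 3 & is.finite(slope) & den > 0

  vals <- rep(fill, length(idx))
  n_clamped <- 0L
  if (parameter == "Bp_ND") {
    bp <- slope - 1
    n_clamped <- sum(ok & bp < -1, na.rm = TRUE)
    bp[bp < -1] <- -1
    vals[ok] <- bp[ok]
  } else {
    vals[ok] <- slope[ok]
  }

  values <- array(fill, d)
  flags <- array(0L, d)
  values[idx] <- vals
  flags[idx] <- ifelse(ok, 1L, 2L)
  structure(list(values = values, flags = flags, parameter = parameter,
                 tstar = tstar, fill = fill, n_clamped = n_clamped),
            class = "parametric_map")
}

#' @export
print.parametric_map <- function(x, ...) {
  cat(sprintf(
    "<parametric_map:%s> %s voxels fitted, %s failed, t* = %g min\n",
    x$parameter, sum(x$flags == 1L), sum(x$flags == 2L), x$tstar))
  invisible(x)
}

#' Summary statistics of a parametric map over a region
#'
#' @param map A `parametric_map`.
#' @param region_mask A [voi_mask()] (or 3D logical array) selecting the
#'   region.
#' @return A list with `mean`, `median`, `sd` (over fitted voxels;
#'   `NA` if none), `n_fitted`, `n_voxels` and `fitted_fraction`.
#' @export
map_summary <- function(map, region_mask) {
  if (!inherits(map, "parametric_map")) stop("`map` must be a `parametric_map`")
  m <- if (inherits(region_mask, "voi_mask")) region_mask$mask else region_mask
  if (!identical(dim(m), dim(map$values))) {
    stop("region mask dimensions do not match the map")
  }
  sel <- m & map$flags == 1L
  vals <- map$values[sel]
  n_tot <- sum(m)
  if (length(vals) == 0L) {
    return(list(mean = NA_real_, median = NA_real_, sd = NA_real_,
                n_fitted = 0L, n_voxels = n_tot, fitted_fraction = 0))
  }
  list(mean = mean(vals), median = stats::median(vals),
       sd = if (length(vals) > 1) stats::sd(vals) else NA_real_,
       n_fitted = length(vals), n_voxels = n_tot,
       fitted_fraction = length(vals) / n_tot)
}
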