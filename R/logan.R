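#' Running integral of a TAC
#'
#' Cumulative integral of a frame-sampled curve, evaluated at the frame
#' midpoints. Because each frame value is the time-average of the
#' activity over the frame, `value * duration` is the exact integral
#' over that frame; the running integral to a frame midpoint is the sum
#' over all preceding whole frames plus half the current frame:
#' `cumsum(value * duration) - value * duration / 2`. For the first
#' frame this is the leading triangle from (0, 0) to the midpoint. The
#' rule is exact at frame boundaries regardless of how sharply the
#' curve peaks within early frames, and exact throughout for curves
#' linear within each frame.
#'
#' @param x A [tac()].
#' @return Numeric vector of running integrals (kBq·min/ml), one per
#'   frame midpoint.
#' @export
cumulative_integral <- function(x) {
  if (!inherits(x, "pet_tac")) stop("`x` must be a `pet_tac`")
  cumint_frames(frame_durations(x$schedule), x$value)
}

cumint_frames <- function(dur, v) {
  a <- v * dur
  cumsum(a) - a / 2
}

# closed-form OLS used by both region-level and voxel-level fits, so the
# two paths are arithmetically identical
ols_line <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x * x); sxy <- sum(x * y); syy <- sum(y * y)
  den <- sxx - sx * sx / n
  if (!is.finite(den) || den <= 0) {
    return(list(slope = NA_real_, intercept = NA_real_, r2 = NA_real_))
  }
  slope <- (sxy - sx * sy / n) / den
  intercept <- sy / n - slope * sx / n
  tss <- syy - sy * sy / n
  r2 <- if (tss > 0) {
    max(0, min(1, 1 - sum((y - intercept - slope * x)^2) / tss))
  } else 1
  list(slope = slope, intercept = intercept, r2 = r2)
}

logan_fit_impl <- function(tissue, driver, tstar, slope_estimates) {
  if (!inherits(tissue, "pet_tac") || !inherits(driver, "pet_tac")) {
    stop("both curves must be `pet_tac` objects")
  }
  if (!isTRUE(all.equal(frame_midpoints(tissue$schedule),
                        frame_midpoints(driver$schedule)))) {
    stop("tissue and input TACs must share one frame schedule")
  }
  mid <- frame_midpoints(tissue$schedule)
  if (tstar < 0 || tstar >= max(mid)) stop("t* must lie within the scan")
  cumT <- cumulative_integral(tissue)
  cumD <- cumulative_integral(driver)
  late <- which(mid > tstar)
  usable <- late[tissue$value[late] > 0]
  dropped <- length(late) - length(usable)
  if (length(usable) < 3L) {
    stop(sprintf(
      "Logan fit needs >= 3 usable points after t* = %g min; found %d",
      tstar, length(usable)))
  }
  x <- cumD[usable] / tissue$value[usable]
  y <- cumT[usable] / tissue$value[usable]
  fit <- ols_line(x, y)
  if (!is.finite(fit$slope)) stop("degenerate Logan regression")
  structure(list(slope = fit$slope, intercept = fit$intercept,
                 tstar = tstar, n_points = length(usable),
                 n_dropped = dropped, r2 = fit$r2,
                 estimates = slope_estimates,
                 points = tibble::tibble(mid = mid[usable], x = x, y = y)),
            class = "logan_fit")
}

#' @export
print.logan_fit <- function(x, ...) {
  cat(sprintf(
    "<logan_fit> slope (%s) = %.4g, intercept = %.4g, t* = %g min, %d pts, R2 = %.4f\n",
    x$estimates, x$slope, x$intercept, x$tstar, x$n_points, x$r2))
  invisible(x)
}

#' Logan graphical analysis with plasma input
#'
#' Transforms the tissue and plasma curves to the Logan coordinates
#' \deqn{y = \int_0^t ROI \, / \, ROI(t), \quad
#'       x = \int_0^t C_p \, / \, ROI(t)}
#' at frame midpoints past the equilibration time `t*`, and fits an
#' ordinary least-squares line. After equilibrium the plot is linear
#' and the slope estimates the total distribution volume V_T. Midpoints
#' where the tissue value is non-positive are dropped (counted in
#' `n_dropped`); at least 3 usable points are required.
#'
#' @param tissue Tissue [tac()].
#' @param input Plasma/blood [tac()] on the same schedule.
#' @param tstar Start of the linear segment, minutes (default 30, the
#'   equilibration time of these tracers).
#' @return A `logan_fit`; the `slope` is the V_T estimate in ml/g.
#' @export
logan_plasma <- function(tissue, input, tstar = 30) {
  logan_fit_impl(tissue, input, tstar, "V_T")
}

#' Logan graphical analysis with a reference tissue
#'
#' As [logan_plasma()] but with the reference-region curve (muscle) in
#' place of plasma: the slope estimates the distribution volume ratio
#' DVR = V_T(target) / V_T(reference). The simplified late-time form
#' without the reference-efflux correction term is used, which is valid
#' past `t*` once the reference region has equilibrated with plasma.
#'
#' @param target Target-tissue [tac()].
#' @param ref Reference-tissue [tac()] on the same schedule.
#' @inheritParams logan_plasma
#' @return A `logan_fit`; the `slope` is the DVR estimate (unitless).
#' @export
logan_reference <- function(target, ref, tstar = 30) {
  logan_fit_impl(target, ref, tstar, "DVR")
}

#' Binding potential from a reference-tissue Logan fit
#'
#' `Bp_ND = DVR - 1`, the non-displaceable binding potential; under the
#' two-tissue model with a reference region matched in non-specific
#' binding it equals k3/k4.
#'
#' @param fit A `logan_fit` from [logan_reference()], or a DVR value.
#' @return Unitless binding potential.
#' @export
binding_potential <- function(fit) {
  dvr <- if (inherits(fit, "logan_fit")) fit$slope else as.numeric(fit)
  if (!is.finite(dvr)) stop("DVR must be finite")
  dvr - 1
}

#' Decompose the total distribution volume
#'
#' Splits V_T into its non-displaceable and specific components using
#' the binding potential:
#' `V_ND = V_T / (1 + Bp)`, `V_S = V_T * Bp / (1 + Bp)`, so that
#' `V_T = V_ND + V_S` holds exactly and `DVR = Bp + 1`.
#'
#' @param v_t Total distribution volume, ml/g, `>= 0`.
#' @param bp Binding potential, `> -1`.
#' @return An object of class `macro_params` with fields `vt`, `vnd`,
#'   `vs`, `dvr`, `bp`.
#' @export
decompose_vt <- function(v_t, bp) {
  if (v_t < 0) stop("V_T must be >= 0")
  if (bp <= -1) stop("binding potential must be > -1")
  vnd <- v_t / (1 + bp)
  structure(list(vt = v_t, vnd = vnd, vs = v_t - vnd,
                 dvr = bp + 1, bp = bp),
            class = "macro_params")
}

#' @export
print.macro_params <- function(x, ...) {
  cat(sprintf(
    "<macro_params> V_T=%.4g V_ND=%.4g V_S=%.4g ml/g; DVR=%.4g Bp_ND=%.4g\n",
    x$vt, x$vnd, x$vs, x$dvr, x$bp))
  invisible(x)
}

#' Logan-transformed coordinates for all frames
#'
#' Returns the transformed coordinates at every frame midpoint with a
#' positive tissue value, for diagnostics and t* selection.
#'
#' @inheritParams logan_plasma
#' @param driver Input or reference [tac()].
#' @return A tibble with columns `mid`, `x`, `y`.
#' @export
logan_points <- function(tissue, driver) {
  mid <- frame_midpoints(tissue$schedule)
  cumT <- cumulative_integral(tissue)
  cumD <- cumulative_integral(driver)
  ok <- tissue$value > 0
  tibble::tibble(mid = mid[ok],
                 x = cumD[ok] / tissue$value[ok],
                 y = cumT[ok] / tissue$value[ok])
}

#' Select the Logan linearization time t*
#'
#' In `"fixed"` mode returns the configured equilibration time (30 min,
#' where these tracers' tissue-plasma exchange has equilibrated). In
#' `"auto"` mode scans candidate midpoints and returns the smallest one
#' such that every later point deviates from the OLS line fitted to the
#' points after it by at most `max_rel_dev` (relative to the fitted
#' value).
#'
#' @param points Transformed coordinates from [logan_points()] (>= 5
#'   rows for auto selection).
#' @param max_rel_dev Maximum allowed relative deviation (default 0.10).
#' @param mode `"fixed"` or `"auto"`.
#' @param fixed The fixed t* in minutes.
#' @return t* in minutes.
#' @export
select_tstar <- function(points, max_rel_dev = 0.10,
                         mode = c("fixed", "auto"), fixed = 30) {
  mode <- match.arg(mode)
  if (mode == "fixed") return(fixed)
  if (nrow(points) < 5L) stop("auto t* selection needs >= 5 points")
  mids <- sort(points$mid)
  for (i in seq_len(length(mids) - 3L)) {
    cand <- mids[i]
    sel <- points$mid >= cand
    if (sum(sel) < 3L) break
    fit <- ols_line(points$x[sel], points$y[sel])
    if (!is.finite(fit$slope)) next
    pred <- fit$intercept + fit$slope * points$x[sel]
    dev <- abs(points$y[sel] - pred) / pmax(abs(pred), .Machine$double.eps)
    if (all(dev <= max_rel_dev)) {
      # report the time from which points are included (strictly greater)
      return(if (i == 1L) 0 else mids[i - 1L])
    }
  }
  stop("no t* satisfies the linearity criterion; consider mode = \"fixed\"")
}
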