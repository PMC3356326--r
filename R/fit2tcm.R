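#' Nonlinear micro-parameter fit of the two-tissue model
#'
#' Estimates K1, k2, k3, k4 by bounded weighted least squares against
#' the frame-averaged two-tissue prediction, with a Latin-hypercube
#' multistart (fixed seed) to escape local minima. The blood fraction
#' `vB` is held fixed (not estimated), matching the rank of information
#' in a single-region fit. This is the micro-parameter oracle; the
#' reproducible macro-parameter path remains the Logan fits combined by
#' [decompose_vt()].
#'
#' @param tissue Tissue [tac()] in kBq/ml.
#' @param input Plasma input: a `pet_input` model or a blood [tac()].
#' @param lower,upper Bounds on (K1, k2, k3, k4) in natural units.
#' @param n_starts Number of multistart points.
#' @param seed Seed for the multistart design.
#' @param weights `"duration"` (default: frame durations, the count-
#'   statistics heuristic), `"uniform"`, or `"invvar"` (inverse of
#'   `value/duration`).
#' @param vB Fixed fractional blood volume used in the model prediction.
#' @param fit_dt Model evaluation grid step (minutes) during fitting.
#' @return An object of class `micro_params`: estimates `K1`, `k2`,
#'   `k3`, `k4`, the residual norm, a `converged` flag, and the implied
#'   macro-parameters (`vt`, `vnd`, `vs`, `bp`).
#' @export
fit_2tcm_nls <- function(tissue, input,
                         lower = rep(1e-4, 4), upper = rep(5, 4),
                         n_starts = 8L, seed = 42L,
                         weights = c("duration", "uniform", "invvar"),
                         vB = 0, fit_dt = 0.01) {
  if (!inherits(tissue, "pet_tac")) stop("`tissue` must be a `pet_tac`")
  weights <- match.arg(weights)
  if (any(lower < 0) || any(upper <= lower)) {
    stop("bounds must satisfy 0 <= lower < upper")
  }
  sched <- tissue$schedule
  durs <- frame_durations(sched)
  w <- switch(weights,
              duration = durs,
              uniform = rep(1, length(durs)),
              invvar = durs / pmax(tissue$value, max(tissue$value) * 1e-3))
  sw <- sqrt(w)
  obs <- tissue$value

  grid <- seq(0, max(frame_ends(sched)), by = fit_dt)
  predict_tac <- function(par) {
    kin <- tissue_kinetics(par[1], par[2], par[3], par[4], vB = vB)
    curves <- solve_2tcm(kin, input, grid, dt = fit_dt)
    frame_average(curves, sched, sub_dt = fit_dt)$value
  }
  resid_fn <- function(par) sw * (predict_tac(par) - obs)

  # Latin-hypercube multistart on a log scale within the bounds
  u <- withr::with_seed(seed, {
    vapply(1:4, function(j) {
      (sample(n_starts) - 1 + stats::runif(n_starts)) / n_starts
    }, numeric(n_starts))
  })
  if (is.null(dim(u))) u <- matrix(u, nrow = 1)
  start_lo <- pmax(lower, 1e-4)  # keep the log-space design finite
  starts <- exp(sweep(sweep(u, 2, log(upper / start_lo), `*`),
                      2, log(start_lo), `+`))

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(par = fit$par, rss = rss, info = fit$info)
    }
  }
  if (is.null(best)) {
    return(structure(list(K1 = NA_real_, k2 = NA_real_, k3 = NA_real_,
                          k4 = NA_real_, residual = Inf, converged = FALSE),
                     class = "micro_params"))
  }
  p <- best$par
  kin <- tissue_kinetics(p[1], p[2], p[3], p[4], vB = vB)
  structure(list(K1 = p[1], k2 = p[2], k3 = p[3], k4 = p[4],
                 residual = sqrt(best$rss),
                 converged = best$info %in% 1:3,
                 vt = vt_true(kin), vnd = vnd_true(kin),
                 vs = vs_true(kin), bp = bp_true(kin)),
            class = "micro_params")
}

#' @export
print.micro_params <- function(x, ...) {
  cat(sprintf(
    "<micro_params> K1=%.4g k2=%.4g k3=%.4g k4=%.4g (V_T=%.4g, Bp=%.4g)%s\n",
    x$K1, x$k2, x$k3, x$k4, x$vt, x$bp,
    if (isTRUE(x$converged)) "" else " [not converged]"))
  invisible(x)
}
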