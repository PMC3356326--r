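#' Time-activity curves
#'
#' A time-activity curve (TAC) holds one value per frame of a
#' [frame_schedule()], in either `kBq/ml` (calibrated activity
#' concentration) or `%ID/g` (percent injected dose per gram).
#'
#' @param schedule A `frame_schedule`.
#' @param value Numeric vector, one finite value per frame.
#' @param units `"kBq/ml"` or `"%ID/g"`.
#' @return An object of class `pet_tac`.
#' @export
tac <- function(schedule, value, units = c("kBq/ml", "%ID/g")) {
  stopifnot_schedule(schedule)
  units <- match.arg(units)
  value <- as.numeric(value)
  if (length(value) != n_frames(schedule)) {
    stop("`value` must have one entry per frame")
  }
  if (any(!is.finite(value))) stop("TAC values must be finite")
  structure(list(schedule = schedule, value = value, units = units),
            class = "pet_tac")
}

#' @export
print.pet_tac <- function(x, ...) {
  cat(sprintf("<pet_tac> %d frames [%s], peak %.3g at %.2g min\n",
              n_frames(x$schedule), x$units, max(x$value),
              frame_midpoints(x$schedule)[which.max(x$value)]))
  invisible(x)
}

#' @rdname tac
#' @param x A `pet_tac`.
#' @param ... Unused.
#' @export
as_tibble_tac <- function(x, ...) {
  tibble::tibble(frame_start_min = frame_starts(x$schedule),
                 frame_end_min = frame_ends(x$schedule),
                 value = x$value,
                 units = x$units)
}

#' Average a model curve over acquisition frames
#'
#' PET frames measure the time-averaged activity over their duration.
#' Each frame value is `(1/duration) * integral` of the curve's `total`
#' over the frame, computed by trapezoidal quadrature on a fine uniform
#' sub-grid (frame endpoints included, so the average is exact for
#' curves that are linear within a frame).
#'
#' @param curves A `model_curves` object whose grid covers
#'   `[0, last frame end]`.
#' @param sched A [frame_schedule()].
#' @param sub_dt Sub-grid step in minutes.
#' @return A [tac()] in kBq/ml.
#' @export
frame_average <- function(curves, sched, sub_dt = 0.001) {
  stopifnot_schedule(sched)
  if (!inherits(curves, "model_curves")) {
    stop("`curves` must be a `model_curves` object")
  }
  tmax <- max(frame_ends(sched))
  if (max(curves$time) < tmax - 1e-9 || min(curves$time) > 0) {
    stop("curve grid must cover [0, ", tmax, "] min")
  }
  vals <- vapply(seq_len(n_frames(sched)), function(i) {
    a <- frame_starts(sched)[i]
    b <- frame_ends(sched)[i]
    nseg <- max(2L, ceiling((b - a) / sub_dt) + 1L)
    tt <- seq(a, b, length.out = nseg)
    y <- stats::approx(curves$time, curves$total, xout = tt)$y
    sum((y[-1] + y[-nseg]) / 2 * diff(tt)) / (b - a)
  }, numeric(1))
  tac(sched, vals, "kBq/ml")
}

#' Simulate a frame-averaged tissue TAC
#'
#' Convenience wrapper: solves the compartment model on a fine grid and
#' averages the total concentration over the acquisition frames.
#'
#' @inheritParams solve_2tcm
#' @param sched A [frame_schedule()].
#' @param fine_dt Solution grid step in minutes.
#' @return A [tac()] in kBq/ml.
#' @export
simulate_tac <- function(kin, input, sched, fine_dt = 0.001) {
  stopifnot_schedule(sched)
  grid <- seq(0, max(frame_ends(sched)), by = fine_dt)
  frame_average(solve_2tcm(kin, input, grid), sched, sub_dt = fine_dt)
}

#' @rdname simulate_tac
#' @details `simulate_input_tac()` frame-averages the plasma input
#'   itself, as measured in a pure-blood region.
#' @export
simulate_input_tac <- function(input, sched, fine_dt = 0.001) {
  stopifnot_schedule(sched)
  grid <- seq(0, max(frame_ends(sched)), by = fine_dt)
  cp <- eval_input(input, grid)
  curves <- structure(list(time = grid, Cp = cp, Ct = 0 * cp, Cm = 0 * cp,
                           total = cp), class = "model_curves")
  frame_average(curves, sched, sub_dt = fine_dt)
}

#' Frame-count noise specification
#'
#' @param scale Unitless noise scale; 0 means exact pass-through.
#' @param seed Integer RNG seed; noise is reproducible under the seed.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(scale = 1, seed = 1L) {
  if (scale < 0) stop("`scale` must be >= 0")
  structure(list(scale = scale, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Add frame-count noise to a TAC
#'
#' Adds independent zero-mean Gaussian noise with per-frame standard
#' deviation `scale * sqrt(max(value, 0) / duration)`, the usual
#' count-limited heuristic in which short frames and hot frames are
#' noisier in proportion to their expected counts. Values may go
#' slightly negative and are kept as-is.
#'
#' @param x A [tac()].
#' @param spec A [noise_spec()].
#' @return A `pet_tac` with noise added.
#' @export
add_noise <- function(x, spec) {
  if (!inherits(x, "pet_tac")) stop("`x` must be a `pet_tac`")
  if (!inherits(spec, "noise_spec")) stop("`spec` must be a `noise_spec`")
  if (spec$scale == 0) return(x)
  sd <- spec$scale * sqrt(pmax(x$value, 0) / frame_durations(x$schedule))
  noise <- withr::with_seed(spec$seed,
                            stats::rnorm(length(x$value), 0, sd))
  tac(x$schedule, x$value + noise, x$units)
}

#' Read and write TAC CSV files
#'
#' CSV layout: header `frame_start_min,frame_end_min,value,units`, one
#' row per frame.
#'
#' @param x A `pet_tac`.
#' @param path File path.
#' @export
write_tac_csv <- function(x, path) {
  utils::write.csv(as.data.frame(as_tibble_tac(x)), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tac_csv
#' @export
read_tac_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame_start_min", "frame_end_min", "value", "units")
  if (!all(need %in% names(df))) {
    stop("TAC CSV must have columns: ", paste(need, collapse = ", "))
  }
  tac(frame_schedule(df$frame_start_min, df$frame_end_min),
      df$value, unique(df$units))
}
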