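#' Frame schedule for a dynamic PET acquisition
#'
#' A frame schedule records the start and end time of every reconstructed
#' frame, in minutes post injection. Frames must be contiguous (each frame
#' starts where the previous one ended), start at time zero, and have
#' strictly positive durations.
#'
#' @param start Numeric vector of frame start times (minutes).
#' @param end Numeric vector of frame end times (minutes), same length.
#'
#' @return An object of class `frame_schedule`: a list with elements
#'   `start` and `end` (minutes).
#' @seealso [schedule_60min_mouse()] for the built-in 30-frame schedule.
#' @export
#' @examples
#' frame_schedule(c(0, 1, 2), c(1, 2, 4))
frame_schedule <- function(start, end) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(start) != length(end) || length(start) < 1L) {
    stop("`start` and `end` must be non-empty vectors of equal length")
  }
  if (start[1] != 0) stop("first frame must start at 0 min")
  if (any(end <= start)) stop("all frame durations must be > 0")
  if (length(start) > 1L && any(abs(start[-1] - end[-length(end)]) > 1e-9)) {
    stop("frames must be contiguous: each start must equal the previous end")
  }
  structure(list(start = start, end = end), class = "frame_schedule")
}

#' Built-in 60-minute mouse acquisition schedule
#'
#' The 30-frame dynamic schedule used throughout the package for 60-min
#' small-animal scans: 10 frames of 30 s, 5 of 60 s, 5 of 120 s and 10 of
#' 240 s, covering exactly 0--60 min.
#'
#' @return A [frame_schedule()] with 30 frames ending at 60 min.
#' @export
#' @examples
#' sched <- schedule_60min_mouse()
#' n_frames(sched)
#' frame_ends(sched)[30]
schedule_60min_mouse <- function() {
  durations <- c(rep(0.5, 10), rep(1, 5), rep(2, 5), rep(4, 10))
  end <- cumsum(durations)
  frame_schedule(c(0, end[-length(end)]), end)
}

#' @rdname frame_schedule
#' @param sched A `frame_schedule`.
#' @export
n_frames <- function(sched) length(sched$start)

#' @rdname frame_schedule
#' @export
frame_starts <- function(sched) sched$start

#' @rdname frame_schedule
#' @export
frame_ends <- function(sched) sched$end

#' @rdname frame_schedule
#' @export
frame_durations <- function(sched) sched$end - sched$start

#' @rdname frame_schedule
#' @export
frame_midpoints <- function(sched) (sched$start + sched$end) / 2

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("<frame_schedule> %d frames, 0-%g min\n",
              n_frames(x), x$end[n_frames(x)]))
  invisible(x)
}

is_frame_schedule <- function(x) inherits(x, "frame_schedule")

stopifnot_schedule <- function(sched) {
  if (!is_frame_schedule(sched)) stop("expected a `frame_schedule` object")
  invisible(sched)
}
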