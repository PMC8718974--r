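#' PET frame schedule
#'
#' A frame schedule holds per-frame start and end times of a dynamic PET
#' acquisition. All kinetic routines in this package work in minutes
#' internally; the TSV interchange format stores seconds, as scanner
#' exports usually do.
#'
#' @param start numeric vector of frame start times.
#' @param end numeric vector of frame end times, same length as `start`.
#' @param units `"min"` or `"s"`; times are converted to minutes.
#' @return An object of class `frame_schedule`: a data frame with columns
#'   `start`, `end`, `mid` and `dur` (all minutes).
#' @examples
#' sch <- default_schedule()
#' range(sch$end)
#' @export
frame_schedule <- function(start, end, units = c("min", "s")) {
  units <- match.arg(units)
  if (length(start) == 0L || length(start) != length(end))
    stop("invalid schedule: 'start' and 'end' must be non-empty and equal length")
  if (units == "s") {
    start <- start / 60
    end <- end / 60
  }
  if (any(end <= start))
    stop("invalid schedule: frame durations must be positive")
  if (is.unsorted(start, strictly = TRUE) || any(start[-1] < end[-length(end)] - 1e-9))
    stop("invalid schedule: frames must be strictly increasing and non-overlapping")
  out <- data.frame(start = start, end = end,
                    mid = (start + end) / 2, dur = end - start)
  class(out) <- c("frame_schedule", "data.frame")
  out
}

#' Default 18-frame, 60-minute schedule
#'
#' Sixty minutes split into 18 frames with short early frames (4 x 0.5 min,
#' 4 x 1 min, 4 x 2 min, 2 x 3 min, 4 x 10 min), the usual shape for a
#' dynamic [11C]PK11195 acquisition. The schedule is a configuration
#' choice; any `frame_schedule` covering the acquisition window works.
#'
#' @return A `frame_schedule`.
#' @export
default_schedule <- function() {
  dur <- c(rep(0.5, 4), rep(1, 4), rep(2, 4), rep(3, 2), rep(10, 4))
  end <- cumsum(dur)
  frame_schedule(start = end - dur, end = end)
}

#' Read / write a frame schedule as TSV
#'
#' The interchange format has columns `frame_start` and `frame_end` in
#' seconds.
#'
#' @param path file path.
#' @return `read_schedule` returns a `frame_schedule`.
#' @export
read_schedule <- function(path) {
  tab <- utils::read.delim(path, sep = "\t")
  frame_schedule(tab$frame_start, tab$frame_end, units = "s")
}

#' @rdname read_schedule
#' @param schedule a `frame_schedule`.
#' @export
write_schedule <- function(schedule, path) {
  utils::write.table(
    data.frame(frame_start = schedule$start * 60, frame_end = schedule$end * 60),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Time-activity curve
#'
#' A TAC pairs a frame schedule with per-frame mean activity for one
#' region. A TAC may carry a fine-grid version of the underlying
#' continuous curve (attribute `fine`) when it was produced by a forward
#' simulator; fitting routines never rely on it.
#'
#' @param schedule a `frame_schedule`.
#' @param activity numeric vector of per-frame mean activity (kBq/mL).
#' @param region optional region label.
#' @param fine optional list(t, value) fine-grid curve.
#' @return An object of class `tac`.
#' @export
tac <- function(schedule, activity, region = NA_character_, fine = NULL) {
  stopifnot(inherits(schedule, "frame_schedule"))
  if (length(activity) != nrow(schedule))
    stop("activity length must match the number of frames")
  if (any(!is.finite(activity)))
    stop("TAC activity must be finite")
  structure(list(schedule = schedule, activity = activity, region = region),
            fine = fine, class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("TAC [%s]: %d frames, %.1f-%.1f min, peak %.3g at %.2g min\n",
              ifelse(is.na(x$region), "unlabelled", x$region),
              nrow(x$schedule), min(x$schedule$start), max(x$schedule$end),
              max(x$activity), x$schedule$mid[which.max(x$activity)]))
  invisible(x)
}

#' @export
plot.tac <- function(x, ..., xlab = "time (min)", ylab = "activity (kBq/mL)") {
  plot(x$schedule$mid, x$activity, type = "b", xlab = xlab, ylab = ylab, ...)
}

# Fine uniform time grid used for model quadrature (0.1 min step).
fine_grid <- function(schedule, dt = 0.1) {
  seq(0, max(schedule$end), by = dt)
}

# Average a fine-grid curve within each frame of the schedule.
frame_average <- function(t, v, schedule) {
  vapply(seq_len(nrow(schedule)), function(i) {
    sel <- t >= schedule$start[i] - 1e-9 & t <= schedule$end[i] + 1e-9
    mean(v[sel])
  }, numeric(1))
}

# Reconstruct a fine-grid curve from a TAC: use the carried fine curve if
# present, otherwise interpolate frame means at frame midpoints, anchored
# at (0, 0).
tac_fine <- function(x, dt = 0.1) {
  f <- attr(x, "fine")
  t <- fine_grid(x$schedule, dt)
  if (!is.null(f)) return(list(t = t, value = stats::approx(f$t, f$value, t, rule = 2)$y))
  xs <- c(0, x$schedule$mid)
  ys <- c(0, x$activity)
  list(t = t, value = stats::approx(xs, ys, t, rule = 2)$y)
}
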