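#' Frame schedule of a dynamic PET acquisition
#'
#' A frame schedule records the start and end time (minutes post-injection) of
#' every reconstructed frame. Frames must be contiguous and strictly
#' increasing: each frame starts where the previous one ends.
#'
#' @param frame_starts,frame_ends Numeric vectors of frame boundaries in
#'   minutes post-injection.
#' @return A tibble of class `fet_schedule` with columns `start`, `end`,
#'   `mid` (frame midpoint) and `duration`, all in minutes.
#' @examples
#' frame_schedule(c(0, 5), c(5, 10))
#' default_schedule()
#' @export
frame_schedule <- function(frame_starts, frame_ends) {
  if (length(frame_starts) != length(frame_ends) || length(frame_starts) == 0)
    abort("frame_starts and frame_ends must be non-empty and equal length")
  if (any(frame_ends <= frame_starts))
    abort("every frame must have positive duration")
  if (length(frame_starts) > 1 &&
      any(abs(frame_starts[-1] - frame_ends[-length(frame_ends)]) > 1e-9))
    abort("frames must be contiguous: frame_starts[i+1] must equal frame_ends[i]")
  out <- tibble::tibble(
    start = as.numeric(frame_starts),
    end = as.numeric(frame_ends),
    mid = (frame_starts + frame_ends) / 2,
    duration = frame_ends - frame_starts
  )
  class(out) <- c("fet_schedule", class(out))
  out
}

#' Default 40-minute dynamic acquisition schedule
#'
#' One-minute frames over 0-5 min, five-minute frames over 5-20 min and
#' ten-minute frames over 20-40 min (10 frames). The boundaries resolve every
#' time-to-peak group interval exactly; any contiguous schedule can be
#' supplied instead wherever a schedule is accepted.
#'
#' @return A `fet_schedule` tibble.
#' @export
default_schedule <- function() {
  starts <- c(0:4, c(5, 10, 15), c(20, 30))
  ends <- c(1:5, c(10, 15, 20), c(30, 40))
  frame_schedule(starts, ends)
}

#' Read or write a frame schedule JSON sidecar
#'
#' The sidecar stores `frame_starts_min` and `frame_ends_min` arrays.
#'
#' @param schedule A `fet_schedule`.
#' @param path File path of the JSON sidecar.
#' @return `write_schedule()` returns `path` invisibly; `read_schedule()`
#'   returns a `fet_schedule`.
#' @export
write_schedule <- function(schedule, path) {
  jsonlite::write_json(
    list(frame_starts_min = schedule$start, frame_ends_min = schedule$end),
    path, digits = NA
  )
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  frame_schedule(x$frame_starts_min, x$frame_ends_min)
}
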