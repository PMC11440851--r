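#' Frame schedule for a dynamic PET acquisition
#'
#' A frame schedule holds the per-frame start times and durations of a
#' dynamic reconstruction, plus the derived frame mid-times
#' (`start + duration/2`). All curve arithmetic in this package is done on
#' the mid-time grid.
#'
#' @param frame_start numeric vector of frame start times in seconds,
#'   strictly increasing.
#' @param frame_duration numeric vector of frame durations in seconds,
#'   all positive; frames must not overlap.
#' @return An object of class `frame_schedule`: a list with components
#'   `frame_start`, `frame_duration` and `mid_time` (all seconds).
#' @seealso [build_schedule()] for the compact count-by-duration form,
#'   [read_frame_timing()] for BIDS-PET JSON sidecars.
#' @export
frame_schedule <- function(frame_start, frame_duration) {
  frame_start <- as.numeric(frame_start)
  frame_duration <- as.numeric(frame_duration)
  n <- length(frame_start)
  if (n == 0L) stop("invalid schedule: no frames", call. = FALSE)
  if (length(frame_duration) != n)
    stop("invalid schedule: frame_start and frame_duration lengths differ",
         call. = FALSE)
  if (any(!is.finite(frame_start)) || any(!is.finite(frame_duration)))
    stop("invalid schedule: non-finite frame timing", call. = FALSE)
  if (any(frame_duration <= 0))
    stop("invalid schedule: non-positive frame duration", call. = FALSE)
  if (n > 1L) {
    if (any(diff(frame_start) <= 0))
      stop("invalid schedule: frame_start not strictly increasing",
           call. = FALSE)
    overlap <- frame_start[-1L] - (frame_start[-n] + frame_duration[-n])
    if (any(overlap < -1e-9))
      stop("invalid schedule: overlapping frames", call. = FALSE)
  }
  structure(
    list(frame_start = frame_start,
         frame_duration = frame_duration,
         mid_time = frame_start + frame_duration / 2),
    class = "frame_schedule")
}

#' Build a contiguous frame schedule from a count-by-duration recipe
#'
#' Dynamic PET protocols are typically quoted as "40 frames x 1 s +
#' 5 frames x 4 s + ...". This constructor expands such a recipe into a
#' contiguous [frame_schedule()] starting at t = 0.
#'
#' @param spec a list of `c(count, duration)` pairs (or a 2-column matrix /
#'   data.frame with columns count, duration), in acquisition order.
#' @return A [frame_schedule()].
#' @examples
#' # 180 s water protocol: 54 frames
#' build_schedule(list(c(40, 1), c(5, 4), c(6, 10), c(3, 20)))
#' @export
build_schedule <- function(spec) {
  if (is.matrix(spec) || is.data.frame(spec))
    spec <- lapply(seq_len(nrow(spec)), function(i) as.numeric(spec[i, 1:2]))
  if (length(spec) == 0L) stop("invalid schedule: empty spec", call. = FALSE)
  counts <- vapply(spec, function(x) as.numeric(x[1L]), numeric(1))
  durs <- vapply(spec, function(x) as.numeric(x[2L]), numeric(1))
  if (any(!is.finite(counts)) || any(counts < 1) || any(counts != round(counts)))
    stop("invalid schedule: frame counts must be integers >= 1", call. = FALSE)
  if (any(!is.finite(durs)) || any(durs <= 0))
    stop("invalid schedule: non-positive duration", call. = FALSE)
  duration <- rep(durs, times = counts)
  start <- cumsum(c(0, duration[-length(duration)]))
  frame_schedule(start, duration)
}

#' Canonical acquisition schedules
#'
#' `h2o_schedule()` is the 180 s / 54-frame fast protocol
#' (40x1 s + 5x4 s + 6x10 s + 3x20 s) used for [15O]H2O;
#' `fdg_schedule()` is the 600 s / 71-frame protocol
#' (40x1 s + 10x5 s + 15x10 s + 6x60 s) used for slower tracers.
#'
#' @return A [frame_schedule()].
#' @export
h2o_schedule <- function()
  build_schedule(list(c(40, 1), c(5, 4), c(6, 10), c(3, 20)))

#' @rdname h2o_schedule
#' @export
fdg_schedule <- function()
  build_schedule(list(c(40, 1), c(10, 5), c(15, 10), c(6, 60)))

#' Number of frames in a schedule
#' @param schedule a [frame_schedule()].
#' @return integer frame count.
#' @export
n_frames <- function(schedule) length(schedule$frame_start)

#' End time of the last frame
#' @param schedule a [frame_schedule()].
#' @return seconds.
#' @export
schedule_end <- function(schedule) {
  n <- n_frames(schedule)
  schedule$frame_start[n] + schedule$frame_duration[n]
}

#' Read frame timing from a BIDS-PET JSON sidecar
#'
#' Reads the `FrameTimesStart` and `FrameDuration` arrays (seconds) of a
#' BIDS-PET sidecar into a [frame_schedule()].
#'
#' @param path path to a JSON file.
#' @return A [frame_schedule()].
#' @export
read_frame_timing <- function(path) {
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(meta$FrameTimesStart) || is.null(meta$FrameDuration))
    stop("frame timing sidecar must contain FrameTimesStart and FrameDuration",
         call. = FALSE)
  frame_schedule(meta$FrameTimesStart, meta$FrameDuration)
}

#' Write frame timing to a BIDS-PET style JSON sidecar
#' @param schedule a [frame_schedule()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_frame_timing <- function(schedule, path) {
  jsonlite::write_json(
    list(FrameTimesStart = schedule$frame_start,
         FrameDuration = schedule$frame_duration),
    path, digits = NA)
  invisible(path)
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("Frame schedule: %d frames, 0-%g s\n",
              n_frames(x), schedule_end(x)))
  rl <- rle(x$frame_duration)
  cat("  ", paste(sprintf("%d x %g s", rl$lengths, rl$values),
                  collapse = " + "), "\n", sep = "")
  invisible(x)
}

same_schedule <- function(a, b, tol = 1e-9) {
  n_frames(a) == n_frames(b) &&
    max(abs(a$frame_start - b$frame_start)) <= tol &&
    max(abs(a$frame_duration - b$frame_duration)) <= tol
}
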