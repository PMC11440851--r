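#' Time-activity curve
#'
#' A time-activity curve (TAC) is the tracer concentration (Bq/ml) in a
#' voxel, region or blood pool, sampled once per reconstruction frame of a
#' [frame_schedule()]. Negative values are permitted: iterative
#' reconstruction noise can produce them, and no downstream operation
#' assumes non-negativity.
#'
#' @param schedule a [frame_schedule()].
#' @param activity numeric vector, Bq/ml, one value per frame; finite.
#' @return An object of class `tac`.
#' @export
tac <- function(schedule, activity) {
  stopifnot(inherits(schedule, "frame_schedule"))
  activity <- as.numeric(activity)
  if (length(activity) != n_frames(schedule))
    stop("activity length must equal the number of frames", call. = FALSE)
  if (any(!is.finite(activity)))
    stop("activity values must be finite", call. = FALSE)
  structure(list(schedule = schedule, activity = activity), class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("Time-activity curve: %d frames, 0-%g s, peak %.4g Bq/ml\n",
              n_frames(x$schedule), schedule_end(x$schedule),
              max(x$activity)))
  invisible(x)
}

#' @export
plot.tac <- function(x, ..., xlab = "Frame mid-time [s]",
                     ylab = "Activity [Bq/ml]", type = "b") {
  graphics::plot(x$schedule$mid_time, x$activity, xlab = xlab, ylab = ylab,
                 type = type, ...)
  invisible(x)
}

# Frame-spacing weights for cumulative summation: the weight of frame i is
# mid_time(i+1) - mid_time(i); the last frame, whose successor mid-time
# does not exist, is weighted by its own duration (the consistent limit on
# uniform schedules). These weights prevent steps in the summed curve where
# the frame duration changes.
frame_weights <- function(schedule) {
  mt <- schedule$mid_time
  n <- length(mt)
  if (n == 1L) return(schedule$frame_duration)
  c(diff(mt), schedule$frame_duration[n])
}

#' Frame-duration-weighted cumulative sum of a TAC
#'
#' Converts a TAC into the running integral actually used for onset
#' fitting: `values[k] = sum_{i<=k} TAC(i) * w(i)` with weights
#' `w(i) = mid_time(i+1) - mid_time(i)` (the final frame weighted by its
#' own duration). Weighting by the local mid-time spacing keeps the summed
#' curve free of abrupt slope steps at points where the frame duration
#' changes, and the summation suppresses zero-mean frame noise.
#'
#' @param x a [tac()].
#' @return An object of class `cumulative_curve`: list with `schedule`,
#'   `values` (Bq.s/ml per frame) and `plateau_corrected` flag.
#' @export
cumulative_sum <- function(x) {
  stopifnot(inherits(x, "tac"))
  cumulative_curve(x$schedule, cumsum(x$activity * frame_weights(x$schedule)))
}

cumulative_curve <- function(schedule, values, plateau_corrected = FALSE) {
  stopifnot(inherits(schedule, "frame_schedule"),
            length(values) == n_frames(schedule))
  structure(list(schedule = schedule, values = as.numeric(values),
                 plateau_corrected = plateau_corrected),
            class = "cumulative_curve")
}

#' @export
print.cumulative_curve <- function(x, ...) {
  cat(sprintf(
    "Cumulative summed TAC: %d frames, final value %.4g Bq.s/ml%s\n",
    n_frames(x$schedule), x$values[length(x$values)],
    if (isTRUE(x$plateau_corrected)) " (plateau corrected)" else ""))
  invisible(x)
}

#' @export
plot.cumulative_curve <- function(x, ..., xlab = "Frame mid-time [s]",
                                  ylab = "Summed activity [Bq.s/ml]",
                                  type = "b") {
  graphics::plot(x$schedule$mid_time, x$values, xlab = xlab, ylab = ylab,
                 type = type, ...)
  invisible(x)
}

#' Read / write TAC tables
#'
#' Delimited tables with a mandatory header row and columns `frame_start`,
#' `frame_duration`, `activity` (seconds, seconds, Bq/ml). Comma and tab
#' separators are auto-detected on read; writes are comma-separated.
#'
#' @param path file path.
#' @return `read_tac_table` returns a [tac()]; `write_tac_table` returns
#'   `path` invisibly.
#' @export
read_tac_table <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L)
    stop("TAC table is empty: ", path, call. = FALSE)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          strip.white = TRUE)
  need <- c("frame_start", "frame_duration", "activity")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("TAC table missing column(s): ", paste(missing, collapse = ", "),
         " (header line: '", header, "')", call. = FALSE)
  bad <- which(!stats::complete.cases(df[need]))
  if (length(bad))
    stop("TAC table has incomplete row(s) at line(s): ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  tac(frame_schedule(df$frame_start, df$frame_duration), df$activity)
}

#' @rdname read_tac_table
#' @param x a [tac()] to write.
#' @export
write_tac_table <- function(x, path) {
  stopifnot(inherits(x, "tac"))
  df <- data.frame(frame_start = x$schedule$frame_start,
                   frame_duration = x$schedule$frame_duration,
                   activity = x$activity)
  utils::write.table(format(df, digits = 17, scientific = NA, trim = TRUE),
                     path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
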