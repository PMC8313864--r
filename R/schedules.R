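#' Build an illumination schedule
#'
#' A light schedule records, for every acquired frame, the time in seconds and
#' whether the blue (activation) light is on. Rates of the optogenetic model
#' switch between their lit and unlit values according to this flag, with the
#' light treated as continuously on for the duration of a lit frame.
#'
#' @param frame_times Numeric vector of frame acquisition times in seconds,
#'   strictly increasing.
#' @param lit Logical vector, one entry per frame.
#' @return A tibble of class `light_schedule` with columns `frame`, `time_s`
#'   and `lit`.
#' @examples
#' light_schedule(seq(0, 40, by = 4), rep(c(FALSE, TRUE), each = 5)[1:11])
#' @export
light_schedule <- function(frame_times, lit) {
  frame_times <- as.numeric(frame_times)
  lit <- as.logical(lit)
  if (length(frame_times) < 1L) abort("schedule must contain at least one frame")
  if (length(lit) != length(frame_times)) {
    abort("`lit` must have one entry per frame")
  }
  if (anyNA(frame_times) || anyNA(lit)) abort("schedule must not contain NA")
  if (any(diff(frame_times) <= 0)) abort("frame times must be strictly increasing")
  out <- tibble(
    frame = seq_along(frame_times),
    time_s = frame_times,
    lit = lit
  )
  class(out) <- c("light_schedule", class(out))
  out
}

#' Build a schedule from blocks of frames
#'
#' Convenience constructor: consecutive blocks of frames at a fixed frame
#' interval, each block entirely lit or entirely dark.
#'
#' @param blocks A list of `list(n_frames =, lit =)` entries.
#' @param frame_interval_s Time between frames, seconds.
#' @param t0 Time of the first frame, seconds.
#' @return A [light_schedule()].
#' @export
schedule_from_blocks <- function(blocks, frame_interval_s = 4, t0 = 0) {
  n <- vapply(blocks, function(b) as.integer(b$n_frames), integer(1))
  l <- vapply(blocks, function(b) as.logical(b$lit), logical(1))
  if (any(n < 1L)) abort("each block needs at least one frame")
  lit <- rep(l, n)
  times <- t0 + (seq_along(lit) - 1L) * frame_interval_s
  light_schedule(times, lit)
}

#' Standard acquisition protocols
#'
#' Returns the default illumination/bleaching protocols used throughout the
#' package:
#' \describe{
#'   \item{`"opto-standard"`}{5 dark pre-activation frames, 150 lit (release)
#'     frames, 150 dark (recovery) frames, 4 s apart.}
#'   \item{`"opto-staggered"`}{80 lit release frames then four cycles of
#'     19 dark frames and 1 lit frame (staggered release), 4 s apart.}
#'   \item{`"flip"`}{3 pre-bleach frames then 150 frames at 2 s intervals with
#'     a 2 s bleach applied between consecutive frames.}
#'   \item{`"frap"`}{default bleach protocol: 5 pre-bleach frames, 80 recovery
#'     frames at 0.5 s, a single bleach pulse on a cytoplasmic ROI.}
#' }
#'
#' @param name One of `"opto-standard"`, `"opto-staggered"`, `"flip"`,
#'   `"frap"`.
#' @return A [light_schedule()] for the optogenetic and FLIP protocols, or a
#'   [bleach_protocol()] for `"frap"`.
#' @export
default_protocols <- function(name) {
  switch(name,
    "opto-standard" = schedule_from_blocks(
      list(
        list(n_frames = 5, lit = FALSE),
        list(n_frames = 150, lit = TRUE),
        list(n_frames = 150, lit = FALSE)
      ),
      frame_interval_s = 4
    ),
    "opto-staggered" = {
      blocks <- c(
        list(list(n_frames = 80, lit = TRUE)),
        rep(list(
          list(n_frames = 19, lit = FALSE),
          list(n_frames = 1, lit = TRUE)
        ), 4)
      )
      schedule_from_blocks(blocks, frame_interval_s = 4)
    },
    "flip" = {
      sched <- schedule_from_blocks(
        list(list(n_frames = 153, lit = FALSE)),
        frame_interval_s = 2
      )
      # bleach pulses occur between every pair of frames after frame 3
      attr(sched, "bleach_after_frame") <- 3L
      sched
    },
    "frap" = bleach_protocol(),
    abort(paste0("unknown protocol name: ", name))
  )
}

# Contiguous constant-lit blocks of a schedule: tibble with start/end frame
# indices and the lit flag. Used by the piecewise-exact ODE propagator and the
# bilinear normalisation.
schedule_blocks <- function(schedule) {
  lit <- schedule$lit
  r <- rle(lit)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  tibble(start = starts, end = ends, lit = r$values)
}

#' Serialise / deserialise a light schedule as JSON
#'
#' Schedules are stored as `{frame_interval_s, blocks: [{n_frames, lit}]}`
#' when the frame spacing is uniform, otherwise as explicit frame times.
#'
#' @param schedule A [light_schedule()].
#' @param path File path.
#' @return `write_schedule()` returns `path` invisibly; `read_schedule()`
#'   returns a [light_schedule()].
#' @export
write_schedule <- function(schedule, path) {
  dt <- diff(schedule$time_s)
  if (length(dt) > 0 && diff(range(dt)) < 1e-9) {
    blk <- schedule_blocks(schedule)
    obj <- list(
      frame_interval_s = dt[1],
      t0 = schedule$time_s[1],
      blocks = purrr::pmap(blk, function(start, end, lit) {
        list(n_frames = end - start + 1L, lit = lit)
      })
    )
  } else {
    obj <- list(frame_times = schedule$time_s, lit = schedule$lit)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(obj$blocks)) {
    blocks <- obj$blocks
    if (is.data.frame(blocks)) {
      blocks <- purrr::pmap(blocks, function(n_frames, lit) {
        list(n_frames = n_frames, lit = lit)
      })
    }
    schedule_from_blocks(blocks,
      frame_interval_s = obj$frame_interval_s,
      t0 = obj$t0 %||% 0
    )
  } else {
    light_schedule(obj$frame_times, obj$lit)
  }
}
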