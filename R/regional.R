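#' Regional gain map of light-induced intensity change
#'
#' Spatial map of the relative change in fluorescence caused by blue-light
#' release: the mean of the five frames before illumination and the mean of
#' five frames after 200 s of illumination are computed per pixel; the
#' latter is multiplied by 256 and divided by the former (so no change maps
#' to 256), the result is 2x2 mean-binned to reduce noise and stored at
#' 16-bit depth, with an 8-bit export clipped at 255 for display parity.
#' Pixels with zero pre-illumination mean are masked out (`NA`).
#'
#' @param stack An [image_stack()] (protein channel used).
#' @param schedule A [light_schedule()] with at least 5 pre-lit frames and
#'   5 frames at or after 200 s of illumination.
#' @param after_s Illumination duration before the "post" window (default
#'   200 s).
#' @return A list with `gain` (2x2-binned numeric matrix, 256 = no change),
#'   `gain_8bit` (clipped integer matrix), and `summary` (tibble with mean
#'   and CV of the gain over valid pixels).
#' @export
regional_gain_map <- function(stack, schedule, after_s = 200) {
  protein <- stack_channel(stack, "protein")
  lit <- schedule$lit
  first_lit <- if (any(lit)) min(which(lit)) else abort("schedule has no lit frames")
  pre_idx <- which(!lit & seq_along(lit) < first_lit)
  if (length(pre_idx) < 5L) abort("need at least 5 pre-illumination frames")
  pre_idx <- tail(pre_idx, 5L)
  t_on <- schedule$time_s[first_lit]
  post_pool <- which(schedule$time_s >= t_on + after_s)
  if (length(post_pool) < 5L) {
    abort(sprintf("need at least 5 frames after %g s of illumination", after_s))
  }
  post_idx <- post_pool[1:5]
  pre <- apply(protein[, , pre_idx, drop = FALSE], c(1, 2), mean)
  post <- apply(protein[, , post_idx, drop = FALSE], c(1, 2), mean)
  gain <- post * 256 / pre
  gain[pre <= 0] <- NA_real_
  gain_b <- bin2(gain)
  gain16 <- pmin(round(gain_b), 65535L)
  gain8 <- pmin(round(gain_b), 255L)
  valid <- !is.na(gain_b)
  list(
    gain = gain16,
    gain_8bit = gain8,
    summary = tibble(
      mean_gain = mean(gain_b[valid]),
      cv_gain = sd(gain_b[valid]) / mean(gain_b[valid]),
      n_valid = sum(valid), n_masked = sum(!valid)
    )
  )
}

# 2x2 mean binning (trailing odd row/col dropped); NA propagates.
bin2 <- function(m) {
  nr <- nrow(m) %/% 2L * 2L
  nc <- ncol(m) %/% 2L * 2L
  m <- m[seq_len(nr), seq_len(nc)]
  (m[seq(1, nr, 2), seq(1, nc, 2)] + m[seq(2, nr, 2), seq(1, nc, 2)] +
     m[seq(1, nr, 2), seq(2, nc, 2)] + m[seq(2, nr, 2), seq(2, nc, 2)]) / 4
}

#' Average pulse response across staggered-release cycles
#'
#' In the staggered protocol each brief light pulse during recovery is a
#' technical replicate of the release response. Post-pulse segments are
#' aligned at the pulse frame, averaged per frame offset, and summarised by
#' the peak response and the post-peak decline rate.
#'
#' @param trace_per_region A data frame with columns `frame` (or `time_s`)
#'   and one or more response columns (e.g. regional intensities), plus the
#'   pulses defined by `schedule`.
#' @param schedule A [light_schedule()] whose isolated lit frames (after
#'   the initial release block) define the pulses; pulse spacing must be
#'   equal.
#' @param value_cols Character vector of response columns to average
#'   (default: all numeric columns except `frame` and `time_s`).
#' @param n_post Frames after each pulse to include (default: the common
#'   spacing).
#' @return A list with `response` (tibble: `region`, `offset`, `mean`,
#'   `sd`, `n`) and `summary` (tibble: `region`, `peak`, `peak_offset`,
#'   `decline_rate` from a log-linear fit after the peak).
#' @export
average_pulse_response <- function(trace_per_region, schedule,
                                   value_cols = NULL, n_post = NULL) {
  lit <- schedule$lit
  # isolated pulses: lit frames whose previous frame is dark
  pulse_frames <- which(lit & !dplyr::lag(lit, default = FALSE))
  # drop the initial release block start (frame run of length > 1)
  run_len <- vapply(pulse_frames, function(f) {
    k <- 0L
    while (f + k <= length(lit) && lit[f + k]) k <- k + 1L
    k
  }, integer(1))
  pulse_frames <- pulse_frames[run_len == 1L]
  if (length(pulse_frames) < 2L) abort("need at least 2 pulses of identical length")
  spacing <- diff(pulse_frames)
  if (length(unique(spacing)) > 1L) abort("unequal pulse spacing")
  n_post <- n_post %||% spacing[1]
  if (is.null(value_cols)) {
    value_cols <- setdiff(names(trace_per_region)[vapply(trace_per_region, is.numeric, logical(1))],
                          c("frame", "time_s"))
  }
  nf <- nrow(trace_per_region)
  rows <- list()
  for (col in value_cols) {
    segs <- lapply(pulse_frames, function(p) {
      idx <- p + 0:(n_post - 1L)
      idx <- idx[idx <= nf]
      trace_per_region[[col]][idx]
    })
    # a pulse too close to the movie end yields a truncated segment; use the
    # full-length replicates when at least two exist
    full <- lengths(segs) == n_post
    if (sum(full) >= 2L) segs <- segs[full]
    len <- min(lengths(segs))
    segm <- matrix(vapply(segs, function(s) s[seq_len(len)], numeric(len)),
                   nrow = len)
    rows[[col]] <- tibble(
      region = col,
      offset = 0:(len - 1L),
      mean = rowMeans(segm),
      sd = apply(segm, 1, sd),
      n = ncol(segm)
    )
  }
  response <- bind_rows(rows)
  summary <- response |>
    group_by(.data$region) |>
    summarise(
      peak = max(.data$mean),
      peak_offset = .data$offset[which.max(.data$mean)],
      decline_rate = {
        pk <- which.max(.data$mean)
        post <- .data$mean[pk:length(.data$mean)]
        if (length(post) >= 3 && all(post > 0)) {
          -coef(lm(log(post) ~ seq_along(post)))[[2]]
        } else NA_real_
      },
      .groups = "drop"
    )
  list(response = response, summary = summary)
}
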