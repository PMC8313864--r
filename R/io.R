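#' Read and write compartment traces as CSV
#'
#' Traces are stored with columns `time_s`, `lit`, `M`, `C`, `N`,
#' `normalized` (0/1). Round trips are lossless to double precision.
#'
#' @param trace A `compartment_trace`.
#' @param path File path.
#' @return `write_trace()` returns `path` invisibly; `read_trace()` returns
#'   a `compartment_trace`.
#' @export
write_trace <- function(trace, path) {
  df <- tibble(
    time_s = trace$time_s, lit = as.integer(trace$lit),
    M = trace$M, C = trace$C, N = trace$N,
    normalized = as.integer(is_normalized(trace))
  )
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  new_compartment_trace(
    tibble(time_s = df$time_s, lit = as.logical(df$lit),
           M = df$M, C = df$C, N = df$N),
    normalized = isTRUE(all(df$normalized == 1))
  )
}

#' Write and read image stacks as multi-page TIFF with a JSON sidecar
#'
#' Frames and channels are stored as 32-bit float TIFF pages (channel
#' fastest, then frame); acquisition metadata (pixel size, frame interval,
#' channel roles) lives in a JSON sidecar `<path>.json`. Metadata can be
#' overridden at read time when the sidecar is absent.
#'
#' @param stack An [image_stack()].
#' @param path TIFF file path.
#' @return `write_stack()` returns `path` invisibly.
#' @export
write_stack <- function(stack, path) {
  d <- dim(stack$data)
  pages <- vector("list", d[3] * d[4])
  i <- 0L
  # TIFF float pages must lie in [0, 1]; store min-max scaled values and
  # keep the affine transform in the sidecar
  rng <- range(stack$data)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  for (f in seq_len(d[4])) {
    for (ch in seq_len(d[3])) {
      i <- i + 1L
      pages[[i]] <- (stack$data[, , ch, f] - rng[1]) / scale
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(pixel_size_um = stack$pixel_size,
         frame_interval_s = stack$frame_interval,
         channel_roles = stack$channel_roles,
         n_channels = d[3], n_frames = d[4],
         intensity_scale = scale, intensity_offset = rng[1]),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_stack
#' @param role_map Optional named character vector mapping sidecar channel
#'   names to roles, or a character vector of roles when no sidecar
#'   exists.
#' @param pixel_size,frame_interval Overrides used when the sidecar is
#'   missing; an error is raised if the pixel size is available from
#'   neither source.
#' @export
read_stack <- function(path, role_map = NULL, pixel_size = NULL,
                       frame_interval = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE) else NULL
  px <- meta$pixel_size_um %||% pixel_size
  dt <- meta$frame_interval_s %||% frame_interval %||% 1
  if (is.null(px)) abort("pixel size missing: provide a sidecar or `pixel_size`")
  roles <- meta$channel_roles %||% role_map
  if (is.null(roles)) abort("channel roles missing: provide a sidecar or `role_map`")
  if (!is.null(role_map) && !is.null(names(role_map))) {
    roles <- unname(role_map[roles])
    if (anyNA(roles)) abort("role_map does not cover all sidecar channel names")
  }
  n_ch <- meta$n_channels %||% length(roles)
  n_fr <- length(pages) / n_ch
  if (n_fr != floor(n_fr)) abort("page count is not a multiple of the channel count")
  d <- dim(pages[[1]])
  data <- array(0, c(d[1], d[2], n_ch, n_fr))
  i <- 0L
  for (f in seq_len(n_fr)) {
    for (ch in seq_len(n_ch)) {
      i <- i + 1L
      data[, , ch, f] <- pages[[i]]
    }
  }
  data <- data * (meta$intensity_scale %||% 1) + (meta$intensity_offset %||% 0)
  image_stack(data, roles, pixel_size = px, frame_interval = dt)
}

#' Write compartment masks as multi-frame 8-bit TIFF
#'
#' One file per compartment (`<stem>_<compartment>.tif`), 255 inside the
#' mask.
#'
#' @param masks A [compartment_masks()].
#' @param stem Output path stem.
#' @return Invisible character vector of written paths.
#' @export
write_masks <- function(masks, stem) {
  paths <- character()
  for (cmp in c("cell", "nucleus", "mitochondria", "cytoplasm")) {
    arr <- masks[[cmp]]
    pages <- lapply(seq_len(dim(arr)[3]), function(f) arr[, , f] * 1)
    p <- paste0(stem, "_", cmp, ".tif")
    tiff::writeTIFF(pages, p, bits.per.sample = 8L)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Export a fit as JSON
#'
#' Writes the tidy parameter table, fit summary and flags of a model fit.
#'
#' @param fit A fit object (`opto_fit`, `frap_fit` or `flip_fit`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  jsonlite::write_json(
    list(
      model = fit$model,
      variant = fit$variant,
      params = fit$params,
      rss = fit$rss,
      n_residuals = fit$n_residuals,
      n_params = fit$n_params,
      aic = if (is.na(fit$aic)) kin_fit_aic(fit) else fit$aic,
      akaike_weight = fit$akaike_weight,
      converged = fit$converged,
      flags = fit$flags
    ),
    path, auto_unbox = TRUE, digits = NA, dataframe = "columns"
  )
  invisible(path)
}

#' Cohort results table
#'
#' Binds per-cell fits into one row per cell with all rates, confidence
#' intervals, AIC and Akaike weight.
#'
#' @param fits A (named) list of fit objects.
#' @return A tibble, one row per fit.
#' @export
cohort_table <- function(fits) {
  if (is.null(names(fits))) names(fits) <- paste0("cell_", seq_along(fits))
  purrr::imap(fits, function(f, nm) {
    wide <- f$params |>
      select("term", "estimate", "conf_low", "conf_high") |>
      tidyr::pivot_wider(names_from = "term",
                         values_from = c("estimate", "conf_low", "conf_high"),
                         names_glue = "{term}_{.value}")
    bind_cols(tibble(cell = nm), wide, glance(f) |> select(-"model"))
  }) |>
    bind_rows()
}

#' Read and write FLIP traces as CSV
#'
#' Columns: `time_s`, `n`, `c`, `site`.
#'
#' @param trace A `flip_trace`.
#' @param path File path.
#' @return `write_flip_trace()` returns `path` invisibly.
#' @export
write_flip_trace <- function(trace, path) {
  readr::write_csv(tibble(
    time_s = trace$time_s, n = trace$n, c = trace$c,
    site = attr(trace, "bleach_site") %||% NA_character_
  ), path)
  invisible(path)
}

#' @rdname write_flip_trace
#' @export
read_flip_trace <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  out <- tibble(time_s = df$time_s, n = df$n, c = df$c)
  attr(out, "bleach_site") <- df$site[1]
  class(out) <- c("flip_trace", class(out))
  out
}

#' Read and write FRAP series as multi-frame TIFF plus JSON sidecar
#'
#' Frames are float TIFF pages; times, pixel size, mask and protocol live
#' in the sidecar `<path>.json`.
#'
#' @param series A `frap_series`.
#' @param path TIFF path.
#' @return `write_frap_series()` returns `path` invisibly.
#' @export
write_frap_series <- function(series, path) {
  rng <- range(series$frames)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  pages <- lapply(seq_len(dim(series$frames)[3]),
                  function(i) (series$frames[, , i] - rng[1]) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  pr <- series$protocol
  jsonlite::write_json(
    list(
      times_s = series$times,
      pixel_size_um = series$geometry$pixel_size,
      mask = apply(series$geometry$mask, 2, as.integer),
      intensity_scale = scale, intensity_offset = rng[1],
      protocol = pr[!vapply(pr, is.null, logical(1))]
    ),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_frap_series
#' @export
read_frap_series <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  frames <- simplify2array(pages) * (meta$intensity_scale %||% 1)
  mask <- matrix(as.logical(meta$mask), nrow(meta$mask), ncol(meta$mask))
  pr_args <- meta$protocol
  pr <- do.call(bleach_protocol, pr_args[names(pr_args) %in% names(formals(bleach_protocol))])
  structure(
    list(frames = frames, times = meta$times_s,
         geometry = frap_geometry(mask, pixel_size = meta$pixel_size_um),
         protocol = pr, params = NULL),
    class = "frap_series"
  )
}
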