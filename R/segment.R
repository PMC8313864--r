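#' Window profile for percentile-projection segmentation
#'
#' Pairs the number of seeding points with the moving percentile-projection
#' window length: a movie of `n` frames and `n_seeds` seeding points is
#' divided into `n_seeds` windows of `floor(n / n_seeds)` frames (the last
#' window absorbs any remainder); each window yields one percentile
#' projection per channel, and the seed frame of a window sits at its
#' centre. Thresholds defined at the seeds are interpolated across frames.
#'
#' @param n_seeds Number of seeding points (>= 1).
#' @param percentiles Named numeric vector of projection percentiles
#'   (0-100) for `hybrid`, `nucleus`, `mitochondria`.
#' @param thresholds Optional list of per-seed thresholds (one numeric
#'   vector of length `n_seeds` per compartment); when omitted, thresholds
#'   are set automatically by Otsu's method on each seed projection.
#' @return A `window_profile` object.
#' @export
window_profile <- function(n_seeds = 2,
                           percentiles = c(hybrid = 90, nucleus = 50, mitochondria = 90),
                           thresholds = NULL) {
  if (n_seeds < 1) abort("n_seeds must be >= 1")
  if (any(percentiles < 0 | percentiles > 100)) abort("percentiles must lie in [0, 100]")
  structure(
    list(n_seeds = as.integer(n_seeds), percentiles = percentiles,
         thresholds = thresholds),
    class = "window_profile"
  )
}

# Frame windows of a profile: tibble(start, end, seed_frame). Last window
# absorbs the remainder when n_frames / n_seeds is not an integer.
profile_windows <- function(n_seeds, n_frames) {
  if (n_seeds > n_frames) abort("more seeds than frames")
  len <- n_frames %/% n_seeds
  start <- (seq_len(n_seeds) - 1L) * len + 1L
  end <- c(start[-1L] - 1L, n_frames)
  tibble(
    start = start, end = end,
    seed_frame = floor((start + end) / 2)
  )
}

#' Percentile projection over temporal windows
#'
#' Divides the movie into consecutive windows and replaces every frame in a
#' window by that window's per-pixel percentile across frames — a denoised
#' image used for thresholding. A window length of half the movie (two
#' seeds) trades robustness to noise against sensitivity to morphological
#' change. For a 100-frame movie with two seeds the windows are frames
#' 1-50 and 51-100.
#'
#' @param channel Numeric 3D array (rows x cols x frames).
#' @param window_len Window length in frames (1 to `n_frames`); the last
#'   window absorbs any remainder.
#' @param percentile Percentile in `[0, 100]`; 100 is the per-pixel
#'   maximum.
#' @return A list with `projections` (one matrix per window) and `windows`
#'   (tibble of frame ranges).
#' @export
percentile_projection <- function(channel, window_len, percentile) {
  if (percentile < 0 || percentile > 100) abort("percentile must lie in [0, 100]")
  nf <- dim(channel)[3]
  if (window_len < 1 || window_len > nf) abort("window_len must be in [1, n_frames]")
  n_win <- max(1L, nf %/% window_len)
  wins <- profile_windows(n_win, nf)
  projections <- purrr::pmap(wins, function(start, end, seed_frame) {
    window_quantile(channel[, , start:end, drop = FALSE], percentile / 100)
  })
  list(projections = projections, windows = wins)
}

# Per-pixel quantile across the third dimension. type-7 quantile on sorted
# values, vectorised across pixels.
window_quantile <- function(arr, prob) {
  d <- dim(arr)
  nf <- d[3]
  if (nf == 1L) return(arr[, , 1])
  m <- matrix(arr, nrow = d[1] * d[2], ncol = nf)
  sm <- t(apply(m, 1, sort))
  hh <- (nf - 1) * prob + 1
  lo <- floor(hh); hi <- ceiling(hh)
  v <- sm[, lo] + (hh - lo) * (sm[, hi] - sm[, lo])
  matrix(v, d[1], d[2])
}

#' Hybrid whole-cell channel
#'
#' Builds a single channel for whole-cell segmentation: per frame, the
#' per-pixel maximum across the nuclear, mitochondrial and protein channels
#' after each channel has been min-max rescaled over the movie (so one
#' detector gain cannot dominate). Robust to a weak or heterogeneous
#' protein channel.
#'
#' @param stack An [image_stack()] with all three roles.
#' @return Numeric 3D array (rows x cols x frames).
#' @export
build_hybrid_channel <- function(stack) {
  chans <- lapply(c("protein", "mitochondria", "nucleus"), function(role) {
    ch <- stack_channel(stack, role)
    rng <- range(ch)
    if (diff(rng) > 0) (ch - rng[1]) / diff(rng) else ch * 0
  })
  pmax(chans[[1]], chans[[2]], chans[[3]])
}

#' Interpolate per-seed thresholds across frames
#'
#' Thresholds defined at the (equidistant) seeding frames are linearly
#' interpolated between consecutive seeds and held constant before the
#' first and after the last seed. For a 100-frame movie with seeds at
#' frames 25 and 75, frames 1-25 take the first seed's value, frame 50 the
#' midpoint, and frames 75-100 the last seed's value.
#'
#' @param seed_frames Integer vector of seed frame indices (sorted).
#' @param seed_values Numeric thresholds at the seeds.
#' @param n_frames Total number of frames.
#' @return Numeric vector of per-frame thresholds.
#' @export
interpolate_thresholds <- function(seed_frames, seed_values, n_frames) {
  if (is.unsorted(seed_frames, strictly = TRUE)) abort("seed frames must be sorted")
  if (length(seed_frames) != length(seed_values)) abort("one value per seed required")
  if (length(seed_frames) == 1L) return(rep(seed_values, n_frames))
  approx(seed_frames, seed_values, xout = seq_len(n_frames), rule = 2)$y
}

largest_component <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lv <- as.integer(lab)
  tab <- tabulate(lv[lv > 0])
  if (length(tab) == 0L) return(mask & FALSE)
  best <- which(tab == max(tab))
  if (length(best) > 1L) {
    # tie: component centroid closest to the image centre
    ctr <- (dim(mask) + 1) / 2
    d2 <- vapply(best, function(b) {
      px <- which(matrix(lv, nrow(mask), ncol(mask)) == b, arr.ind = TRUE)
      sum((colMeans(px) - ctr)^2)
    }, numeric(1))
    best <- best[which.min(d2)]
  }
  matrix(lv, nrow(mask), ncol(mask)) == best
}

#' Segment compartments from a multi-channel movie
#'
#' Runs the percentile-projection segmentation engine: a hybrid channel is
#' built for the whole-cell boundary; the nuclear and mitochondrial
#' channels are projected per window at their own percentiles; per-seed
#' thresholds (supplied, or Otsu on each seed projection) are interpolated
#' across frames and applied to the projection covering each frame. The
#' cell is the largest connected thresholded component of the hybrid
#' projection (hole-filled), the nucleus the largest thresholded component
#' inside the cell, mitochondria the thresholded mitochondrial pixels
#' inside the cell and outside the nucleus, and the cytoplasm is the cell
#' minus nucleus and mitochondria.
#'
#' @param stack An [image_stack()].
#' @param profile A [window_profile()].
#' @return A [compartment_masks()] object; interpolated thresholds are
#'   attached as attribute `thresholds`.
#' @export
segment_compartments <- function(stack, profile) {
  nf <- n_frames(stack)
  wins <- profile_windows(profile$n_seeds, nf)
  window_len <- wins$end[1] - wins$start[1] + 1L
  chans <- list(
    hybrid = build_hybrid_channel(stack),
    nucleus = stack_channel(stack, "nucleus"),
    mitochondria = stack_channel(stack, "mitochondria")
  )
  projs <- lapply(names(chans), function(nm) {
    percentile_projection(chans[[nm]], window_len, profile$percentiles[[nm]])
  })
  names(projs) <- names(chans)
  # per-seed thresholds: supplied or automatic Otsu on each seed projection
  thr_seed <- profile$thresholds
  if (is.null(thr_seed)) {
    thr_seed <- lapply(names(projs), function(nm) {
      vapply(projs[[nm]]$projections, function(pr) {
        rng <- range(pr)
        if (diff(rng) <= 0) return(rng[1] + 1)  # degenerate: nothing passes
        x <- (pr - rng[1]) / diff(rng)
        if (nm == "hybrid") {
          # cell-vs-background split on log-compressed intensities: robust
          # when one compartment (e.g. a bright nucleus) dominates the
          # hybrid's bright tail and would otherwise pull Otsu's threshold
          # above the dim cytoplasm
          xl <- log1p(100 * x)
          tl <- as.numeric(EBImage::otsu(EBImage::Image(xl / max(xl)),
                                         range = c(0, 1))) * max(xl)
          (expm1(tl) / 100) * diff(rng) + rng[1]
        } else {
          as.numeric(EBImage::otsu(EBImage::Image(x), range = c(0, 1))) *
            diff(rng) + rng[1]
        }
      }, numeric(1))
    })
    names(thr_seed) <- names(projs)
  }
  thr_frames <- lapply(names(projs), function(nm) {
    interpolate_thresholds(wins$seed_frame, thr_seed[[nm]], nf)
  })
  names(thr_frames) <- names(projs)
  # window index covering each frame
  win_of <- rep(seq_len(nrow(wins)), wins$end - wins$start + 1L)
  dims <- dim(stack$data)[1:2]
  cell <- nucleus <- mito <- array(FALSE, c(dims, nf))
  for (f in seq_len(nf)) {
    w <- win_of[f]
    cell_f <- projs$hybrid$projections[[w]] > thr_frames$hybrid[f]
    if (!any(cell_f)) abort(sprintf("empty cell mask at frame %d", f))
    cell_f <- largest_component(cell_f)
    cell_f <- as.matrix(EBImage::fillHull(EBImage::Image(cell_f * 1))) > 0.5
    nuc_f <- (projs$nucleus$projections[[w]] > thr_frames$nucleus[f]) & cell_f
    if (any(nuc_f)) nuc_f <- largest_component(nuc_f)
    mito_f <- (projs$mitochondria$projections[[w]] > thr_frames$mitochondria[f]) &
      cell_f & !nuc_f
    cell[, , f] <- cell_f
    nucleus[, , f] <- nuc_f
    mito[, , f] <- mito_f
  }
  out <- compartment_masks(cell, nucleus, mito)
  attr(out, "thresholds") <- thr_frames
  attr(out, "windows") <- wins
  out
}

#' Extract compartment intensity signals
#'
#' Sums the protein channel over the mitochondrial, cytoplasmic and nuclear
#' masks frame by frame. A compartment empty in some frame yields `NA`
#' (recorded as missing, not zero).
#'
#' @param stack An [image_stack()].
#' @param masks A [compartment_masks()] congruent with the stack.
#' @param schedule Optional [light_schedule()] supplying `time_s`/`lit`
#'   columns; defaults to the stack's frame interval, all dark.
#' @return A raw (non-normalised) `compartment_trace` tibble with columns
#'   `time_s`, `lit`, `M`, `C`, `N`.
#' @export
extract_signals <- function(stack, masks, schedule = NULL) {
  nf <- n_frames(stack)
  if (dim(masks$cell)[3] != nf) abort("masks and stack are not congruent")
  protein <- stack_channel(stack, "protein")
  sum_or_na <- function(img, m) if (any(m)) sum(img[m]) else NA_real_
  M <- C <- N <- numeric(nf)
  for (f in seq_len(nf)) {
    img <- protein[, , f]
    M[f] <- sum_or_na(img, masks$mitochondria[, , f])
    C[f] <- sum_or_na(img, masks$cytoplasm[, , f])
    N[f] <- sum_or_na(img, masks$nucleus[, , f])
  }
  if (is.null(schedule)) {
    schedule <- light_schedule((seq_len(nf) - 1L) * stack$frame_interval,
                               rep(FALSE, nf))
  }
  new_compartment_trace(
    tibble(time_s = schedule$time_s, lit = schedule$lit, M = M, C = C, N = N),
    normalized = FALSE
  )
}

#' Compare dynamic and constant thresholding by fit residuals
#'
#' Segments and fits a movie under a dynamic (multi-seed, interpolated
#' thresholds) and a constant (single-seed) window profile, and reports the
#' fitted residual sum for each so the mode giving smaller fitting errors
#' can be selected.
#'
#' @param stack An [image_stack()].
#' @param schedule A [light_schedule()] for the movie.
#' @param dynamic_profile,constant_profile [window_profile()] objects; the
#'   constant profile must have a single seed.
#' @param variant Passed to [fit_opto_model()].
#' @return A tibble with `mode`, `n_seeds`, `rss`.
#' @export
compare_threshold_modes <- function(stack, schedule,
                                    dynamic_profile = window_profile(n_seeds = 2),
                                    constant_profile = window_profile(n_seeds = 1),
                                    variant = model_variant()) {
  run <- function(profile, mode) {
    masks <- segment_compartments(stack, profile)
    trace <- extract_signals(stack, masks, schedule)
    norm <- bilinear_normalise(trace, schedule)
    fit <- fit_opto_model(norm, variant)
    tibble(mode = mode, n_seeds = profile$n_seeds, rss = fit$rss)
  }
  bind_rows(
    run(dynamic_profile, "dynamic"),
    run(constant_profile, "constant")
  )
}
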