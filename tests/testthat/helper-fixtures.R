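# Shared fixtures: small, built in code at test time.

# Reference dark-state binding medians and diffusivity used across tests
# (the +LOV dark condition), plus plausible lit-state rates.
ref_rates <- function() {
  rate_params(
    k_imp = 0.002, k_exp = 0.002,
    k_on_unlit = 0.027, k_off_unlit = 0.019,
    k_on_lit = 0.03, k_off_lit = 0.2
  )
}

# Short opto schedule for fast fitting tests: same phase structure as the
# standard protocol, fewer frames.
short_opto_schedule <- function(n_pre = 5, n_lit = 60, n_post = 60, dt = 4) {
  schedule_from_blocks(
    list(
      list(n_frames = n_pre, lit = FALSE),
      list(n_frames = n_lit, lit = TRUE),
      list(n_frames = n_post, lit = FALSE)
    ),
    frame_interval_s = dt
  )
}

# Small elliptical FRAP geometry.
small_frap_geometry <- function(size = 64, pixel_size = 0.13) {
  ctr <- c(size, size) / 2 + 0.5
  frap_geometry(ellipse_mask_test(size, ctr, c(0.45, 0.38) * size),
                pixel_size = pixel_size)
}

ellipse_mask_test <- function(size, center, axes) {
  rr <- matrix(seq_len(size), size, size)
  cc <- t(rr)
  ((rr - center[1]) / axes[1])^2 + ((cc - center[2]) / axes[2])^2 <= 1
}

# Small synthetic movie spec used by segmentation / end-to-end tests.
small_cell_spec <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(size = 96, pixel_size = 0.2,
         n_filaments = 7, filament_length = 80,
         expression_scale = 2000, seed = seed),
    list(...)
  )
  do.call(synthetic_cell_spec, args)
}
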