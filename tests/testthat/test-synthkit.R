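test_that("cell geometry is deterministic, nested and within coverage bounds", {
  spec <- small_cell_spec(seed = 12)
  g1 <- make_cell_geometry(spec)
  g2 <- make_cell_geometry(spec)
  expect_identical(g1$mitochondria, g2$mitochondria)
  expect_false(any(g1$nucleus & g1$mitochondria))
  expect_false(any(g1$mitochondria & !g1$cell))
  expect_false(any(g1$nucleus & !g1$cell))
  # filament coverage of the cytoplasm sits in a plausible band
  cyto <- g1$cell & !g1$nucleus
  cover <- sum(g1$mitochondria) / sum(cyto)
  expect_gt(cover, 0.02)
  expect_lt(cover, 0.5)
  # a different seed gives a different network
  g3 <- make_cell_geometry(small_cell_spec(seed = 13))
  expect_false(identical(g1$mitochondria, g3$mitochondria))

  expect_error(synthetic_cell_spec(size = 96, nucleus_axes = c(45, 45)),
               "inside the cell")
})

test_that("noiseless, bleach-free rendering distributes the trace exactly", {
  spec <- small_cell_spec(seed = 2, noise = "none",
                          bleach_slopes = c(release = 0, recovery = 0))
  sched <- short_opto_schedule(2, 10, 10)
  movie <- synthetic_movie(ref_rates(), sched, spec)
  gt <- movie$ground_truth
  protein <- movie$stack$data[, , 1, ]
  m_mask <- gt$masks$mitochondria[, , 1]
  c_mask <- gt$masks$cell[, , 1] & !gt$masks$nucleus[, , 1] & !m_mask
  n_mask <- gt$masks$nucleus[, , 1]
  sums <- t(vapply(seq_len(dim(protein)[3]), function(f) {
    c(sum(protein[, , f][m_mask]), sum(protein[, , f][c_mask]),
      sum(protein[, , f][n_mask]))
  }, numeric(3)))
  # channel sums exactly proportional to (M, C, N)
  k <- sums[1, 1] / gt$trace$M[1]
  expect_equal(sums[, 1], gt$trace$M * k, tolerance = 1e-12)
  expect_equal(sums[, 2], gt$trace$C * k, tolerance = 1e-12)
  expect_equal(sums[, 3], gt$trace$N * k, tolerance = 1e-12)
})

test_that("rendering is reproducible under a fixed seed and varies across seeds", {
  spec <- small_cell_spec(seed = 4)
  sched <- short_opto_schedule(2, 5, 5)
  m1 <- synthetic_movie(ref_rates(), sched, spec)
  m2 <- synthetic_movie(ref_rates(), sched, spec)
  expect_identical(m1$stack$data, m2$stack$data)
  m3 <- synthetic_movie(ref_rates(), sched, small_cell_spec(seed = 5))
  expect_false(identical(m1$stack$data, m3$stack$data))
})

test_that("render_movie rejects mismatched trace and geometry", {
  spec <- small_cell_spec(seed = 2)
  geom <- make_cell_geometry(spec)
  tr <- simulate_trace(ref_rates(), short_opto_schedule(2, 5, 5))
  bad_spec <- spec
  bad_spec$bleach_slopes <- c(release = 1, recovery = 1)  # drives negative
  expect_error(render_movie(geom, tr, bad_spec), "non-positive")
})

test_that("regional gain map is 256 for no change and follows the formula", {
  # post = pre: gain 256 everywhere, 8-bit export saturates at 255
  spec <- small_cell_spec(seed = 6, noise = "none",
                          bleach_slopes = c(release = 0, recovery = 0))
  sched <- schedule_from_blocks(
    list(list(n_frames = 5, lit = FALSE), list(n_frames = 60, lit = TRUE)), 4)
  no_change <- rate_params(0, 1e-9, 0.027, 0.019, 0.027, 0.019)
  movie <- synthetic_movie(no_change, sched, spec)
  gm <- regional_gain_map(movie$stack, movie$schedule)
  inside <- !is.na(gm$gain) & gm$gain > 0
  expect_true(all(gm$gain[inside] == 256))
  expect_true(all(gm$gain_8bit[inside] == 255))

  # direct formula: pre mean 200, post mean 100 -> 128
  size <- 16
  d <- array(0, c(size, size, 1, 60))
  d[, , 1, 1:5] <- 200
  d[, , 1, 6:60] <- 100
  stack <- image_stack(d, "protein", 0.2, 4)
  sched2 <- light_schedule((0:59) * 4, c(rep(FALSE, 5), rep(TRUE, 55)))
  gm2 <- regional_gain_map(stack, sched2)
  expect_true(all(gm2$gain == 128))

  expect_error(regional_gain_map(stack, light_schedule((0:59) * 4, rep(FALSE, 60))),
               "lit")
})

test_that("uniform release yields a spatially flat gain map at the noise floor", {
  spec <- small_cell_spec(seed = 8, expression_scale = 4000)
  sched <- schedule_from_blocks(
    list(list(n_frames = 5, lit = FALSE), list(n_frames = 60, lit = TRUE)), 4)
  movie <- synthetic_movie(ref_rates(), sched, spec)
  gm <- regional_gain_map(movie$stack, movie$schedule)
  # CV over the cytoplasm (exclude mask edges where compartments mix)
  cyto <- optoshuttle:::bin2(
    (movie$ground_truth$masks$cell[, , 1] &
       !movie$ground_truth$masks$nucleus[, , 1] &
       !movie$ground_truth$masks$mitochondria[, , 1]) * 1) == 1
  vals <- gm$gain[cyto & !is.na(gm$gain)]
  expect_lt(sd(vals) / mean(vals), 0.1)
})

test_that("average_pulse_response aligns replicates and validates spacing", {
  sched <- default_protocols("opto-staggered")
  # three identical post-pulse segments: zero sd
  resp <- numeric(nrow(sched))
  pulses <- c(100, 120, 140, 160)
  for (p in pulses) {
    idx <- p + 0:19
    idx <- idx[idx <= nrow(sched)]
    resp[idx] <- exp(-0.2 * (seq_along(idx) - 1))
  }
  df <- tibble::tibble(frame = seq_len(nrow(sched)), region_a = resp)
  out <- average_pulse_response(df, sched)
  # the final pulse sits on the last frame; the three full replicates are
  # identical, so the spread is zero
  expect_true(all(out$response$n == 3))
  expect_true(all(out$response$sd < 1e-12))
  expect_equal(out$summary$peak, 1)
  expect_equal(out$summary$decline_rate, 0.2, tolerance = 1e-6)

  # mean of simple segments
  df2 <- df
  vals <- list(c(1, 2, 3), c(3, 2, 1), c(2, 2, 2))
  for (i in 1:3) df2$region_a[pulses[i] + 0:2] <- vals[[i]]
  df2$region_a[pulses[4]] <- 2  # truncated final replicate is dropped
  out2 <- average_pulse_response(df2, sched, n_post = 3)
  expect_equal(out2$response$mean, c(2, 2, 2))

  # single pulse or unequal spacing errors
  one_pulse <- schedule_from_blocks(
    list(list(n_frames = 10, lit = FALSE), list(n_frames = 1, lit = TRUE),
         list(n_frames = 10, lit = FALSE)), 4)
  expect_error(average_pulse_response(df[1:21, ], one_pulse), "at least 2")
  uneven <- schedule_from_blocks(
    list(list(n_frames = 5, lit = FALSE), list(n_frames = 1, lit = TRUE),
         list(n_frames = 8, lit = FALSE), list(n_frames = 1, lit = TRUE),
         list(n_frames = 3, lit = FALSE), list(n_frames = 1, lit = TRUE),
         list(n_frames = 5, lit = FALSE)), 4)
  expect_error(average_pulse_response(df[1:24, ], uneven), "spacing")
})

test_that("heterogeneous release mode produces a spatial gradient in the gain map", {
  spec_het <- small_cell_spec(seed = 10, expression_scale = 4000,
                              heterogeneous = TRUE)
  sched <- schedule_from_blocks(
    list(list(n_frames = 5, lit = FALSE), list(n_frames = 60, lit = TRUE)), 4)
  movie <- synthetic_movie(ref_rates(), sched, spec_het)
  gm <- regional_gain_map(movie$stack, movie$schedule)
  cyto <- optoshuttle:::bin2(
    (movie$ground_truth$masks$cell[, , 1] &
       !movie$ground_truth$masks$nucleus[, , 1] &
       !movie$ground_truth$masks$mitochondria[, , 1]) * 1) == 1
  g <- gm$gain
  half <- ncol(g) %/% 2
  left <- mean(g[, 1:half][cyto[, 1:half]], na.rm = TRUE)
  right <- mean(g[, (half + 1):ncol(g)][cyto[, (half + 1):ncol(g)]], na.rm = TRUE)
  expect_gt(abs(right - left), 5)
})
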