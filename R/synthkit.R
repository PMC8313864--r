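#' Specification of a synthetic cell movie
#'
#' Describes the geometry, optics and noise of a rendered test movie: an
#' elliptical epithelial-like cell containing an offset elliptical nucleus
#' and a filamentous mitochondrial network confined to the cytoplasm, a
#' protein channel whose compartment totals follow the shuttling ODE,
#' per-phase linear photobleaching, and Poisson-Gaussian detection noise.
#'
#' @param size Image size in pixels (square).
#' @param pixel_size Pixel size, micrometres.
#' @param cell_axes Semi-axes of the cell ellipse, pixels.
#' @param nucleus_axes Semi-axes of the nucleus ellipse, pixels.
#' @param nucleus_offset Offset `c(row, col)` of the nucleus centre from
#'   the cell centre, pixels (nucleus must remain strictly inside the
#'   cell).
#' @param n_filaments Number of mitochondrial filaments.
#' @param filament_length Random-walk steps per filament.
#' @param filament_width Dilation radius of the filaments, pixels.
#' @param expression_scale Mean photon count scale of the protein channel
#'   (a.u.).
#' @param noise One of `"poisson-gaussian"` (default) or `"none"`;
#'   controlled by `read_noise_sd` and the photon statistics of
#'   `expression_scale`.
#' @param read_noise_sd Gaussian read-noise standard deviation (a.u.).
#' @param bleach_slopes Per-phase linear bleach slopes (fraction of initial
#'   intensity lost per second) as `c(release =, recovery =)`; `c(0, 0)`
#'   disables bleaching.
#' @param heterogeneous Logical: add a smooth left-right gradient in local
#'   release amplitude across the cytoplasm (exercises regional analyses).
#' @param seed Integer seed governing geometry and noise.
#' @return A `synthetic_cell_spec` object.
#' @export
synthetic_cell_spec <- function(size = 256, pixel_size = 0.2,
                                cell_axes = NULL, nucleus_axes = NULL,
                                nucleus_offset = NULL,
                                n_filaments = 14, filament_length = 180,
                                filament_width = 1,
                                expression_scale = 2000,
                                noise = c("poisson-gaussian", "none"),
                                read_noise_sd = 2,
                                bleach_slopes = c(release = 4e-4, recovery = 1.5e-4),
                                heterogeneous = FALSE,
                                seed = 1) {
  noise <- match.arg(noise)
  cell_axes <- cell_axes %||% c(0.42, 0.34) * size
  nucleus_axes <- nucleus_axes %||% c(0.16, 0.13) * size
  nucleus_offset <- nucleus_offset %||% c(0.04, -0.06) * size
  # nucleus strictly inside the cell: bounding check on the offset ellipse
  if (any(abs(nucleus_offset) + nucleus_axes >= cell_axes)) {
    abort("nucleus must lie strictly inside the cell")
  }
  structure(
    list(size = as.integer(size), pixel_size = pixel_size,
         cell_axes = cell_axes, nucleus_axes = nucleus_axes,
         nucleus_offset = nucleus_offset,
         n_filaments = n_filaments, filament_length = filament_length,
         filament_width = filament_width,
         expression_scale = expression_scale, noise = noise,
         read_noise_sd = read_noise_sd, bleach_slopes = bleach_slopes,
         heterogeneous = heterogeneous, seed = seed),
    class = "synthetic_cell_spec"
  )
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

ellipse_mask <- function(size, center, axes) {
  rr <- matrix(seq_len(size), size, size)
  cc <- t(rr)
  ((rr - center[1]) / axes[1])^2 + ((cc - center[2]) / axes[2])^2 <= 1
}

#' Ground-truth cell geometry
#'
#' Renders the static ground-truth compartment masks of a synthetic cell:
#' elliptical cell and nucleus, and a mitochondrial network generated by
#' seeded persistent random walks within the cytoplasm (dilated to the
#' configured filament width). Deterministic for a fixed seed.
#'
#' @param spec A [synthetic_cell_spec()].
#' @return A single-frame [compartment_masks()] (3D arrays with one
#'   frame).
#' @export
make_cell_geometry <- function(spec) {
  size <- spec$size
  ctr <- c(size, size) / 2 + 0.5
  cell <- ellipse_mask(size, ctr, spec$cell_axes)
  nucleus <- ellipse_mask(size, ctr + spec$nucleus_offset, spec$nucleus_axes)
  if (any(nucleus & !cell)) abort("nucleus must lie strictly inside the cell")
  cyto_allowed <- cell & !nucleus
  mito <- with_seed(spec$seed, {
    m <- matrix(FALSE, size, size)
    allowed_idx <- which(cyto_allowed, arr.ind = TRUE)
    for (fil in seq_len(spec$n_filaments)) {
      p <- allowed_idx[sample.int(nrow(allowed_idx), 1L), ]
      ang <- runif(1, 0, 2 * pi)
      for (s in seq_len(spec$filament_length)) {
        ang <- ang + rnorm(1, sd = 0.35)  # persistent, tortuous walk
        q <- round(p + c(cos(ang), sin(ang)))
        if (q[1] < 1 || q[1] > size || q[2] < 1 || q[2] > size ||
            !cyto_allowed[q[1], q[2]]) {
          ang <- ang + pi / 2  # deflect off boundaries
          next
        }
        p <- q
        m[p[1], p[2]] <- TRUE
      }
    }
    if (spec$filament_width > 0) {
      brush <- EBImage::makeBrush(2 * spec$filament_width + 1, "disc")
      m <- as.matrix(EBImage::dilate(EBImage::Image(m * 1), brush)) > 0.5
    }
    m & cyto_allowed
  })
  compartment_masks(
    cell = array(cell, c(size, size, 1)),
    nucleus = array(nucleus, c(size, size, 1)),
    mitochondria = array(mito, c(size, size, 1))
  )
}

#' Render a synthetic multi-channel movie
#'
#' Distributes the compartment totals of a trace over the ground-truth
#' geometry: the protein channel spreads `M`, `C` and `N` uniformly over
#' the mitochondrial, cytoplasmic and nuclear pixels of each frame; the
#' mitochondrial and nuclear channels are static textures. Per-phase linear
#' photobleaching multiplies all channels, and Poisson-Gaussian detection
#' noise is applied with the spec's seed. The returned ground-truth bundle
#' makes every downstream test self-contained.
#'
#' @param geometry A single-frame [compartment_masks()] from
#'   [make_cell_geometry()].
#' @param trace A `compartment_trace` giving the per-frame proportions and
#'   light states.
#' @param spec The [synthetic_cell_spec()] used for the geometry.
#' @return A list with `stack` (an [image_stack()]), `schedule`, and
#'   `ground_truth` (list: `masks`, `trace`, `spec`).
#' @export
render_movie <- function(geometry, trace, spec) {
  nf <- nrow(trace)
  size <- spec$size
  cell <- geometry$cell[, , 1]
  nuc <- geometry$nucleus[, , 1]
  mito <- geometry$mitochondria[, , 1]
  cyto <- cell & !nuc & !mito
  n_mito <- sum(mito); n_cyto <- sum(cyto); n_nuc <- sum(nuc)
  if (n_mito == 0 || n_cyto == 0 || n_nuc == 0) abort("geometry has an empty compartment")
  # per-phase linear bleach factor on all channels
  lit <- trace$lit
  times <- trace$time_s
  bleach <- rep(1, nf)
  if (any(lit) && any(spec$bleach_slopes != 0)) {
    last_lit <- max(which(lit))
    rel <- seq_len(min(last_lit, nf))
    bleach[rel] <- 1 - spec$bleach_slopes[["release"]] * (times[rel] - times[1])
    if (last_lit < nf) {
      rec <- seq(last_lit + 1L, nf)
      b0 <- bleach[last_lit] - spec$bleach_slopes[["release"]] *
        (times[last_lit + 1L] - times[last_lit])
      bleach[rec] <- b0 - spec$bleach_slopes[["recovery"]] * (times[rec] - times[last_lit + 1L])
    }
    if (any(bleach <= 0)) abort("bleach slopes drive intensity non-positive")
  }
  # optional spatial heterogeneity of release amplitude (left-right ramp)
  het <- matrix(1, size, size)
  if (isTRUE(spec$heterogeneous)) {
    het <- matrix(rep(seq(0.6, 1.4, length.out = size), each = size), size, size)
  }
  mito_tex <- matrix(0, size, size); mito_tex[mito] <- 1
  nuc_tex <- matrix(0, size, size); nuc_tex[nuc] <- 1
  data <- array(0, c(size, size, 3, nf))
  roles <- c("protein", "mitochondria", "nucleus")
  es <- spec$expression_scale
  with_seed(spec$seed + 1L, {
    for (f in seq_len(nf)) {
      protein <- matrix(0, size, size)
      protein[mito] <- trace$M[f] / n_mito
      if (isTRUE(spec$heterogeneous)) {
        # region-specific release amplitude: the baseline cytoplasmic level
        # is uniform but the light-induced change is modulated by the ramp
        dC <- trace$C[f] - trace$C[1]
        protein[cyto] <- (trace$C[1] + het[cyto] * dC) / n_cyto
      } else {
        protein[cyto] <- trace$C[f] / n_cyto
      }
      protein[nuc] <- trace$N[f] / n_nuc
      protein <- protein * es * n_cyto  # photons per pixel scale
      mito_ch <- mito_tex * es * 0.5
      nuc_ch <- nuc_tex * es * 0.5
      imgs <- list(protein, mito_ch, nuc_ch)
      for (ch in 1:3) {
        img <- imgs[[ch]] * bleach[f]
        if (spec$noise == "poisson-gaussian") {
          pos <- img > 0
          img[pos] <- rpois(sum(pos), img[pos])
          img <- img + rnorm(length(img), sd = spec$read_noise_sd)
        }
        data[, , ch, f] <- img
      }
    }
  })
  stack <- image_stack(data, roles, pixel_size = spec$pixel_size,
                       frame_interval = if (nf > 1) diff(times)[1] else 1)
  schedule <- light_schedule(times, lit)
  list(
    stack = stack,
    schedule = schedule,
    ground_truth = list(masks = geometry, trace = trace, spec = spec)
  )
}

#' One-call synthetic opto-release movie
#'
#' Convenience wrapper: dark steady state, the given rates and protocol,
#' geometry and rendering from a single spec.
#'
#' @param rates A [rate_params()].
#' @param schedule A [light_schedule()]; default the standard release/
#'   recovery protocol.
#' @param spec A [synthetic_cell_spec()].
#' @return As [render_movie()], with the generating `rates` added to the
#'   ground truth.
#' @export
synthetic_movie <- function(rates, schedule = default_protocols("opto-standard"),
                            spec = synthetic_cell_spec()) {
  geometry <- make_cell_geometry(spec)
  trace <- simulate_trace(rates, schedule)
  out <- render_movie(geometry, trace, spec)
  out$ground_truth$rates <- rates
  out
}
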