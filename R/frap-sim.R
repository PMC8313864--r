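#' FRAP geometry
#'
#' The cytoplasmic region over which the reaction-diffusion model is solved:
#' a boolean pixel mask, the pixel size and an optional per-pixel density of
#' mitochondrial binding sites. With the default uniform density the
#' effective association rate is a single constant
#' (`k_on = r_on * S_M`, valid when binding sites greatly exceed protein).
#'
#' @param mask Logical matrix (rows x cols): cytoplasm pixels.
#' @param pixel_size Pixel edge length, micrometres.
#' @param binding_density Optional non-negative matrix of relative binding
#'   site density (zero outside the mask); default uniform (1 on the mask).
#' @return A `frap_geometry` object.
#' @export
frap_geometry <- function(mask, pixel_size = 0.13, binding_density = NULL) {
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  if (!any(mask)) abort("mask must be non-empty")
  if (is.null(binding_density)) {
    binding_density <- matrix(0, nrow(mask), ncol(mask))
    binding_density[mask] <- 1
  } else {
    binding_density <- as.matrix(binding_density)
    if (any(binding_density < 0)) abort("binding density must be non-negative")
    binding_density[!mask] <- 0
  }
  structure(
    list(mask = mask, pixel_size = pixel_size,
         binding_density = binding_density),
    class = "frap_geometry"
  )
}

#' FRAP model parameters
#'
#' @param D_c Cytoplasmic diffusivity of free protein, um^2 s^-1.
#' @param k_on Effective mitochondrial association rate constant, s^-1.
#' @param k_off Dissociation rate constant, s^-1.
#' @param alpha Photobleaching sensitivity of the probe, per relative laser
#'   intensity per second.
#' @return A `frap_params` object.
#' @export
frap_params <- function(D_c, k_on, k_off, alpha) {
  p <- list(D_c = D_c, k_on = k_on, k_off = k_off, alpha = alpha)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || is.na(p[[nm]]) || p[[nm]] < 0) {
      abort(paste0("frap parameter `", nm, "` must be a single non-negative number"))
    }
  }
  structure(p, class = "frap_params")
}

#' Bleach protocol
#'
#' Describes the photobleaching pulse and imaging illumination of a FRAP
#' acquisition: the spatial laser profile (relative intensity in `[0, 1]`),
#' the bleach pulse duration, the frame interval and the (uniform, low)
#' imaging intensity responsible for recovery-phase bleaching.
#'
#' @param roi_center Pixel coordinates `c(row, col)` of the bleach ROI
#'   centre (default: image centre).
#' @param roi_radius ROI radius in pixels.
#' @param profile_shape `"empirical-like"` (disk with Gaussian edge,
#'   standing in for fixed-cell calibration profiles) or `"hard-disk"`.
#' @param bleach_duration Bleach pulse length, seconds.
#' @param frame_interval Frame spacing, seconds (0.25 s without the LOV
#'   partner, 0.5 s with it).
#' @param imaging_intensity Relative imaging illumination between bleaches.
#' @param n_prebleach,n_postbleach Frames acquired before/after the pulse.
#' @param edge_sigma Gaussian edge width of the empirical-like profile, px.
#' @return A `bleach_protocol` object.
#' @export
bleach_protocol <- function(roi_center = NULL, roi_radius = 10,
                            profile_shape = c("empirical-like", "hard-disk"),
                            bleach_duration = 0.2, frame_interval = 0.5,
                            imaging_intensity = 0.05,
                            n_prebleach = 5, n_postbleach = 80,
                            edge_sigma = 2) {
  profile_shape <- match.arg(profile_shape)
  structure(
    list(roi_center = roi_center, roi_radius = roi_radius,
         profile_shape = profile_shape, bleach_duration = bleach_duration,
         frame_interval = frame_interval,
         imaging_intensity = imaging_intensity,
         n_prebleach = n_prebleach, n_postbleach = n_postbleach,
         edge_sigma = edge_sigma),
    class = "bleach_protocol"
  )
}

#' Spatial bleach-intensity profile
#'
#' Radially symmetric relative laser-intensity profile of the bleach pulse.
#' `"hard-disk"` is the indicator of the disk; `"empirical-like"` is the
#' disk convolved with a Gaussian edge, standing in for profiles calibrated
#' on fixed cells (which are not available as data). At the reference pixel
#' scale (0.13 um/px) radii of 10, 15 and 20 px correspond to ROI diameters
#' of 2.6, 4.0(-ish) and 5.3 um.
#'
#' @param radius_px ROI radius in pixels (> 0).
#' @param shape `"empirical-like"` or `"hard-disk"`.
#' @param size Output matrix size `c(rows, cols)`.
#' @param center Profile centre `c(row, col)`; default image centre.
#' @param edge_sigma Gaussian edge width (px) for `"empirical-like"`.
#' @return Matrix of relative intensities in `[0, 1]`, maximal at the
#'   centre.
#' @export
make_bleach_profile <- function(radius_px, shape = c("empirical-like", "hard-disk"),
                                size = c(128, 128), center = NULL,
                                edge_sigma = 2) {
  shape <- match.arg(shape)
  if (radius_px <= 0) abort("radius must be positive")
  if (is.null(center)) center <- (size + 1) / 2
  rr <- matrix(seq_len(size[1]), size[1], size[2])
  cc <- matrix(seq_len(size[2]), size[1], size[2], byrow = TRUE)
  d <- sqrt((rr - center[1])^2 + (cc - center[2])^2)
  if (shape == "hard-disk") {
    prof <- (d <= radius_px) * 1
  } else {
    # disk with error-function edge: radial convolution of the indicator
    # with a Gaussian of sd edge_sigma
    prof <- 0.5 * (1 + erf((radius_px - d) / (sqrt(2) * edge_sigma)))
    prof <- prof / max(prof)
  }
  prof
}

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Infer cytoplasm geometry from a FRAP image series
#'
#' Computes the mean intensity projection of all frames (noise reduction),
#' locates the cell boundary from intensity discontinuities by edge
#' detection (Sobel gradient, Otsu-thresholded, filled), and keeps the
#' largest connected region. The mean of a user-defined exterior reporting
#' region is stored as the background level for subtraction.
#'
#' @param frames 3D numeric array (rows x cols x frames) or a list of
#'   matrices.
#' @param pixel_size Pixel size, micrometres.
#' @param background_region Optional logical matrix marking an exterior
#'   reporting region; default: the pixels outside the inferred mask.
#' @return A [frap_geometry()] with attribute `background` (estimated
#'   background level).
#' @export
infer_cytoplasm_geometry <- function(frames, pixel_size = 0.13,
                                     background_region = NULL) {
  if (is.list(frames)) frames <- simplify2array(frames)
  if (length(dim(frames)) == 2L) frames <- array(frames, c(dim(frames), 1L))
  mean_proj <- apply(frames, c(1, 2), mean)
  rng <- diff(range(mean_proj))
  if (rng <= 0) abort("featureless image: segmentation is empty")
  img <- (mean_proj - min(mean_proj)) / rng
  sob_x <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, byrow = TRUE)
  gx <- EBImage::filter2(img, sob_x)
  gy <- EBImage::filter2(img, t(sob_x))
  grad <- sqrt(gx^2 + gy^2)
  thr <- EBImage::otsu(EBImage::Image(grad / max(grad)), range = c(0, 1))
  edges <- grad / max(grad) > thr
  filled <- EBImage::fillHull(EBImage::Image(edges * 1))
  lab <- EBImage::bwlabel(filled)
  tab <- tabulate(as.integer(lab[lab > 0]))
  if (length(tab) == 0L) abort("empty segmentation")
  mask <- matrix(as.integer(lab) == which.max(tab), nrow(img), ncol(img))
  # erode the ring thickness contributed by the gradient band
  mask <- as.matrix(EBImage::erode(EBImage::Image(mask * 1),
                                   EBImage::makeBrush(3, "disc"))) > 0.5
  if (!any(mask)) abort("empty segmentation")
  if (is.null(background_region)) {
    # default exterior reporting region: stay clear of the cell boundary
    grown <- as.matrix(EBImage::dilate(EBImage::Image(mask * 1),
                                       EBImage::makeBrush(9, "disc"))) > 0.5
    background_region <- !grown
  }
  bg <- mean(mean_proj[background_region])
  geom <- frap_geometry(mask, pixel_size = pixel_size)
  attr(geom, "background") <- bg
  geom
}

# Sparse 5-point Laplacian over the mask with zero-flux (reflecting)
# boundaries: L[i,i] = -(number of in-mask neighbours), L[i,j] = 1. Row sums
# are zero, so diffusion conserves mass exactly.
masked_laplacian <- function(mask) {
  idx <- matrix(0L, nrow(mask), ncol(mask))
  idx[mask] <- seq_len(sum(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  pairs_i <- integer(0); pairs_j <- integer(0)
  src_r <- which(mask, arr.ind = TRUE)
  shift <- function(drow, dcol) {
    nb_r <- src_r[, 1] + drow
    nb_c <- src_r[, 2] + dcol
    ok <- nb_r >= 1 & nb_r <= nr & nb_c >= 1 & nb_c <= nc
    src <- idx[src_r[ok, , drop = FALSE]]
    nb <- idx[cbind(nb_r[ok], nb_c[ok])]
    keep <- nb > 0
    list(i = src[keep], j = nb[keep])
  }
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    s <- shift(d[1], d[2])
    pairs_i <- c(pairs_i, s$i); pairs_j <- c(pairs_j, s$j)
  }
  n <- sum(mask)
  off <- Matrix::sparseMatrix(i = pairs_i, j = pairs_j, x = 1, dims = c(n, n))
  deg <- Matrix::rowSums(off)
  off - Matrix::Diagonal(n, deg)
}

#' Simulate a FRAP experiment
#'
#' Solves the reaction-diffusion system for observable (unbleached) protein
#' on the cytoplasm mask:
#' \deqn{\partial c/\partial t = D_c \nabla^2 c - k_{on} c + k_{off} m - \alpha I c}
#' \deqn{\partial m/\partial t = k_{on} c - k_{off} m - \alpha I m}
#' with zero-flux boundaries (no protein crosses the nuclear or cell
#' membrane). The bleach pulse is integrated through the same
#' reaction-diffusion dynamics with the per-pixel loss rate
#' `alpha * I(x)` over `bleach_duration` (diffusion during the finite
#' pulse is what carries the diffusivity signal at sub-second frame
#' intervals); between frames the
#' uniform imaging illumination bleaches at intensity
#' `imaging_intensity`. Numerics: Lie splitting per substep with the 2x2
#' binding/bleach exchange solved in closed form per pixel and diffusion
#' advanced by backward Euler using a sparse Cholesky factorisation
#' (unconditionally stable).
#'
#' @param geom A [frap_geometry()].
#' @param params A [frap_params()].
#' @param protocol A [bleach_protocol()].
#' @param c_init `"equilibrium"`: free concentration uniform at 1, bound
#'   `m = (k_on / k_off) c` per pixel (scaled by the binding density), or
#'   `m = 0` when `k_on = 0`.
#' @param n_substeps Substeps per frame interval (>= 1).
#' @return A `frap_series`: list with `frames` (rows x cols x n array of
#'   observed `c + m`), `times` (s; bleach pulse at t = 0), `geometry`,
#'   `protocol`, `params`.
#' @export
simulate_frap <- function(geom, params, protocol, c_init = "equilibrium",
                          n_substeps = 4) {
  if (!inherits(geom, "frap_geometry")) abort("geom must be a frap_geometry")
  if (!inherits(params, "frap_params")) abort("params must be a frap_params")
  if (n_substeps < 1) abort("unstable step configuration: n_substeps must be >= 1")
  mask <- geom$mask
  n <- sum(mask)
  h <- geom$pixel_size
  dens <- geom$binding_density[mask]
  kon <- params$k_on * dens
  koff <- params$k_off
  # equilibrium initial condition
  c_vec <- rep(1, n)
  m_vec <- if (koff > 0) kon / koff * c_vec else rep(0, n)
  if (params$k_on == 0) m_vec <- rep(0, n)
  center <- protocol$roi_center %||% ((dim(mask) + 1) / 2)
  profile <- make_bleach_profile(protocol$roi_radius, protocol$profile_shape,
                                 size = dim(mask), center = center,
                                 edge_sigma = protocol$edge_sigma)
  Ipulse <- profile[mask]
  dt <- protocol$frame_interval / n_substeps
  L <- masked_laplacian(mask)
  Dh <- params$D_c / h^2
  A <- Matrix::Diagonal(n) - (dt * Dh) * L
  chol_A <- if (params$D_c > 0) Matrix::Cholesky(Matrix::forceSymmetric(A)) else NULL
  img_I <- protocol$imaging_intensity
  n_frames <- protocol$n_prebleach + protocol$n_postbleach
  frames <- array(0, c(nrow(mask), ncol(mask), n_frames))
  times <- numeric(n_frames)
  t0 <- -protocol$n_prebleach * protocol$frame_interval
  frame_i <- 0L
  snap <- function(cv, mv) {
    out <- matrix(0, nrow(mask), ncol(mask))
    out[mask] <- cv + mv
    out
  }
  advance_frame <- function(c_vec, m_vec) {
    for (s in seq_len(n_substeps)) {
      # imaging-light bleach + binding exchange over dt (closed form)
      ex <- exchange_step(c_vec, m_vec, kon, koff, params$alpha * img_I, dt)
      c_vec <- ex$c; m_vec <- ex$m
      if (!is.null(chol_A)) {
        c_vec <- as.vector(Matrix::solve(chol_A, c_vec))
      }
    }
    list(c = c_vec, m = m_vec)
  }
  # pre-bleach frames (imaging illumination only)
  for (k in seq_len(protocol$n_prebleach)) {
    frame_i <- frame_i + 1L
    times[frame_i] <- t0 + (k - 1) * protocol$frame_interval
    frames[, , frame_i] <- snap(c_vec, m_vec)
    st <- advance_frame(c_vec, m_vec)
    c_vec <- st$c; m_vec <- st$m
  }
  # bleach pulse: integrated through the PDE so that diffusion during the
  # finite pulse shapes the post-bleach profile (this is what makes the
  # diffusivity identifiable at sub-second frame intervals)
  if (protocol$bleach_duration > 0 && params$alpha > 0) {
    n_bs <- max(10L, n_substeps)
    dt_b <- protocol$bleach_duration / n_bs
    A_b <- Matrix::Diagonal(n) - (dt_b * Dh) * L
    chol_b <- if (params$D_c > 0) Matrix::Cholesky(Matrix::forceSymmetric(A_b)) else NULL
    beta_b <- params$alpha * Ipulse
    for (s in seq_len(n_bs)) {
      ex <- exchange_step(c_vec, m_vec, kon, koff, beta_b, dt_b)
      c_vec <- ex$c; m_vec <- ex$m
      if (!is.null(chol_b)) c_vec <- as.vector(Matrix::solve(chol_b, c_vec))
    }
  }
  for (k in seq_len(protocol$n_postbleach)) {
    frame_i <- frame_i + 1L
    times[frame_i] <- (k - 1) * protocol$frame_interval
    frames[, , frame_i] <- snap(c_vec, m_vec)
    st <- advance_frame(c_vec, m_vec)
    c_vec <- st$c; m_vec <- st$m
  }
  structure(
    list(frames = frames, times = times, geometry = geom,
         protocol = protocol, params = params),
    class = "frap_series"
  )
}

# Closed-form solution over dt of
#   dc/dt = -(kon + beta) c + koff m
#   dm/dt = kon c - (koff + beta) m
# with per-pixel kon (vector), scalar koff and bleach rate beta. The common
# bleach factor exp(-beta dt) multiplies the pure exchange solution.
exchange_step <- function(c_vec, m_vec, kon, koff, beta, dt) {
  s <- kon + koff
  tot <- c_vec + m_vec
  # exchange equilibrium split
  ceq <- ifelse(s > 0, koff / s * tot, c_vec)
  decay <- exp(-s * dt)
  c_new <- ceq + (c_vec - ceq) * decay
  m_new <- tot - c_new
  fade <- exp(-beta * dt)
  list(c = c_new * fade, m = m_new * fade)
}

#' Total unbleached fluorescence per frame
#' @param series A `frap_series`.
#' @return Tibble with `time_s` and `total`.
#' @export
frap_total_mass <- function(series) {
  tibble(
    time_s = series$times,
    total = apply(series$frames, 3, sum)
  )
}

#' Radially binned recovery profiles
#'
#' Averages each frame over concentric annuli around the bleach ROI centre;
#' the default fitting objective compares these profiles between data and
#' model.
#'
#' @param series A `frap_series`.
#' @param bin_width Annulus width, pixels.
#' @param max_radius Outermost radius, pixels (default: 2.5 x ROI radius
#'   capped at the image).
#' @return Tibble with `frame`, `time_s`, `radius_px`, `intensity`.
#' @export
frap_radial_profile <- function(series, bin_width = 2, max_radius = NULL) {
  mask <- series$geometry$mask
  center <- series$protocol$roi_center %||% ((dim(mask) + 1) / 2)
  rr <- matrix(seq_len(nrow(mask)), nrow(mask), ncol(mask))
  cc <- matrix(seq_len(ncol(mask)), nrow(mask), ncol(mask), byrow = TRUE)
  d <- sqrt((rr - center[1])^2 + (cc - center[2])^2)
  if (is.null(max_radius)) {
    max_radius <- min(2.5 * series$protocol$roi_radius, max(d[mask]))
  }
  bins <- floor(d / bin_width)
  keep <- mask & d <= max_radius
  bin_f <- factor(bins[keep])
  nf <- dim(series$frames)[3]
  prof <- vapply(seq_len(nf), function(i) {
    fr <- series$frames[, , i]
    tapply(fr[keep], bin_f, mean)
  }, numeric(nlevels(bin_f)))
  tibble(
    frame = rep(seq_len(nf), each = nlevels(bin_f)),
    time_s = rep(series$times, each = nlevels(bin_f)),
    radius_px = rep((as.numeric(levels(bin_f)) + 0.5) * bin_width, nf),
    intensity = as.vector(prof)
  )
}

# Internal: FRAP stepping from an arbitrary uniform initial condition with
# no bleach pulse, returning the free (c) and bound (m) fields per frame as
# n_pixels x n_frames matrices. Used for consistency checks between the
# spatial model and its well-mixed two-compartment reduction.
simulate_frap_custom_init <- function(geom, params, protocol, c0, m0,
                                      n_substeps = 4) {
  mask <- geom$mask
  n <- sum(mask)
  dens <- geom$binding_density[mask]
  kon <- params$k_on * dens
  koff <- params$k_off
  c_vec <- rep(c0, n)
  m_vec <- if (length(m0) == n) m0 else rep(m0, n)
  dt <- protocol$frame_interval / n_substeps
  L <- masked_laplacian(mask)
  A <- Matrix::Diagonal(n) - (dt * params$D_c / geom$pixel_size^2) * L
  chol_A <- if (params$D_c > 0) Matrix::Cholesky(Matrix::forceSymmetric(A)) else NULL
  nf <- protocol$n_postbleach
  c_frames <- matrix(0, n, nf)
  m_frames <- matrix(0, n, nf)
  times <- (seq_len(nf) - 1L) * protocol$frame_interval
  beta <- params$alpha * protocol$imaging_intensity
  for (k in seq_len(nf)) {
    c_frames[, k] <- c_vec
    m_frames[, k] <- m_vec
    for (s in seq_len(n_substeps)) {
      ex <- exchange_step(c_vec, m_vec, kon, koff, beta, dt)
      c_vec <- ex$c; m_vec <- ex$m
      if (!is.null(chol_A)) c_vec <- as.vector(Matrix::solve(chol_A, c_vec))
    }
  }
  list(c_frames = c_frames, m_frames = m_frames, times = times)
}
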