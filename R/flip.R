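#' FLIP model parameters
#'
#' Parameters of the two-compartment fluorescence-loss-in-photobleaching
#' model: nuclear import/export rate constants, the bleaching hazard
#' parameters and the initial normalised intensities. The bleaching hazard
#' applied to the bleached compartment is
#' \deqn{h(t) = \eta_1 + \eta_2 e^{-\lambda t},}
#' a fast early component relaxing to a slow constant rate, so that the
#' bleached-compartment decay is effectively double-exponential.
#'
#' @param k_imp,k_exp Import and export rate constants (s^-1).
#' @param eta1 Slow (asymptotic) bleach rate (s^-1).
#' @param eta2 Excess initial bleach rate (s^-1).
#' @param lam Relaxation rate of the fast bleach component (s^-1).
#' @param c0 Initial normalised cytoplasmic intensity.
#' @param n0 Initial normalised nuclear intensity; default imposes the
#'   pre-bleach steady state `n0 = (k_imp / k_exp) c0`.
#' @return An object of class `flip_params`.
#' @export
flip_params <- function(k_imp, k_exp, eta1, eta2, lam, c0 = 1,
                        n0 = NULL) {
  if (is.null(n0)) {
    if (k_exp <= 0) abort("steady-state n0 requires k_exp > 0")
    n0 <- (k_imp / k_exp) * c0
  }
  p <- list(k_imp = k_imp, k_exp = k_exp, eta1 = eta1, eta2 = eta2,
            lam = lam, c0 = c0, n0 = n0)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || is.na(p[[nm]]) ||
        p[[nm]] < 0) {
      abort(paste0("flip parameter `", nm, "` must be a single non-negative number"))
    }
  }
  structure(p, class = "flip_params")
}

flip_hazard <- function(p, t) p$eta1 + p$eta2 * exp(-p$lam * t)

# Generator of the FLIP system at time t; the hazard acts on the bleached
# compartment only. State order (n, c).
flip_matrix <- function(p, site, t) {
  h <- flip_hazard(p, t)
  hn <- if (site == "nucleus") h else 0
  hc <- if (site == "cytoplasm") h else 0
  matrix(c(
    -(p$k_exp + hn), p$k_imp,
    p$k_exp, -(p$k_imp + hc)
  ), nrow = 2, byrow = TRUE)
}

#' Simulate a FLIP trace
#'
#' Integrates
#' \deqn{dn/dt = k_{imp} c - k_{exp} n - [site = nucleus]\, h(t)\, n}
#' \deqn{dc/dt = k_{exp} n - k_{imp} c - [site = cytoplasm]\, h(t)\, c}
#' from the pre-bleach steady state, with the double-exponential bleaching
#' hazard `h(t)` acting continuously on the bleached compartment (the bleach
#' pulses are much shorter than the transport time scales).
#'
#' @param params A [flip_params()] object.
#' @param site `"nucleus"` or `"cytoplasm"`: which compartment is bleached.
#' @param times Frame times in seconds (bleaching starts at `t = 0`; times
#'   may include negative pre-bleach frames during which `h = 0`).
#' @param method `"lsoda"` (default; adaptive, rtol 1e-10) or `"magnus"`
#'   (second-order midpoint matrix-exponential stepping, used as an
#'   independent numerical route in the validation suite).
#' @param step Step size for the Magnus integrator, seconds.
#' @return A `flip_trace`: tibble with columns `time_s`, `n`, `c` and
#'   attribute `bleach_site`.
#' @export
simulate_flip <- function(params, site = c("nucleus", "cytoplasm"), times,
                          method = c("lsoda", "magnus"), step = 0.005) {
  site <- match.arg(site)
  method <- match.arg(method)
  if (!inherits(params, "flip_params")) abort("params must be a flip_params object")
  times <- as.numeric(times)
  if (any(diff(times) <= 0)) abort("times must be strictly increasing")
  x0 <- c(params$n0, params$c0)
  if (method == "lsoda") {
    rhs <- function(t, y, p) {
      h <- if (t >= 0) flip_hazard(params, t) else 0
      hn <- if (site == "nucleus") h else 0
      hc <- if (site == "cytoplasm") h else 0
      list(c(
        params$k_imp * y[2] - params$k_exp * y[1] - hn * y[1],
        params$k_exp * y[1] - params$k_imp * y[2] - hc * y[2]
      ))
    }
    tt <- unique(c(min(times[1], 0), times))
    sol <- deSolve::lsoda(x0, tt, rhs, rtol = 1e-10, atol = 1e-13)
    res <- sol[match(times, sol[, 1]), 2:3, drop = FALSE]
  } else {
    res <- matrix(NA_real_, nrow = length(times), ncol = 2)
    x <- x0
    t_cur <- min(times[1], 0)
    for (i in seq_along(times)) {
      x <- flip_step_magnus(params, site, x, t_cur, times[i], step)
      res[i, ] <- x
      t_cur <- times[i]
    }
  }
  out <- tibble(time_s = times, n = res[, 1], c = res[, 2])
  attr(out, "bleach_site") <- site
  class(out) <- c("flip_trace", class(out))
  out
}

# Midpoint (second-order Magnus) matrix-exponential stepping from t0 to t1.
# Exact for piecewise-constant hazard; O(step^2) globally otherwise.
flip_step_magnus <- function(params, site, x, t0, t1, step) {
  if (t1 <= t0) return(x)
  n_steps <- max(1L, ceiling((t1 - t0) / step))
  dt <- (t1 - t0) / n_steps
  for (k in seq_len(n_steps)) {
    tm <- t0 + (k - 0.5) * dt
    A <- if (tm >= 0) {
      flip_matrix(params, site, tm)
    } else {
      matrix(c(-params$k_exp, params$k_imp, params$k_exp, -params$k_imp),
             nrow = 2, byrow = TRUE)
    }
    x <- expm2(A * dt) %*% x
  }
  as.vector(x)
}

# Closed-form 2x2 matrix exponential.
expm2 <- function(A) {
  tr <- (A[1, 1] + A[2, 2]) / 2
  B <- A - diag(tr, 2)
  # B has trace 0; B^2 = det? For trace-free B, B^2 = -det(B) I
  d2 <- B[1, 1]^2 + B[1, 2] * B[2, 1]  # B^2 = d2 * I
  if (d2 > 0) {
    s <- sqrt(d2)
    ch <- cosh(s); sh <- sinh(s) / s
  } else if (d2 < 0) {
    s <- sqrt(-d2)
    ch <- cos(s); sh <- sin(s) / s
  } else {
    ch <- 1; sh <- 1
  }
  exp(tr) * (ch * diag(2) + sh * B)
}

# Exact closed-form solution for CONSTANT hazard (eta2 = 0): autonomous 2x2
# linear system solved by a single matrix exponential per time point.
flip_analytic_constant_hazard <- function(params, site, times) {
  stopifnot(params$eta2 == 0)
  A <- flip_matrix(params, site, 0)
  x0 <- c(params$n0, params$c0)
  res <- t(vapply(times, function(t) {
    if (t <= 0) x0 else as.vector(expm2(A * t) %*% x0)
  }, numeric(2)))
  tibble(time_s = times, n = res[, 1], c = res[, 2])
}

#' Normalise raw FLIP intensities
#'
#' Background-subtracts and control-normalises raw compartment intensity
#' traces: the extracellular background is subtracted frame-wise, and the
#' result is divided by the mean of two control ROI traces (one nuclear, one
#' cytoplasmic, from a non-bleached cell) so that drift common to all cells
#' cancels.
#'
#' @param raw_traces A data frame with columns `time_s`, `n`, `c` (raw total
#'   intensities of the bleached cell's compartments).
#' @param control_rois A data frame with columns `control_n`, `control_c`
#'   (raw control ROI traces), or a numeric matrix with two columns.
#' @param background_roi Numeric vector of extracellular background
#'   intensities per frame (or a single number).
#' @param bleach_site `"nucleus"` or `"cytoplasm"`.
#' @return A `flip_trace` tibble with normalised `n` and `c`.
#' @export
normalise_flip <- function(raw_traces, control_rois, background_roi,
                           bleach_site = c("nucleus", "cytoplasm")) {
  bleach_site <- match.arg(bleach_site)
  ctrl <- if (is.data.frame(control_rois)) {
    cbind(control_rois$control_n, control_rois$control_c)
  } else {
    as.matrix(control_rois)
  }
  bg <- rep_len(as.numeric(background_roi), nrow(raw_traces))
  ctrl_mean <- rowMeans(ctrl - bg)
  if (any(ctrl_mean <= 0)) abort("control ROI mean must be positive after background subtraction")
  out <- tibble(
    time_s = raw_traces$time_s,
    n = (raw_traces$n - bg) / ctrl_mean,
    c = (raw_traces$c - bg) / ctrl_mean
  )
  attr(out, "bleach_site") <- bleach_site
  class(out) <- c("flip_trace", class(out))
  out
}

#' Double-exponential fit of whole-cell intensity decay
#'
#' Fits `a(t) = A1 exp(-r1 t) + A2 exp(-r2 t)` (with `r1 <= r2`) to the
#' total normalised intensity of the entire cell by least squares, and maps
#' the result to initial guesses for the bleaching-hazard parameters:
#' `eta1 = r1` (slow asymptotic rate), `lam = r2 - r1` and
#' `eta2 = (A2 / (A1 + A2)) * lam` (excess hazard amplitude at `t = 0`).
#'
#' @param times Frame times (seconds, from bleach onset).
#' @param total Total normalised cell intensity per frame.
#' @return A list with `eta1`, `eta2`, `lam`, plus the raw fit `A1`, `r1`,
#'   `A2`, `r2`.
#' @export
fit_double_exponential <- function(times, total) {
  if (length(times) < 6L) abort("need at least 6 time points")
  if (total[length(total)] >= total[1]) {
    warn("input does not decay; rate guesses clipped at 0")
    return(list(eta1 = 0, eta2 = 0, lam = 0,
                A1 = mean(total), r1 = 0, A2 = 0, r2 = 0))
  }
  # crude single-exponential rate for starting values
  pos <- total > 0
  r0 <- -coef(lm(log(total[pos]) ~ times[pos]))[[2]]
  r0 <- max(r0, 1e-6)
  resid_fn <- function(p) {
    A1 <- p[1]; r1 <- exp(p[2]); A2 <- p[3]; r2 <- exp(p[4])
    A1 * exp(-r1 * times) + A2 * exp(-r2 * times) - total
  }
  start <- c(0.7 * total[1], log(r0 / 2), 0.3 * total[1], log(r0 * 5))
  fit <- minpack.lm::nls.lm(start, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- fit$par
  A <- c(p[1], p[3]); r <- exp(c(p[2], p[4]))
  o <- order(r)
  A <- A[o]; r <- r[o]
  # degenerate single-exponential branch: negligible second amplitude
  if (abs(A[2]) < 1e-8 * max(abs(A[1]), 1)) {
    return(list(eta1 = max(r[1], 0), eta2 = 0, lam = 0,
                A1 = A[1], r1 = r[1], A2 = 0, r2 = r[2]))
  }
  lam <- max(r[2] - r[1], 0)
  list(
    eta1 = max(r[1], 0),
    eta2 = max(A[2] / (A[1] + A[2]), 0) * lam,
    lam = lam,
    A1 = A[1], r1 = r[1], A2 = A[2], r2 = r[2]
  )
}

#' Fit the FLIP model to a normalised trace
#'
#' Nonlinear least squares over `(k_imp, k_exp, eta1, eta2, lam, c0)`; the
#' initial nuclear intensity is eliminated through the pre-bleach steady
#' state `n0 = (k_imp / k_exp) c0`. Initial guesses: the first cytoplasmic
#' intensity for `c0`, rates of order 1e-3 for `k_imp`/`k_exp`, and the
#' double-exponential fit of total cell intensity for the hazard parameters.
#'
#' @param trace A `flip_trace` (normalised) with attribute `bleach_site`, or
#'   a data frame with columns `time_s`, `n`, `c`.
#' @param bleach_site Override for the bleach site if not carried by the
#'   trace.
#' @return A `flip_fit` object; see [tidy()] and [glance()] methods.
#' @export
fit_flip <- function(trace, bleach_site = NULL) {
  site <- bleach_site %||% attr(trace, "bleach_site")
  if (is.null(site)) abort("bleach_site must be known")
  times <- trace$time_s
  guess_h <- fit_double_exponential(times, trace$n + trace$c)
  start <- c(
    log(1e-3), log(1e-3),
    log(max(guess_h$eta1, 1e-5)), log(max(guess_h$eta2, 1e-5)),
    log(max(guess_h$lam, 1e-4)), log(max(trace$c[1], 1e-6))
  )
  unpack <- function(p) {
    flip_params(
      k_imp = exp(p[1]), k_exp = exp(p[2]),
      eta1 = exp(p[3]), eta2 = exp(p[4]), lam = exp(p[5]),
      c0 = exp(p[6])
    )
  }
  resid_fn <- function(p) {
    pr <- unpack(p)
    sim <- simulate_flip(pr, site, times)
    c(sim$n - trace$n, sim$c - trace$c)
  }
  fit <- minpack.lm::nls.lm(start, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12, ptol = 1e-12))
  est <- unpack(fit$par)
  r <- fit$fvec
  n_res <- length(r)
  n_par <- length(fit$par)
  sigma2 <- sum(r^2) / max(n_res - n_par, 1)
  # delta-method CIs on the natural scale from the log-scale curvature
  hess <- fit$hessian
  cov_log <- tryCatch(solve(hess) * 2 * sigma2, error = function(e) matrix(NA, n_par, n_par))
  se_log <- sqrt(pmax(diag(cov_log), 0))
  vals <- unlist(est[c("k_imp", "k_exp", "eta1", "eta2", "lam", "c0")])
  se <- vals * se_log
  identifiable <- all(is.finite(se_log)) && all(se_log[1:2] < 10)
  new_kin_fit(
    model = "flip",
    params = tibble(
      term = names(vals), estimate = unname(vals),
      std_error = unname(se),
      conf_low = unname(vals - qnorm(0.975) * se),
      conf_high = unname(vals + qnorm(0.975) * se)
    ),
    rss = sum(r^2), n_residuals = n_res, n_params = n_par,
    converged = fit$info %in% 1:4,
    flags = if (identifiable) character() else "unidentifiable",
    data = trace,
    extra = list(bleach_site = site, sigma2 = sigma2)
  )
}
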