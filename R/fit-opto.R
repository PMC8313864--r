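#' Model variants of the optogenetic fit
#'
#' The compared model family: a single mitochondrial on (recovery) rate
#' across lit and unlit states versus separate lit/unlit on rates
#' (`on_rate_mode`), optionally with the dark-state binding rates fixed to
#' externally measured values or with their ratio fixed (`dark_rate_mode`).
#'
#' @param on_rate_mode `"single"` (one on rate for both light states) or
#'   `"dual"` (separate lit and unlit on rates).
#' @param dark_rate_mode `"free"`, `"fixed_values"` (dark on/off fixed to
#'   `fixed_dark`) or `"fixed_ratio"` (dark on/off ratio fixed to
#'   `fixed_ratio`).
#' @param fixed_dark Numeric `c(k_on_unlit =, k_off_unlit =)`; required for
#'   `"fixed_values"` (typically FRAP medians).
#' @param fixed_ratio Numeric scalar `k_on_unlit / k_off_unlit`; required
#'   for `"fixed_ratio"`.
#' @return A `model_variant` object.
#' @export
model_variant <- function(on_rate_mode = c("dual", "single"),
                          dark_rate_mode = c("free", "fixed_values", "fixed_ratio"),
                          fixed_dark = NULL, fixed_ratio = NULL) {
  on_rate_mode <- match.arg(on_rate_mode)
  dark_rate_mode <- match.arg(dark_rate_mode)
  if (dark_rate_mode == "fixed_values" &&
      (is.null(fixed_dark) || !all(c("k_on_unlit", "k_off_unlit") %in% names(fixed_dark)))) {
    abort("fixed_values requires fixed_dark = c(k_on_unlit =, k_off_unlit =)")
  }
  if (dark_rate_mode == "fixed_ratio" && is.null(fixed_ratio)) {
    abort("fixed_ratio requires a fixed_ratio value")
  }
  structure(
    list(on_rate_mode = on_rate_mode, dark_rate_mode = dark_rate_mode,
         fixed_dark = fixed_dark, fixed_ratio = fixed_ratio),
    class = "model_variant"
  )
}

variant_label <- function(v) {
  paste0(v$on_rate_mode, "-on/", v$dark_rate_mode)
}

# Free parameter names for a variant. All rates are fitted on the log scale
# (enforcing positivity); M0 on the logit scale.
variant_free_params <- function(variant) {
  base <- c("k_imp", "k_exp", "k_off_unlit", "k_off_lit", "M0")
  on <- switch(variant$dark_rate_mode,
    free = "k_on_unlit",
    fixed_values = character(),
    fixed_ratio = character()
  )
  off_dark <- if (variant$dark_rate_mode == "fixed_values") character() else "k_off_unlit"
  on_lit <- if (variant$on_rate_mode == "dual") "k_on_lit" else character()
  unique(c("k_imp", "k_exp", on, off_dark, on_lit, "k_off_lit", "M0"))
}

# Assemble rate_params + M0 from the free parameter vector (natural scale).
variant_assemble <- function(theta, variant) {
  g <- function(nm, default = NULL) if (nm %in% names(theta)) theta[[nm]] else default
  if (variant$dark_rate_mode == "fixed_values") {
    k_on_u <- variant$fixed_dark[["k_on_unlit"]]
    k_off_u <- variant$fixed_dark[["k_off_unlit"]]
  } else if (variant$dark_rate_mode == "fixed_ratio") {
    k_off_u <- g("k_off_unlit")
    k_on_u <- variant$fixed_ratio * k_off_u
  } else {
    k_on_u <- g("k_on_unlit")
    k_off_u <- g("k_off_unlit")
  }
  k_off_l <- g("k_off_lit")
  k_on_l <- if (variant$on_rate_mode == "dual") g("k_on_lit") else k_on_u
  list(
    rates = rate_params(
      k_imp = g("k_imp"), k_exp = g("k_exp"),
      k_on_unlit = k_on_u, k_off_unlit = k_off_u,
      k_on_lit = k_on_l, k_off_lit = k_off_l
    ),
    M0 = g("M0")
  )
}

# Initial state given M0 and rates: N0/C0 pinned by the dark steady-state
# ratio k_imp/k_exp, C0 + N0 = 1 - M0.
opto_init_state <- function(M0, rates) {
  rn <- rates$k_imp / rates$k_exp
  C0 <- (1 - M0) / (1 + rn)
  c(M = M0, C = C0, N = rn * C0)
}

opto_model_trace <- function(theta, variant, schedule) {
  asm <- variant_assemble(theta, variant)
  init <- opto_init_state(asm$M0, asm$rates)
  simulate_trace(asm$rates, schedule, init = as.list(init))
}

# Weighted residual vector: each compartment's residuals divided by the sd
# of that compartment's observed values, so every compartment contributes
# comparably to the objective regardless of its dynamic range.
opto_residuals <- function(theta, variant, trace, weights, frame_mask = NULL) {
  sim <- opto_model_trace(theta, variant, schedule = trace)
  r <- c(
    (sim$M - trace$M) / weights[["M"]],
    (sim$C - trace$C) / weights[["C"]],
    (sim$N - trace$N) / weights[["N"]]
  )
  if (!is.null(frame_mask)) {
    r <- r[rep(frame_mask, 3L)]
  }
  r
}

opto_weights <- function(trace) {
  w <- c(M = sd(trace$M), C = sd(trace$C), N = sd(trace$N))
  w[w <= 0 | !is.finite(w)] <- 1
  w
}

# log/logit packing of the free parameters
pack_theta <- function(theta) {
  p <- numeric(length(theta))
  names(p) <- names(theta)
  for (nm in names(theta)) {
    p[nm] <- if (nm == "M0") stats::qlogis(min(max(theta[[nm]], 1e-6), 1 - 1e-6)) else log(theta[[nm]])
  }
  p
}

unpack_theta <- function(p) {
  theta <- as.list(p)
  for (nm in names(theta)) {
    theta[[nm]] <- if (nm == "M0") stats::plogis(p[[nm]]) else exp(p[[nm]])
  }
  theta
}

default_opto_guesses <- function(trace, variant) {
  # Lambda: median mitochondrial intensity over the first five unlit frames
  pre <- which(!trace$lit)
  pre <- pre[pre <= (min(which(trace$lit), Inf) - 1)]
  Lambda <- if (length(pre)) median(trace$M[head(pre, 5)]) else median(head(trace$M, 5))
  Lambda <- min(max(Lambda, 0.05), 0.95)
  g <- list(
    k_imp = 2e-3, k_exp = 2e-3,
    k_on_unlit = 0.027, k_off_unlit = 0.019,
    k_on_lit = 0.03, k_off_lit = 0.1,
    M0 = Lambda
  )
  g[variant_free_params(variant)]
}

#' Fit the three-compartment optogenetic model to a normalised trace
#'
#' Nonlinear least squares (Levenberg-Marquardt) of the shuttling ODE
#' against a normalised release/recovery trace. Residuals of each
#' compartment are divided by that compartment's observed standard
#' deviation so all three contribute equally. The initial nuclear and
#' cytoplasmic proportions are eliminated through the dark steady-state
#' ratio (`N0 = (k_imp / k_exp) C0`, `M0 + C0 + N0 = 1`) leaving the
#' initial mitochondrial proportion `M0` as the single fitted initial
#' condition, with the median mitochondrial intensity over the first five
#' dark frames as its starting guess. Lit-state rates are informed only by
#' lit-phase residuals; the fit is flagged unidentifiable when the curvature
#' carries no information on a parameter (e.g. lit rates on an all-dark
#' trace). Three jittered multi-starts guard against local minima.
#'
#' @param trace A normalised `compartment_trace` with a `lit` column.
#' @param variant A [model_variant()]; default dual on-rate, all free.
#' @param guesses Optional named list of starting values on the natural
#'   scale (rates s^-1, `M0` proportion).
#' @param n_starts Number of jittered starts (first start unjittered).
#' @param seed Seed for the start jitter.
#' @return An `opto_fit` object (see [tidy()], [glance()], [autoplot()]).
#' @export
fit_opto_model <- function(trace, variant = model_variant(), guesses = NULL,
                           n_starts = 3, seed = 1) {
  if (!is_normalized(trace)) {
    warn("trace is not flagged as normalized; fitting proportions anyway")
  }
  free <- variant_free_params(variant)
  g <- default_opto_guesses(trace, variant)
  if (!is.null(guesses)) g[names(guesses)[names(guesses) %in% free]] <- guesses[names(guesses) %in% free]
  g <- g[free]
  weights <- opto_weights(trace)
  obj <- function(p) {
    theta <- unpack_theta(setNames(as.list(p), free))
    opto_residuals(theta, variant, trace, weights)
  }
  p0 <- pack_theta(g)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    start <- if (s == 1) p0 else p0 + rnorm(length(p0), sd = 0.3)
    fit <- tryCatch(
      minpack.lm::nls.lm(start, fn = obj,
        control = minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-13, ptol = 1e-13)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || sum(fit$fvec^2) < sum(best$fvec^2)) best <- fit
  }
  if (is.null(best)) abort("all optimisation starts failed")
  fit <- best
  theta <- unpack_theta(setNames(as.list(fit$par), free))
  rss <- sum(fit$fvec^2)
  n_res <- length(fit$fvec)
  n_par <- length(free)
  sigma2 <- rss / max(n_res - n_par, 1)
  hess <- fit$hessian  # 2 * J'J approximation from nls.lm
  # curvature-based covariance on the transformed scale
  cov_t <- tryCatch(solve(hess) * 2 * sigma2, error = function(e) {
    matrix(NA_real_, n_par, n_par)
  })
  se_t <- sqrt(pmax(diag(cov_t), 0))
  est <- unlist(theta)
  # delta method back to the natural scale
  dscale <- vapply(seq_along(free), function(i) {
    if (free[i] == "M0") est[i] * (1 - est[i]) else est[i]
  }, numeric(1))
  se <- se_t * dscale
  flags <- character()
  if (!fit$info %in% 1:4) flags <- c(flags, "non-convergence")
  info_diag <- diag(hess)
  unident <- free[info_diag < 1e-8 * max(info_diag, 1)]
  if (length(unident)) flags <- c(flags, paste0("unidentifiable:", paste(unident, collapse = ",")))
  new_kin_fit(
    model = "opto",
    params = tibble(
      term = free, estimate = unname(est), std_error = unname(se),
      conf_low = unname(est - qnorm(0.975) * se),
      conf_high = unname(est + qnorm(0.975) * se)
    ),
    rss = rss, n_residuals = n_res, n_params = n_par,
    converged = fit$info %in% 1:4 && length(unident) == 0,
    flags = flags,
    data = trace,
    variant = variant_label(variant),
    extra = list(variant = variant, weights = weights, sigma2 = sigma2,
                 theta = theta, par_packed = fit$par)
  )
}

#' Phase-restricted confidence-interval widths
#'
#' Quantifies how much each acquisition phase constrains the fitted rates:
#' the model is fitted (or the curvature evaluated) using residuals from the
#' release (lit) phase only, the recovery (post-lit dark) phase only, or
#' both, and the approximate 95% confidence-interval width is reported per
#' parameter. Using both phases can only add curvature, so both-phase
#' intervals are expected to be no wider than either single-phase interval
#' on matched data. Parameters with no curvature in a phase (e.g. lit rates
#' from recovery-only data) are reported as `Inf` and flagged.
#'
#' @param trace A normalised `compartment_trace`.
#' @param variant A [model_variant()].
#' @param phases Character vector from `c("release", "recovery", "both")`.
#' @param refit If `TRUE` (default) the model is refitted on each phase
#'   restriction; otherwise the curvature is evaluated at the both-phase
#'   estimate.
#' @param guesses,seed,... Passed to [fit_opto_model()].
#' @return A tibble with columns `phase`, `term`, `estimate`, `ci_width`.
#' @export
phase_restricted_ci <- function(trace, variant = model_variant(),
                                phases = c("release", "recovery", "both"),
                                refit = TRUE, guesses = NULL, seed = 1, ...) {
  phases <- match.arg(phases, several.ok = TRUE)
  lit <- trace$lit
  last_lit <- max(which(lit))
  masks <- list(
    release = seq_along(lit) <= last_lit,
    recovery = seq_along(lit) > last_lit,
    both = rep(TRUE, length(lit))
  )
  full_fit <- fit_opto_model(trace, variant, guesses = guesses, seed = seed, ...)
  free <- full_fit$params$term
  weights <- full_fit$extra$weights
  out <- list()
  for (ph in phases) {
    mask <- masks[[ph]]
    if (!any(mask)) abort(paste0("phase `", ph, "` not present in trace"))
    p_at <- full_fit$extra$par_packed
    if (refit && ph != "both") {
      obj <- function(p) {
        theta <- unpack_theta(setNames(as.list(p), free))
        opto_residuals(theta, full_fit$extra$variant, trace, weights, frame_mask = mask)
      }
      ft <- tryCatch(
        minpack.lm::nls.lm(p_at, fn = obj,
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL
      )
      if (!is.null(ft)) p_at <- ft$par
    }
    theta <- unpack_theta(setNames(as.list(p_at), free))
    rfun <- function(p) {
      th <- unpack_theta(setNames(as.list(p), free))
      opto_residuals(th, full_fit$extra$variant, trace, weights, frame_mask = mask)
    }
    r0 <- rfun(p_at)
    J <- num_jacobian(rfun, p_at)
    jtj <- crossprod(J)
    sigma2 <- sum(r0^2) / max(length(r0) - length(p_at), 1)
    d <- diag(jtj)
    widths <- rep(Inf, length(free))
    ok <- d > 1e-10 * max(d, 1)
    if (any(ok)) {
      cov_ok <- tryCatch(solve(jtj[ok, ok, drop = FALSE]) * sigma2,
                         error = function(e) NULL)
      if (!is.null(cov_ok)) {
        se_t <- sqrt(pmax(diag(cov_ok), 0))
        est_ok <- unlist(theta)[ok]
        dsc <- ifelse(free[ok] == "M0", est_ok * (1 - est_ok), est_ok)
        widths[ok] <- 2 * qnorm(0.975) * se_t * dsc
      }
    }
    out[[ph]] <- tibble(phase = ph, term = free,
                        estimate = unname(unlist(theta)), ci_width = widths)
  }
  bind_rows(out)
}

num_jacobian <- function(f, p, eps = 1e-6) {
  f0 <- f(p)
  J <- matrix(NA_real_, nrow = length(f0), ncol = length(p))
  for (i in seq_along(p)) {
    dp <- p
    h <- eps * max(abs(p[i]), 1)
    dp[i] <- p[i] + h
    J[, i] <- (f(dp) - f0) / h
  }
  J
}

#' Compare optogenetic model variants by AIC
#'
#' Fits each variant to the same normalised trace and compares the quality
#' of fit with the Gaussian-residual Akaike information criterion
#' `AIC = n log(RSS / n) + 2k` (k = fitted parameters + 1 for the residual
#' variance). Akaike weights `w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)`
#' ("AIC probability") are reported over the successfully fitted set.
#'
#' @param trace A normalised `compartment_trace`.
#' @param variants A named list of [model_variant()] objects (at least 2).
#' @param ... Passed to [fit_opto_model()].
#' @return A tibble with one row per variant: `variant`, `rss`, `n_params`,
#'   `aic`, `delta_aic`, `akaike_weight`, `converged`, `note`; fits are
#'   attached as attribute `fits`.
#' @export
compare_models_aic <- function(trace, variants, ...) {
  if (length(variants) < 2L) abort("need at least 2 variants to compare")
  if (is.null(names(variants))) {
    names(variants) <- vapply(variants, variant_label, character(1))
  }
  fits <- purrr::imap(variants, function(v, nm) {
    tryCatch(fit_opto_model(trace, v, ...), error = function(e) e)
  })
  failed <- purrr::map_lgl(fits, ~ inherits(.x, "error"))
  rows <- purrr::imap(fits, function(f, nm) {
    if (inherits(f, "error")) {
      tibble(variant = nm, rss = NA_real_, n_params = NA_integer_,
             aic = NA_real_, converged = FALSE,
             note = paste("fit failed:", conditionMessage(f)))
    } else {
      tibble(variant = nm, rss = f$rss, n_params = f$n_params,
             aic = kin_fit_aic(f), converged = f$converged,
             note = paste(f$flags, collapse = ";"))
    }
  })
  out <- bind_rows(rows)
  ok <- !is.na(out$aic)
  out$delta_aic <- NA_real_
  out$akaike_weight <- NA_real_
  if (any(ok)) {
    d <- out$aic[ok] - min(out$aic[ok])
    w <- exp(-d / 2)
    out$delta_aic[ok] <- d
    out$akaike_weight[ok] <- w / sum(w)
  }
  out <- out[, c("variant", "rss", "n_params", "aic", "delta_aic",
                 "akaike_weight", "converged", "note")]
  for (nm in names(fits)) {
    if (!inherits(fits[[nm]], "error")) {
      fits[[nm]]$aic <- out$aic[out$variant == nm]
      fits[[nm]]$akaike_weight <- out$akaike_weight[out$variant == nm]
    }
  }
  attr(out, "fits") <- fits[!failed]
  out
}
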