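# Shared container for all model fits (opto ODE, FRAP PDE, FLIP ODE).
# Carries tidy parameter estimates, residual summaries, convergence and
# identifiability flags, and optional model-comparison fields (AIC, Akaike
# weight, variant tag).
new_kin_fit <- function(model, params, rss, n_residuals, n_params,
                        converged, flags = character(), data = NULL,
                        variant = NULL, extra = list()) {
  structure(
    list(
      model = model,
      params = params,
      rss = rss,
      n_residuals = n_residuals,
      n_params = n_params,
      converged = converged,
      flags = flags,
      variant = variant,
      aic = NA_real_,
      akaike_weight = NA_real_,
      data = data,
      extra = extra
    ),
    class = c(paste0(model, "_fit"), "kin_fit")
  )
}

# Gaussian-residual AIC: n * log(RSS / n) + 2k, k counting the fitted
# parameters plus one for the residual variance.
kin_fit_aic <- function(fit) {
  n <- fit$n_residuals
  k <- fit$n_params + 1
  n * log(fit$rss / n) + 2 * k
}

#' @export
print.kin_fit <- function(x, ...) {
  cat(sprintf("<%s fit>%s\n", x$model,
              if (!is.null(x$variant)) paste0(" variant: ", x$variant) else ""))
  cat(sprintf("  converged: %s   RSS: %.4g   residuals: %d   params: %d\n",
              x$converged, x$rss, x$n_residuals, x$n_params))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  print(x$params)
  invisible(x)
}

#' Tidy a kinetic model fit
#'
#' @param x A fit returned by [fit_opto_model()], [fit_frap()] or
#'   [fit_flip()].
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `std_error`, `conf_low`, `conf_high`.
#' @export
tidy.kin_fit <- function(x, ...) {
  x$params
}

#' One-row summary of a kinetic model fit
#'
#' @param x A fit object.
#' @param ... Unused.
#' @return A one-row tibble with `model`, `variant`, `rss`, `n_residuals`,
#'   `n_params`, `aic`, `akaike_weight`, `converged`, `flags`.
#' @export
glance.kin_fit <- function(x, ...) {
  tibble(
    model = x$model,
    variant = x$variant %||% NA_character_,
    rss = x$rss,
    n_residuals = x$n_residuals,
    n_params = x$n_params,
    aic = if (is.na(x$aic)) kin_fit_aic(x) else x$aic,
    akaike_weight = x$akaike_weight,
    converged = x$converged,
    flags = paste(x$flags, collapse = ";")
  )
}

# Named vector of point estimates.
#' @export
coef.kin_fit <- function(object, ...) {
  setNames(object$params$estimate, object$params$term)
}
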