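#' Subtract extracellular background from a compartment trace
#'
#' The mean of a user-defined region away from any cell is subtracted
#' frame-wise from each compartment intensity. Values driven negative are
#' floored at zero and counted.
#'
#' @param trace A `compartment_trace` (raw intensities).
#' @param background_trace Numeric vector of background intensities per
#'   frame, or a single number.
#' @return The background-subtracted trace; the number of floored values is
#'   attached as attribute `n_floored` (with a warning when non-zero).
#' @export
subtract_background <- function(trace, background_trace) {
  bg <- rep_len(as.numeric(background_trace), nrow(trace))
  out <- trace
  n_floored <- 0L
  for (cmp in c("M", "C", "N")) {
    v <- trace[[cmp]] - bg
    n_floored <- n_floored + sum(v < 0)
    out[[cmp]] <- pmax(v, 0)
  }
  if (n_floored > 0L) {
    warn(sprintf("%d background-subtracted values were negative and floored at 0", n_floored))
  }
  attr(out, "n_floored") <- n_floored
  out
}

#' Bilinear photobleaching normalisation
#'
#' Laser bleaching is approximately linear within each illumination phase,
#' so the total cell intensity `M + C + N` is estimated by a separate
#' least-squares line per phase (release = frames up to the end of the lit
#' block, recovery = the frames after it), fitted away from the phase
#' starts where noise is larger. Each compartment is then divided frame-wise
#' by the fitted bilinear total, turning intensities into proportions of
#' total cell signal (which the model assumes is conserved at one).
#'
#' @param trace A background-subtracted `compartment_trace`.
#' @param schedule Optional [light_schedule()]; defaults to the `lit` column
#'   of the trace.
#' @param exclusion_fraction Fraction of each phase's frames, at the phase
#'   start, excluded from the line fit (default 0.2).
#' @return A normalised `compartment_trace` (attribute `normalized = TRUE`);
#'   the fitted line coefficients are attached as attribute `bilinear_fit`.
#' @export
bilinear_normalise <- function(trace, schedule = NULL, exclusion_fraction = 0.2) {
  lit <- if (is.null(schedule)) trace$lit else schedule$lit
  if (!any(lit) || all(lit)) abort("trace must contain both lit and unlit phases")
  times <- trace$time_s
  total <- trace$M + trace$C + trace$N
  # release phase: everything up to the last lit frame (the few dark
  # pre-activation frames ride with it); recovery: the frames after.
  last_lit <- max(which(lit))
  if (last_lit >= length(lit)) abort("no recovery (post-lit) phase in trace")
  phases <- list(release = seq_len(last_lit),
                 recovery = seq(last_lit + 1L, length(lit)))
  fitted_total <- numeric(length(total))
  coefs <- list()
  for (ph in names(phases)) {
    idx <- phases[[ph]]
    n_excl <- floor(exclusion_fraction * length(idx))
    use <- idx[setdiff(seq_along(idx), seq_len(n_excl))]
    if (length(use) < 3L) abort(sprintf("phase `%s` has fewer than 3 usable frames", ph))
    fit <- lm(total[use] ~ times[use])
    coefs[[ph]] <- c(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]))
    fitted_total[idx] <- coefs[[ph]]["intercept"] + coefs[[ph]]["slope"] * times[idx]
  }
  if (any(fitted_total <= 0)) abort("bilinear fit of total intensity is non-positive")
  out <- trace
  out$M <- trace$M / fitted_total
  out$C <- trace$C / fitted_total
  out$N <- trace$N / fitted_total
  attr(out, "normalized") <- TRUE
  attr(out, "bilinear_fit") <- coefs
  class(out) <- unique(c("compartment_trace", class(out)))
  out
}
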