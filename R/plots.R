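#' Plot a compartment trace
#'
#' Line plot of the mitochondrial, cytoplasmic and nuclear signals over
#' time, with lit phases shaded.
#'
#' @param object A `compartment_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.compartment_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("M", "C", "N"),
                              names_to = "compartment", values_to = "intensity")
  long$compartment <- factor(long$compartment, c("M", "C", "N"),
                             c("mitochondria", "cytoplasm", "nucleus"))
  lit_blocks <- schedule_blocks(object)
  lit_blocks <- lit_blocks[lit_blocks$lit, , drop = FALSE]
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$time_s, .data$intensity,
                                          colour = .data$compartment))
  if (nrow(lit_blocks)) {
    shade <- tibble(
      xmin = object$time_s[lit_blocks$start],
      xmax = object$time_s[lit_blocks$end]
    )
    p <- p + ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax, ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "lightskyblue", alpha = 0.25
    )
  }
  p +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "time (s)",
      y = if (is_normalized(object)) "proportion of total" else "intensity (a.u.)",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot an optogenetic model fit
#'
#' Overlays the fitted model trace on the data, per compartment.
#'
#' @param object An `opto_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.opto_fit <- function(object, ...) {
  trace <- object$data
  sim <- opto_model_trace(object$extra$theta, object$extra$variant, trace)
  obs <- tidyr::pivot_longer(as_tibble(trace)[c("time_s", "M", "C", "N")],
                             c("M", "C", "N"), names_to = "compartment")
  fitl <- tidyr::pivot_longer(as_tibble(sim)[c("time_s", "M", "C", "N")],
                              c("M", "C", "N"), names_to = "compartment")
  ggplot2::ggplot(obs, ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::geom_line(data = fitl, colour = "firebrick") +
    ggplot2::facet_wrap(~compartment, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "proportion of total") +
    ggplot2::theme_minimal()
}

#' Plot FRAP recovery curves
#'
#' Mean intensity inside the bleach ROI over time, with the bleach instant
#' marked.
#'
#' @param object A `frap_series`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.frap_series <- function(object, ...) {
  mask <- object$geometry$mask
  center <- object$protocol$roi_center %||% ((dim(mask) + 1) / 2)
  rr <- matrix(seq_len(nrow(mask)), nrow(mask), ncol(mask))
  cc <- matrix(seq_len(ncol(mask)), nrow(mask), ncol(mask), byrow = TRUE)
  roi <- mask & sqrt((rr - center[1])^2 + (cc - center[2])^2) <= object$protocol$roi_radius
  df <- tibble(
    time_s = object$times,
    roi_mean = apply(object$frames, 3, function(fr) mean(fr[roi]))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$roi_mean)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "time since bleach (s)", y = "ROI mean intensity") +
    ggplot2::theme_minimal()
}

#' Plot a FLIP trace
#' @param object A `flip_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flip_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("n", "c"),
                              names_to = "compartment")
  long$compartment <- factor(long$compartment, c("n", "c"),
                             c("nucleus", "cytoplasm"))
  ggplot2::ggplot(long, ggplot2::aes(.data$time_s, .data$value,
                                     colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "normalised intensity", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a regional gain map
#'
#' @param gain_map Result of [regional_gain_map()].
#' @return A ggplot object (raster heat map; 256 = no change).
#' @export
plot_gain_map <- function(gain_map) {
  g <- gain_map$gain
  df <- tibble(
    row = rep(seq_len(nrow(g)), ncol(g)),
    col = rep(seq_len(ncol(g)), each = nrow(g)),
    gain = as.vector(g)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$gain)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey80") +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "gain\n(256 = no change)") +
    ggplot2::theme_void()
}
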