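#' Multi-channel time-lapse image stack
#'
#' A 4D intensity array (rows x cols x channels x frames) with named channel
#' roles and acquisition metadata. Channels carry the protein of interest,
#' a mitochondrial marker and a nuclear marker.
#'
#' @param data Numeric 4D array `[row, col, channel, frame]`.
#' @param channel_roles Character vector naming each channel's role; must
#'   contain unique values from `"protein"`, `"mitochondria"`, `"nucleus"`.
#' @param pixel_size Pixel size, micrometres.
#' @param frame_interval Frame spacing, seconds.
#' @return An `image_stack` object.
#' @export
image_stack <- function(data, channel_roles, pixel_size, frame_interval) {
  if (length(dim(data)) != 4L) abort("data must be a 4D array [row, col, channel, frame]")
  if (dim(data)[4] < 1L) abort("stack must contain at least one frame")
  if (length(channel_roles) != dim(data)[3]) {
    abort("channel_roles must name every channel")
  }
  if (anyDuplicated(channel_roles)) abort("channel roles must be unique")
  structure(
    list(data = data, channel_roles = channel_roles,
         pixel_size = pixel_size, frame_interval = frame_interval),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> %d x %d px, %d channel(s) [%s], %d frame(s)\n",
              d[1], d[2], d[3], paste(x$channel_roles, collapse = ", "), d[4]))
  cat(sprintf("  pixel %g um, frame interval %g s\n", x$pixel_size, x$frame_interval))
  invisible(x)
}

stack_channel <- function(stack, role) {
  i <- match(role, stack$channel_roles)
  if (is.na(i)) abort(paste0("stack has no `", role, "` channel"))
  stack$data[, , i, , drop = TRUE]
}

n_frames <- function(stack) dim(stack$data)[4]

#' Per-frame compartment masks
#'
#' Boolean masks (rows x cols x frames) for the cell, nucleus, mitochondria
#' and cytoplasm. Invariants: nucleus and mitochondria lie inside the cell,
#' the reported compartments are pairwise disjoint, and
#' cytoplasm = cell minus (nucleus union mitochondria).
#'
#' @param cell,nucleus,mitochondria,cytoplasm Logical 3D arrays.
#' @return A `compartment_masks` object.
#' @export
compartment_masks <- function(cell, nucleus, mitochondria, cytoplasm = NULL) {
  if (is.null(cytoplasm)) cytoplasm <- cell & !nucleus & !mitochondria
  if (any(nucleus & !cell)) abort("nucleus must lie inside the cell")
  if (any(mitochondria & !cell)) abort("mitochondria must lie inside the cell")
  structure(
    list(cell = cell, nucleus = nucleus, mitochondria = mitochondria,
         cytoplasm = cytoplasm),
    class = "compartment_masks"
  )
}

# Jaccard index between two logical masks; used throughout validation.
#' Jaccard overlap between two masks
#' @param a,b Logical arrays of equal dimension.
#' @return Intersection-over-union in `[0, 1]`.
#' @export
mask_jaccard <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
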