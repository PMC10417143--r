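#' Multi-channel 3-D image stack
#'
#' Light container for a 3-channel confocal z-stack. Voxels are stored as a
#' 4-D numeric array indexed `[row, column, layer, channel]` with channels
#' ordered marker, membrane, nuclei. Geometry defaults follow a 40x air
#' objective acquisition: 0.7 um z-steps and a 512-pixel field of view
#' spanning 317.95 um.
#'
#' @param voxels Numeric 4-D array `[height, width, n_layers, 3]` of
#'   nonnegative intensities.
#' @param z_step Axial step between consecutive layers, in micrometres.
#' @param pixel_size Lateral pixel size in micrometres.
#' @param channel_names Ordered channel labels; the quantification code
#'   relies on the marker/membrane/nuclei order and refuses anything else.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels,
                        z_step = 0.7,
                        pixel_size = 317.95 / 512,
                        channel_names = c("marker", "membrane", "nuclei")) {
  if (!is.array(voxels) || length(dim(voxels)) != 4L) {
    stop("`voxels` must be a 4-D array [height, width, n_layers, channel]",
         call. = FALSE)
  }
  if (dim(voxels)[4] != 3L) {
    stop("exactly three channels (marker, membrane, nuclei) are required",
         call. = FALSE)
  }
  if (dim(voxels)[3] < 1L) stop("at least one layer is required", call. = FALSE)
  if (any(voxels < 0)) stop("intensities must be nonnegative", call. = FALSE)
  if (!identical(as.character(channel_names),
                 c("marker", "membrane", "nuclei"))) {
    stop("channel order must be marker, membrane, nuclei; ",
         "reorder the input instead of relabelling", call. = FALSE)
  }
  if (!is.numeric(z_step) || length(z_step) != 1L || z_step <= 0) {
    stop("`z_step` must be a single positive number", call. = FALSE)
  }
  dimnames(voxels)[[4]] <- channel_names
  structure(
    list(voxels = voxels, z_step = z_step, pixel_size = pixel_size,
         channel_names = as.character(channel_names)),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<image_stack> %d x %d px, %d layers (%.1f um at %.2f um/layer), channels: %s\n",
    d[1], d[2], d[3], stack_thickness(d[3], x$z_step), x$z_step,
    paste(x$channel_names, collapse = "/")))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$voxels)

#' Number of z-layers in a stack
#' @param stack An `image_stack`.
#' @return Integer layer count.
#' @export
n_layers <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  dim(stack$voxels)[3]
}

#' Physical thickness of a scanned stack
#'
#' Converts a layer count into micrometres of tissue depth, e.g. 199 layers
#' at 0.7 um/layer span 139.3 um.
#'
#' @param n_layers Nonnegative layer count.
#' @param z_step Axial step in micrometres per layer (default 0.7).
#' @return Thickness in micrometres.
#' @export
stack_thickness <- function(n_layers, z_step = 0.7) {
  if (any(n_layers < 0)) stop("`n_layers` must be nonnegative", call. = FALSE)
  if (any(z_step <= 0)) stop("`z_step` must be positive", call. = FALSE)
  n_layers * z_step
}

#' Z-projection of a stack
#'
#' Collapses the stack to one 2-D image per channel. The only supported mode
#' is `"sum"`, which adds intensities across layers so the total intensity of
#' each channel is conserved exactly.
#'
#' @param stack An `image_stack`.
#' @param mode Projection mode; only `"sum"`.
#' @return A named list of `height x width` matrices, one per channel.
#' @export
z_projection <- function(stack, mode = "sum") {
  stopifnot(inherits(stack, "image_stack"))
  if (!identical(mode, "sum")) {
    stop("unknown projection mode: ", mode, " (only \"sum\" is supported)",
         call. = FALSE)
  }
  out <- lapply(seq_along(stack$channel_names), function(ch) {
    v <- stack$voxels[, , , ch, drop = FALSE]
    dim(v) <- dim(stack$voxels)[1:3]
    rowSums(v, dims = 2L)
  })
  names(out) <- stack$channel_names
  out
}

#' Write a stack as multi-page TIFF plus a JSON sidecar
#'
#' Pages are ordered layer-within-channel (all marker layers, then membrane,
#' then nuclei); the sidecar records geometry and the channel order so a
#' round-trip restores the stack exactly. Intensities are stored as 16-bit.
#'
#' @param stack An `image_stack` with integer intensities in `[0, 65535]`.
#' @param path Output TIFF path; the sidecar is written at `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  if (any(stack$voxels > 65535)) {
    stop("intensities exceed the 16-bit range", call. = FALSE)
  }
  d <- dim(stack$voxels)
  pages <- list()
  for (ch in seq_len(d[4])) {
    for (z in seq_len(d[3])) {
      pages[[length(pages) + 1L]] <- stack$voxels[, , z, ch] / 65535
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(
    z_step = stack$z_step, pixel_size = stack$pixel_size,
    channel_names = stack$channel_names,
    n_layers = d[3], height = d[1], width = d[2],
    page_order = "layer-within-channel"
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a stack written by [write_stack()]
#'
#' @param path TIFF path with a `<path>.json` sidecar.
#' @return An `image_stack`.
#' @export
read_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(meta$channel_names, c("marker", "membrane", "nuclei"))) {
    stop("sidecar channel order is not marker/membrane/nuclei: ",
         paste(meta$channel_names, collapse = "/"), call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  vox <- array(0, dim = c(meta$height, meta$width, meta$n_layers, 3L))
  i <- 1L
  for (ch in 1:3) {
    for (z in seq_len(meta$n_layers)) {
      vox[, , z, ch] <- round(pages[[i]] * 65535)
      i <- i + 1L
    }
  }
  image_stack(vox, z_step = meta$z_step, pixel_size = meta$pixel_size,
              channel_names = meta$channel_names)
}
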