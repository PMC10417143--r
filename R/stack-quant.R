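#' Background subtraction
#'
#' Subtracts an estimated background from every layer of every channel and
#' clamps negatives to zero. `method = "percentile"` estimates the background
#' of each layer/channel as the given intensity percentile of that layer
#' (default 20th); `method = "constant"` subtracts a fixed intensity.
#'
#' @param stack An `image_stack`.
#' @param method `"percentile"` or `"constant"`.
#' @param level Percentile in `[0, 100]`, or the constant intensity.
#' @return An `image_stack` of the same geometry.
#' @export
subtract_background <- function(stack, method = c("percentile", "constant"),
                                level = 20) {
  stopifnot(inherits(stack, "image_stack"))
  method <- match.arg(method)
  if (method == "percentile" && (level < 0 || level > 100)) {
    stop("percentile `level` must lie in [0, 100]", call. = FALSE)
  }
  if (method == "constant" && level < 0) {
    stop("constant `level` must be nonnegative", call. = FALSE)
  }
  v <- stack$voxels
  d <- dim(v)
  for (ch in seq_len(d[4])) {
    for (z in seq_len(d[3])) {
      layer <- v[, , z, ch]
      bg <- if (method == "percentile") {
        stats::quantile(layer, probs = level / 100, names = FALSE)
      } else {
        level
      }
      v[, , z, ch] <- pmax(layer - bg, 0)
    }
  }
  stack$voxels <- v
  stack
}

# median of three matrices, elementwise
med3 <- function(a, b, c) pmax(pmin(a, b), pmin(pmax(a, b), c))

# edge-replicated shift of a matrix by (di, dj)
shift_mat <- function(x, di, dj) {
  nr <- nrow(x); nc <- ncol(x)
  ri <- pmin(pmax(seq_len(nr) + di, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dj, 1L), nc)
  x[ri, ci, drop = FALSE]
}

# 2-D median filter of one matrix, edge-replicated
median_filter_layer <- function(x, window) {
  if (window == 1L) return(x)
  half <- (window - 1L) %/% 2L
  offs <- expand.grid(di = -half:half, dj = -half:half)
  shifted <- lapply(seq_len(nrow(offs)),
                    function(i) shift_mat(x, offs$di[i], offs$dj[i]))
  if (window == 3L) {
    # sort each column of the 3x3 neighbourhood, then take
    # med3(max of minima, median of medians, min of maxima)
    lo <- mi <- hi <- vector("list", 3L)
    for (j in 0:2) {
      a <- shifted[[3 * j + 1]]; b <- shifted[[3 * j + 2]]; c <- shifted[[3 * j + 3]]
      lo[[j + 1]] <- pmin(a, b, c)
      hi[[j + 1]] <- pmax(a, b, c)
      mi[[j + 1]] <- med3(a, b, c)
    }
    return(med3(pmax(lo[[1]], lo[[2]], lo[[3]]),
                med3(mi[[1]], mi[[2]], mi[[3]]),
                pmin(hi[[1]], hi[[2]], hi[[3]])))
  }
  flat <- vapply(shifted, as.vector, numeric(length(x)))
  out <- apply(flat, 1L, stats::median)
  matrix(out, nrow(x), ncol(x))
}

#' Per-layer 2-D median filter
#'
#' Applies a square median filter to every layer of every channel
#' independently (the boundary is edge-replicated). `window = 1` is the
#' identity.
#'
#' @param stack An `image_stack`.
#' @param window Odd window side length.
#' @return A filtered `image_stack`.
#' @export
median_filter <- function(stack, window = 3L) {
  stopifnot(inherits(stack, "image_stack"))
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    stop("`window` must be an odd integer >= 1", call. = FALSE)
  }
  if (window == 1L) return(stack)
  v <- stack$voxels
  d <- dim(v)
  for (ch in seq_len(d[4])) {
    for (z in seq_len(d[3])) {
      v[, , z, ch] <- median_filter_layer(v[, , z, ch], window)
    }
  }
  stack$voxels <- v
  stack
}

#' Count supra-threshold pixels per layer and channel
#'
#' A pixel counts when its intensity is strictly greater than the channel's
#' threshold.
#'
#' @param stack An `image_stack`.
#' @param threshold Single threshold or one per channel (marker, membrane,
#'   nuclei order).
#' @return A tibble with columns `layer`, `marker`, `membrane`, `nuclei`.
#' @export
count_channel_pixels <- function(stack, threshold = 0) {
  stopifnot(inherits(stack, "image_stack"))
  if (any(threshold < 0)) stop("thresholds must be >= 0", call. = FALSE)
  thr <- rep_len(threshold, 3L)
  d <- dim(stack$voxels)
  counts <- vapply(1:3, function(ch) {
    v <- stack$voxels[, , , ch, drop = FALSE]
    dim(v) <- d[1:3]
    colSums(matrix(v > thr[ch], nrow = d[1] * d[2], ncol = d[3]))
  }, numeric(d[3]))
  counts <- matrix(counts, nrow = d[3], ncol = 3L)
  tibble::tibble(layer = seq_len(d[3]),
                 marker = counts[, 1], membrane = counts[, 2],
                 nuclei = counts[, 3])
}

#' Per-layer relative marker intensity
#'
#' The study statistic: for each layer, marker-positive pixel count divided
#' by membrane-positive pixel count. Layers without any membrane signal have
#' an undefined ratio; they are flagged `defined = FALSE` (with `r = NA`) and
#' are excluded from downstream layer selection and clustering.
#'
#' @param counts Tibble from [count_channel_pixels()] (columns `layer`,
#'   `marker`, `membrane`; `nuclei` optional).
#' @return A `layer_profile` tibble with columns `layer`, `marker_count`,
#'   `membrane_count`, `nuclei_count`, `r`, `defined`.
#' @export
relative_intensity <- function(counts) {
  stopifnot(all(c("layer", "marker", "membrane") %in% names(counts)))
  defined <- counts$membrane > 0
  r <- ifelse(defined, counts$marker / counts$membrane, NA_real_)
  out <- tibble::tibble(
    layer = counts$layer,
    marker_count = counts$marker,
    membrane_count = counts$membrane,
    nuclei_count = if ("nuclei" %in% names(counts)) counts$nuclei else NA_real_,
    r = r,
    defined = defined
  )
  class(out) <- c("layer_profile", class(out))
  out
}

#' Quantify a stack into a layer profile
#'
#' Convenience wrapper running the full preprocessing chain: background
#' subtraction, per-layer median filtering, supra-threshold pixel counting,
#' and the relative-intensity ratio.
#'
#' @param stack An `image_stack`.
#' @param bg_method,bg_level Passed to [subtract_background()].
#' @param median_window Passed to [median_filter()]; `1` skips filtering.
#' @param count_threshold Passed to [count_channel_pixels()].
#' @return A `layer_profile` tibble.
#' @export
quantify_stack <- function(stack, bg_method = "percentile", bg_level = 20,
                           median_window = 3L, count_threshold = 0) {
  stack |>
    subtract_background(method = bg_method, level = bg_level) |>
    median_filter(window = median_window) |>
    count_channel_pixels(threshold = count_threshold) |>
    relative_intensity()
}

#' Select the supra-cutoff layer range
#'
#' Finds the longest contiguous run of layers whose relative intensity
#' strictly exceeds `cutoff` (default 0.01, the weak-signal filter).
#' Undefined layers break runs. With `contiguous = FALSE` all supra-cutoff
#' layers are counted instead and `first`/`last` bound them.
#'
#' @param profile A `layer_profile`.
#' @param cutoff Relative-intensity cutoff.
#' @param contiguous Return the longest contiguous run (default) or all
#'   supra-cutoff layers.
#' @return One-row tibble `first`, `last`, `n_selected`, `thickness_um`.
#'   An empty selection has `NA` bounds and zero thickness.
#' @export
select_layers <- function(profile, cutoff = 0.01, contiguous = TRUE) {
  stopifnot(inherits(profile, "layer_profile") || is.data.frame(profile))
  if (nrow(profile) == 0L) stop("`profile` is empty", call. = FALSE)
  z_step <- attr(profile, "z_step") %||% 0.7
  above <- !is.na(profile$r) & profile$r > cutoff
  if (!any(above)) {
    return(tibble::tibble(first = NA_integer_, last = NA_integer_,
                          n_selected = 0L, thickness_um = 0))
  }
  if (contiguous) {
    runs <- rle(above)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    idx <- which(runs$values)
    best <- idx[which.max(runs$lengths[idx])]
    first <- profile$layer[starts[best]]
    last <- profile$layer[ends[best]]
    n_sel <- runs$lengths[best]
  } else {
    first <- profile$layer[which(above)[1]]
    last <- profile$layer[rev(which(above))[1]]
    n_sel <- sum(above)
  }
  tibble::tibble(first = as.integer(first), last = as.integer(last),
                 n_selected = as.integer(n_sel),
                 thickness_um = stack_thickness(n_sel, z_step))
}
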