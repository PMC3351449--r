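#' Multi-channel 3D image stack container
#'
#' Thin container for confocal-like voxel data. Voxels are stored as a
#' `(y, x, z)` array for a single channel or `(y, x, z, channel)` for
#' multi-channel stacks, with non-negative integer intensities bounded by the
#' declared bit depth. The dorsoventral axis is the `y` axis; `dv_dorsal`
#' records which direction is dorsal (`"low"` = toward row 1).
#'
#' @param voxels 3D or 4D array of non-negative intensities (ADU).
#' @param bit_depth 8 or 16.
#' @param dv_dorsal `"low"` or `"high"`.
#' @param channel_names optional character vector naming the channels.
#' @return An object of class `volume_stack`.
#' @export
volume_stack <- function(voxels, bit_depth = 8L, dv_dorsal = "low",
                         channel_names = NULL) {
  if (!length(dim(voxels)) %in% c(3L, 4L))
    stop("voxels must be a (y,x,z) or (y,x,z,channel) array")
  if (min(voxels) < 0) stop("intensities must be non-negative")
  if (max(voxels) > 2^bit_depth - 1)
    stop("intensities exceed the declared bit depth")
  nch <- if (length(dim(voxels)) == 4L) dim(voxels)[4] else 1L
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nch))
  structure(list(voxels = voxels, bit_depth = as.integer(bit_depth),
                 dv_dorsal = dv_dorsal, channel_names = channel_names),
            class = "volume_stack")
}

#' @export
print.volume_stack <- function(x, ...) {
  d <- dim(x$voxels)
  nch <- if (length(d) == 4L) d[4] else 1L
  cat(sprintf("volume_stack: %d x %d x %d voxels, %d channel(s), %d-bit, dorsal = %s y\n",
              d[1], d[2], d[3], nch, x$bit_depth,
              if (x$dv_dorsal == "low") "decreasing" else "increasing"))
  invisible(x)
}

#' @export
dim.volume_stack <- function(x) dim(x$voxels)

#' Extract one channel of a stack
#'
#' @param stack a [volume_stack()].
#' @param channel channel index or name.
#' @return A single-channel `volume_stack`; the voxel data of that channel
#'   is returned unchanged.
#' @export
select_channel <- function(stack, channel = 1L) {
  stopifnot(inherits(stack, "volume_stack"))
  if (is.character(channel)) {
    channel <- match(channel, stack$channel_names)
    if (is.na(channel)) stop("unknown channel name")
  }
  nch <- if (length(dim(stack$voxels)) == 4L) dim(stack$voxels)[4] else 1L
  if (channel < 1L || channel > nch) stop("channel index out of range")
  vox <- if (length(dim(stack$voxels)) == 4L) stack$voxels[, , , channel,
                                                           drop = TRUE]
         else stack$voxels
  if (length(dim(vox)) == 2L) vox <- array(vox, c(dim(vox), 1L))
  volume_stack(vox, bit_depth = stack$bit_depth, dv_dorsal = stack$dv_dorsal,
               channel_names = stack$channel_names[channel])
}

#' Maximum-intensity projection along z
#'
#' Projects a single-channel volume to 2D by taking, for every `(y, x)`
#' column, the maximum intensity over z. By default the projection is
#' rescaled to the 8-bit gray range (a no-op for 8-bit input), so that
#' downstream scores live on a fixed intensity scale; set
#' `rescale_8bit = FALSE` to keep the native depth.
#'
#' @param volume a single-channel [volume_stack()] or a (y,x,z) array.
#' @param rescale_8bit rescale linearly to 0..255 and round.
#' @return An object of class `projection2d` with fields `pixels`,
#'   `bit_depth` and a `provenance` record.
#' @export
max_project_z <- function(volume, rescale_8bit = TRUE) {
  if (inherits(volume, "volume_stack")) {
    if (length(dim(volume$voxels)) == 4L && dim(volume$voxels)[4] > 1L)
      stop("max_project_z expects a single-channel volume; use select_channel()")
    vox <- if (length(dim(volume$voxels)) == 4L) volume$voxels[, , , 1L]
           else volume$voxels
    bd <- volume$bit_depth
    dv <- volume$dv_dorsal
    ch <- volume$channel_names[1]
  } else {
    vox <- volume; bd <- 8L; dv <- "low"; ch <- NA_character_
  }
  if (length(vox) == 0L) stop("empty volume")
  if (length(dim(vox)) == 2L) vox <- array(vox, c(dim(vox), 1L))
  px <- project_max(vox)
  rescaled <- FALSE
  if (rescale_8bit && bd > 8L) {
    px <- round(px * 255 / (2^bd - 1))
    bd <- 8L
    rescaled <- TRUE
  }
  projection2d(px, bit_depth = bd, dv_dorsal = dv,
               provenance = list(channel = ch, crop = NULL,
                                 mask_applied = FALSE, rescaled = rescaled))
}

#' 2D projection container
#'
#' @param pixels numeric (y, x) matrix of intensities.
#' @param bit_depth intensity bit depth after any rescaling.
#' @param dv_dorsal dorsoventral convention inherited from the stack.
#' @param provenance list recording source channel, crop rectangle and mask
#'   application.
#' @param mask optional logical matrix of excluded (soma) pixels.
#' @return Object of class `projection2d`.
#' @export
projection2d <- function(pixels, bit_depth = 8L, dv_dorsal = "low",
                         provenance = list(), mask = NULL) {
  stopifnot(is.matrix(pixels))
  if (!is.null(mask) && !identical(dim(mask), dim(pixels)))
    stop("mask shape must match the projection")
  structure(list(pixels = pixels, bit_depth = as.integer(bit_depth),
                 dv_dorsal = dv_dorsal, provenance = provenance, mask = mask),
            class = "projection2d")
}

#' @export
print.projection2d <- function(x, ...) {
  cat(sprintf("projection2d: %d x %d px, %d-bit%s%s\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth,
              if (!is.null(x$provenance$crop)) ", cropped" else "",
              if (isTRUE(x$provenance$mask_applied)) ", soma-masked" else ""))
  invisible(x)
}

#' Rectangular crop specification
#'
#' Half-open, 0-based pixel rectangle `[y0, y1) x [x0, x1)`, matching the
#' coordinate convention of the sidecar files.
#'
#' @param y0,y1,x0,x1 integer bounds with `0 <= y0 < y1` and `0 <= x0 < x1`.
#' @return Object of class `crop_rect`.
#' @export
crop_rect <- function(y0, y1, x0, x1) {
  if (y0 < 0 || x0 < 0 || y1 <= y0 || x1 <= x0)
    stop("degenerate crop rectangle")
  structure(list(y0 = as.integer(y0), y1 = as.integer(y1),
                 x0 = as.integer(x0), x1 = as.integer(x1)),
            class = "crop_rect")
}

#' Crop a projection to a rectangle
#'
#' @param projection a [projection2d()].
#' @param rect a [crop_rect()] within bounds.
#' @return The cropped `projection2d`; downstream maps are in the cropped
#'   frame and the rectangle is recorded in the provenance.
#' @export
crop <- function(projection, rect) {
  stopifnot(inherits(projection, "projection2d"), inherits(rect, "crop_rect"))
  d <- dim(projection$pixels)
  if (rect$y1 > d[1] || rect$x1 > d[2]) stop("crop rectangle out of bounds")
  ys <- (rect$y0 + 1L):rect$y1
  xs <- (rect$x0 + 1L):rect$x1
  projection$pixels <- projection$pixels[ys, xs, drop = FALSE]
  if (!is.null(projection$mask))
    projection$mask <- projection$mask[ys, xs, drop = FALSE]
  projection$provenance$crop <- rect
  projection
}

#' Mask out soma pixels in a projection
#'
#' Masked pixels are set to zero and flagged so that they are excluded both
#' from adaptive-threshold neighborhood statistics and from the index map:
#' a masked soma can then neither contribute to the score nor depress the
#' local mean around it.
#'
#' @param projection a [projection2d()].
#' @param mask logical matrix, same shape; `TRUE` marks soma pixels.
#' @return The masked `projection2d`.
#' @export
apply_soma_mask <- function(projection, mask) {
  stopifnot(inherits(projection, "projection2d"))
  mask <- mask > 0
  if (!identical(dim(mask), dim(projection$pixels)))
    stop("mask shape must match the projection")
  projection$pixels[mask] <- 0
  projection$mask <- if (is.null(projection$mask)) mask else projection$mask | mask
  projection$provenance$mask_applied <- TRUE
  projection
}

#' Automatic soma mask from bright compact regions
#'
#' Deterministic replacement for manual soma masking: pixels above the given
#' intensity quantile are labeled into connected components; components with
#' at least `min_area` pixels (and, if `compactness_min` is set, a
#' sufficiently disc-like shape) are kept and dilated by `dilate_px`.
#' Compactness is `4 * area / (pi * d^2)` with `d` the bounding-box
#' diagonal: about 0.5 for a disc, near zero for a thin tube, so the filter
#' keeps somata while sparing axons.
#'
#' @param projection a [projection2d()].
#' @param min_area minimum component area in px.
#' @param intensity_quantile quantile of the pixel intensities used as the
#'   brightness cutoff.
#' @param dilate_px dilation margin in px applied to the kept components.
#' @param compactness_min minimum compactness, or `NULL` to disable the
#'   shape filter.
#' @return Logical (y, x) matrix; may be empty.
#' @export
auto_soma_mask <- function(projection, min_area = 50L,
                           intensity_quantile = 0.99, dilate_px = 3L,
                           compactness_min = NULL) {
  stopifnot(inherits(projection, "projection2d"))
  px <- projection$pixels
  thr <- stats::quantile(px, intensity_quantile, names = FALSE)
  bw <- px > thr & px > 0
  if (!any(bw)) return(matrix(FALSE, nrow(px), ncol(px)))
  lab <- EBImage::bwlabel(bw * 1)
  keep <- logical(max(lab))
  for (l in seq_len(max(lab))) {
    idx <- which(lab == l, arr.ind = TRUE)
    area <- nrow(idx)
    if (area < min_area) next
    if (!is.null(compactness_min)) {
      d2 <- (diff(range(idx[, 1])) + 1)^2 + (diff(range(idx[, 2])) + 1)^2
      if (4 * area / (pi * d2) < compactness_min) next
    }
    keep[l] <- TRUE
  }
  mask <- matrix(FALSE, nrow(px), ncol(px))
  pos <- lab > 0
  mask[pos] <- keep[lab[pos]]
  if (any(mask)) mask <- dilate_mask(mask, dilate_px)
  mask
}

#' Adaptive local-mean thresholding of axon pixels
#'
#' Indexes a pixel as axon signal when its intensity exceeds the mean of its
#' odd square neighborhood by more than `offset` ADU. Borders are handled by
#' reflective padding. Soma-masked pixels are excluded from the neighborhood
#' statistics and can never be indexed.
#'
#' @param projection a [projection2d()] (soma-masked or not).
#' @param window odd window side length in px, at least 3.
#' @param offset additive offset in ADU above the local mean.
#' @return Object of class `axon_index_map`: list with the logical `map` and
#'   the threshold parameters used.
#' @export
adaptive_threshold <- function(projection, window = 25L, offset = 10) {
  stopifnot(inherits(projection, "projection2d"))
  window <- as.integer(window)
  if (window %% 2L == 0L || window < 3L) stop("window must be odd and >= 3")
  px <- projection$pixels
  if (window > min(dim(px))) stop("window larger than the image")
  valid <- if (is.null(projection$mask)) matrix(TRUE, nrow(px), ncol(px))
           else !projection$mask
  num <- box_sum(px * valid, window)
  den <- box_sum(valid * 1, window)
  local_mean <- ifelse(den > 0, num / pmax(den, 1), 0)
  map <- valid & (px > local_mean + offset)
  structure(list(map = map, window = window, offset = offset),
            class = "axon_index_map")
}

#' Sum pixel intensities over the indexed axon positions
#'
#' @param projection a [projection2d()].
#' @param index_map an [adaptive_threshold()] result (or a logical matrix).
#' @param embryo_id optional identifier carried into the result.
#' @return Object of class `score_result` with `score` (ADU sum over indexed
#'   pixels), `n_indexed_pixels` and the parameter record.
#' @export
score_projection <- function(projection, index_map, embryo_id = NA_character_) {
  stopifnot(inherits(projection, "projection2d"))
  map <- if (inherits(index_map, "axon_index_map")) index_map$map else index_map > 0
  if (!identical(dim(map), dim(projection$pixels)))
    stop("index map shape must match the projection")
  structure(list(embryo_id = embryo_id,
                 score = sum(projection$pixels[map]),
                 n_indexed_pixels = sum(map),
                 parameters = list(
                   window = if (inherits(index_map, "axon_index_map"))
                     index_map$window else NA,
                   offset = if (inherits(index_map, "axon_index_map"))
                     index_map$offset else NA,
                   provenance = projection$provenance)),
            class = "score_result")
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf("score_result%s: score = %.0f ADU over %d indexed px\n",
              if (is.na(x$embryo_id)) "" else paste0(" [", x$embryo_id, "]"),
              x$score, x$n_indexed_pixels))
  invisible(x)
}

#' Quantify one embryo: projection, masking, thresholding, scoring
#'
#' Composition of the full quantification chain:
#' [select_channel()] -> [max_project_z()] -> [crop()] ->
#' [apply_soma_mask()] -> [adaptive_threshold()] -> [score_projection()].
#'
#' @param stack a [volume_stack()].
#' @param channel channel index or name of the labeled signal.
#' @param rect optional [crop_rect()]; `NULL` scores the full frame.
#' @param mask optional logical soma mask in full-frame coordinates (cropped
#'   internally when `rect` is given); `"auto"` derives one with
#'   [auto_soma_mask()]; `NULL` applies no mask.
#' @param window,offset adaptive-threshold parameters.
#' @param rescale_8bit passed to [max_project_z()].
#' @param embryo_id identifier carried into the result.
#' @param auto_mask_args list of extra arguments for [auto_soma_mask()].
#' @return A `score_result`.
#' @export
quantify_embryo <- function(stack, channel = 1L, rect = NULL, mask = NULL,
                            window = 25L, offset = 10, rescale_8bit = TRUE,
                            embryo_id = NA_character_,
                            auto_mask_args = list()) {
  proj <- max_project_z(select_channel(stack, channel),
                        rescale_8bit = rescale_8bit)
  auto <- identical(mask, "auto")
  if (!auto && !is.null(mask)) {
    full_mask <- mask > 0
    if (!identical(dim(full_mask), dim(proj$pixels)))
      stop("mask shape must match the full-frame projection")
  }
  if (!is.null(rect)) {
    proj <- crop(proj, rect)
    if (!auto && !is.null(mask))
      full_mask <- full_mask[(rect$y0 + 1L):rect$y1,
                             (rect$x0 + 1L):rect$x1, drop = FALSE]
  }
  if (auto) {
    proj <- apply_soma_mask(proj, do.call(auto_soma_mask,
                                          c(list(proj), auto_mask_args)))
  } else if (!is.null(mask)) {
    proj <- apply_soma_mask(proj, full_mask)
  }
  idx <- adaptive_threshold(proj, window = window, offset = offset)
  score_projection(proj, idx, embryo_id = embryo_id)
}
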