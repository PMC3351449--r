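#' Write a stack as a multi-page TIFF with a JSON sidecar
#'
#' Pages are written channel-major (all z-slices of channel 1, then channel
#' 2, ...), one page per slice, at the stack's bit depth. The sidecar
#' (`<path>.json`) declares the page layout, channel order, bit depth and DV
#' convention so the file is self-describing.
#'
#' @param stack a [volume_stack()].
#' @param path output TIFF path.
#' @param sidecar write the JSON sidecar (default `TRUE`).
#' @return Invisibly, `path`.
#' @export
write_stack <- function(stack, path, sidecar = TRUE) {
  stopifnot(inherits(stack, "volume_stack"))
  vox <- stack$voxels
  if (length(dim(vox)) == 3L) vox <- array(vox, c(dim(vox), 1L))
  d <- dim(vox)
  top <- 2^stack$bit_depth - 1
  pages <- vector("list", d[3] * d[4])
  k <- 0L
  for (ch in seq_len(d[4])) for (z in seq_len(d[3])) {
    k <- k + 1L
    pages[[k]] <- vox[, , z, ch] / top
  }
  tiff::writeTIFF(pages, path, bits.per.sample = stack$bit_depth)
  if (sidecar) {
    meta <- list(n_y = d[1], n_x = d[2], n_z = d[3], n_channels = d[4],
                 bit_depth = stack$bit_depth,
                 channel_names = as.list(stack$channel_names),
                 dv_dorsal = stack$dv_dorsal, page_order = "channel_major")
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read a multi-page TIFF stack
#'
#' Reads the TIFF and, when present, its JSON sidecar (`<path>.json`) to
#' recover the channel layout; without a sidecar a single channel is
#' assumed and the bit depth is taken from the file. Channels can be
#' permuted on read via `channel_order` (indices or names as declared in
#' the sidecar).
#'
#' @param path TIFF path.
#' @param channel_order optional permutation of channels (integer indices
#'   or sidecar channel names).
#' @return A [volume_stack()] with voxels `(y, x, z, channel)`.
#' @export
read_stack <- function(path, channel_order = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE,
                                   info = TRUE),
                    error = function(e) stop("unreadable TIFF: ", path,
                                             " (", conditionMessage(e), ")"))
  if (is.matrix(pages) || !is.list(pages)) pages <- list(pages)
  scpath <- paste0(path, ".json")
  if (file.exists(scpath)) {
    meta <- jsonlite::read_json(scpath, simplifyVector = TRUE)
    nch <- meta$n_channels
    nz <- meta$n_z
    bd <- meta$bit_depth
    cn <- unlist(meta$channel_names)
    dv <- meta$dv_dorsal %||% "low"
    if (nch * nz != length(pages))
      stop("sidecar page layout does not match the TIFF page count")
  } else {
    nch <- 1L
    nz <- length(pages)
    bps <- attr(pages[[1]], "bits.per.sample")
    bd <- if (!is.null(bps)) as.integer(bps)
          else if (max(pages[[1]]) > 255) 16L else 8L
    cn <- "ch1"
    dv <- "low"
  }
  d <- dim(pages[[1]])
  vox <- array(0L, c(d[1], d[2], nz, nch))
  k <- 0L
  for (ch in seq_len(nch)) for (z in seq_len(nz)) {
    k <- k + 1L
    vox[, , z, ch] <- as.integer(pages[[k]])
  }
  if (!is.null(channel_order)) {
    if (is.character(channel_order)) {
      perm <- match(channel_order, cn)
      if (anyNA(perm)) stop("unknown channel name in channel_order")
    } else perm <- as.integer(channel_order)
    vox <- vox[, , , perm, drop = FALSE]
    cn <- cn[perm]
  }
  volume_stack(vox, bit_depth = bd, dv_dorsal = dv, channel_names = cn)
}

#' Write an index map as a black-and-white PNG
#'
#' Indexed axon positions are white on black.
#'
#' @param index_map an `axon_index_map` or logical matrix.
#' @param path output PNG path.
#' @return Invisibly, `path`.
#' @export
write_index_map <- function(index_map, path) {
  map <- if (inherits(index_map, "axon_index_map")) index_map$map
         else index_map > 0
  png::writePNG(map * 1, path)
  invisible(path)
}

#' Read a single neuron trace from JSON
#'
#' The trace file holds the soma as per-slice boundary contours and each
#' process as a polyline, e.g.
#' \preformatted{
#' {"dv_dorsal": "low",
#'  "soma": [{"z": 5, "points": [[40, 60], [40, 61], ...]}],
#'  "processes": [{"path": [[45, 60], [60, 58]], "origin": [45, 60]}]}
#' }
#'
#' @param path JSON file path.
#' @return A [neuron_trace()].
#' @export
read_trace_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  soma <- lapply(seq_len(nrow_or_len(obj$soma)), function(i) {
    sl <- if (is.data.frame(obj$soma)) obj$soma[i, ] else obj$soma[[i]]
    list(z = sl$z[[1]], points = as.matrix(as.data.frame(sl$points)))
  })
  procs <- obj$processes
  if (is.data.frame(procs)) procs <- split(procs, seq_len(nrow(procs)))
  processes <- lapply(procs, function(p) {
    path_m <- as.matrix(as.data.frame(p$path))
    o <- unlist(p$origin)
    list(path = path_m, origin = if (length(o)) o else NULL)
  })
  neuron_trace(soma, processes, dv_dorsal = obj$dv_dorsal %||% "low")
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)

#' Write a neuron trace to JSON
#'
#' @param trace a [neuron_trace()] with contour-form soma or a mask (masks
#'   are converted to per-slice boundary contours).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_trace_json <- function(trace, path) {
  stopifnot(inherits(trace, "neuron_trace"))
  s <- trace$soma
  if (!is.list(s)) {
    if (length(dim(s)) == 2L) s <- array(s, c(dim(s), 1L))
    soma <- list()
    for (z in seq_len(dim(s)[3])) {
      sl <- trace; sl$soma <- s[, , z]
      if (!any(s[, , z])) next
      bp <- soma_boundary_points(sl)
      soma[[length(soma) + 1L]] <- list(z = z, points = unname(bp))
    }
  } else {
    soma <- lapply(s, function(sl) list(z = sl$z, points = unname(sl$points)))
  }
  obj <- list(dv_dorsal = trace$dv_dorsal, soma = soma,
              processes = lapply(trace$processes, function(p)
                list(path = unname(p$path), origin = unname(p$origin))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
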