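#' Single labeled neuron trace
#'
#' Container for a manually traced neuron: the soma (as a 3D/2D logical
#' mask, or as per-slice boundary contours) and one or more processes as
#' polylines, each with its emergence point on the soma surface. Origin and
#' trajectory calls consume geometry only; no image intensities enter.
#'
#' @param soma either a logical (y,x) or (y,x,z) array, or a list of
#'   per-slice contours, each a list with `z` and `points` (a matrix with
#'   columns y,x of boundary points).
#' @param processes list of processes; each a list with `path` (polyline
#'   matrix, columns y,x or y,x,z) and optionally `origin` (c(y,x) or
#'   c(y,x,z); defaults to the first path vertex).
#' @param dv_dorsal `"low"` (dorsal toward row 1) or `"high"`.
#' @return Object of class `neuron_trace`.
#' @export
neuron_trace <- function(soma, processes, dv_dorsal = "low") {
  if (length(processes) < 1L) stop("a traced neuron needs at least one process")
  processes <- lapply(processes, function(p) {
    p$path <- as.matrix(p$path)
    if (is.null(p$origin)) p$origin <- p$path[1, ]
    p
  })
  tr <- structure(list(soma = soma, processes = processes,
                       dv_dorsal = dv_dorsal),
                  class = "neuron_trace")
  if (nrow(soma_points(tr)) < 1L) stop("empty soma")
  tr
}

# All soma pixels (mask form) or boundary points (contour form) as a
# (k x 2) matrix of (y, x).
soma_points <- function(trace) {
  s <- trace$soma
  if (is.list(s)) {
    do.call(rbind, lapply(s, function(sl) as.matrix(sl$points)[, 1:2,
                                                               drop = FALSE]))
  } else {
    idx <- which(s, arr.ind = TRUE)
    if (length(idx) == 0L) matrix(numeric(0), 0, 2)
    else idx[, 1:2, drop = FALSE]
  }
}

# Soma boundary points: contour points directly, or mask pixels with a
# non-mask 4-neighbor in-plane.
soma_boundary_points <- function(trace) {
  s <- trace$soma
  if (is.list(s)) return(soma_points(trace))
  if (length(dim(s)) == 2L) s <- array(s, c(dim(s), 1L))
  d <- dim(s)
  shift <- function(a, dy, dx) {
    out <- array(FALSE, dim(a))
    ys <- seq_len(d[1]) + dy; xs <- seq_len(d[2]) + dx
    oky <- ys >= 1 & ys <= d[1]; okx <- xs >= 1 & xs <= d[2]
    out[oky, okx, ] <- a[ys[oky], xs[okx], , drop = FALSE]
    out
  }
  interior <- s & shift(s, 1, 0) & shift(s, -1, 0) &
    shift(s, 0, 1) & shift(s, 0, -1)
  idx <- which(s & !interior, arr.ind = TRUE)
  idx[, 1:2, drop = FALSE]
}

#' Dorsoventral extent of the soma
#'
#' The extent is taken over the union of all slices' soma pixels along the
#' DV (y) axis; the midline is its midpoint, corresponding to the bar drawn
#' halfway between the dorsal and ventral sides of the cell body.
#'
#' @param trace a [neuron_trace()].
#' @return Named numeric vector `c(dorsal_pole, ventral_pole, midline)` in
#'   pixel coordinates.
#' @export
soma_dv_extent <- function(trace) {
  stopifnot(inherits(trace, "neuron_trace"))
  ys <- soma_points(trace)[, 1]
  rng <- range(ys)
  if (diff(rng) < 1) stop("degenerate soma: dorsoventral extent below 1 px")
  if (trace$dv_dorsal == "low")
    c(dorsal_pole = rng[1], ventral_pole = rng[2], midline = mean(rng))
  else
    c(dorsal_pole = rng[2], ventral_pole = rng[1], midline = mean(rng))
}

#' Classify the axon emergence site along the dorsoventral axis
#'
#' Computes the normalized DV position `u` of the emergence point within
#' the soma extent (0 = dorsal pole, 1 = ventral pole) and calls the origin
#' `middle` when `|u - 0.5| <= middle_band / 2`, `dorsal` when
#' `u < 0.5`, and `ventral` otherwise. The default band marks the central
#' 10% of the soma DV extent as "close to the middle".
#'
#' @param trace a [neuron_trace()].
#' @param process process index.
#' @param middle_band width of the middle band as a fraction of the extent.
#' @return Object of class `origin_call`: list with `process`, `call`
#'   (`"ventral"`, `"dorsal"` or `"middle"`) and `u`.
#' @export
classify_origin <- function(trace, process = 1L, middle_band = 0.1) {
  stopifnot(inherits(trace, "neuron_trace"))
  p <- trace$processes[[process]]
  o <- p$origin[1:2]
  bp <- soma_boundary_points(trace)
  dmin <- sqrt(min((bp[, 1] - o[1])^2 + (bp[, 2] - o[2])^2))
  if (dmin > 1.5)
    stop("emergence point is not on the soma boundary (distance ",
         round(dmin, 2), " px)")
  ext <- soma_dv_extent(trace)
  u <- abs(o[1] - ext["dorsal_pole"]) /
    abs(ext["ventral_pole"] - ext["dorsal_pole"])
  u <- unname(min(max(u, 0), 1))
  call <- if (abs(u - 0.5) <= middle_band / 2) "middle"
          else if (u < 0.5) "dorsal" else "ventral"
  structure(list(process = process, call = call, u = u),
            class = "origin_call")
}

#' Classify the trajectory of a process as dorsal or ventral
#'
#' A process is called dorsal when the net DV displacement of its distal
#' endpoint relative to the soma midline is dorsalward by more than
#' `dead_zone` pixels, and ventral otherwise.
#'
#' @param trace a [neuron_trace()].
#' @param process process index.
#' @param dead_zone dorsalward displacement (px) that must be exceeded for
#'   a dorsal call.
#' @param min_length minimum polyline length (px); shorter processes are
#'   rejected as untraceable.
#' @return Object of class `trajectory_call`: list with `process`, `call`
#'   and the signed dorsalward displacement `displacement`.
#' @export
classify_trajectory <- function(trace, process = 1L, dead_zone = 5,
                                min_length = 10) {
  stopifnot(inherits(trace, "neuron_trace"))
  p <- trace$processes[[process]]
  path <- p$path[, 1:2, drop = FALSE]
  seg <- diff(path)
  len <- sum(sqrt(rowSums(seg^2)))
  if (len < min_length)
    stop("process too short to classify (", round(len, 1), " px)")
  ext <- soma_dv_extent(trace)
  y_end <- path[nrow(path), 1]
  disp <- if (trace$dv_dorsal == "low") unname(ext["midline"]) - y_end
          else y_end - unname(ext["midline"])
  structure(list(process = process,
                 call = if (disp > dead_zone) "dorsal" else "ventral",
                 displacement = disp),
            class = "trajectory_call")
}

#' Build a neuron trace from simulator ground truth
#'
#' @param truth a `ground_truth` from [render_single_neuron()].
#' @param dv_dorsal DV convention of the rendered stack.
#' @return A [neuron_trace()] whose soma is the geometric soma mask and
#'   whose processes are the ground-truth centerlines.
#' @export
as_neuron_trace <- function(truth, dv_dorsal = "low") {
  stopifnot(inherits(truth, "ground_truth"))
  processes <- Map(function(cl, o) list(path = cl$path, origin = o[1:2]),
                   truth$axon_centerlines, truth$origin_points)
  neuron_trace(truth$soma_mask, processes, dv_dorsal = dv_dorsal)
}

#' Summarize origin and multiplicity calls over a cohort of neurons
#'
#' @param cells data.frame with one row per cell: `origin` (the call of the
#'   primary process: ventral/dorsal/middle), `n_processes`, and optionally
#'   `treatment`.
#' @return data.frame with one row per treatment: counts and fractions of
#'   ventral-, dorsal- and middle-origin cells and of single- vs
#'   multi-process cells. Fractions sum to 1 within each block.
#' @export
summarize_cells <- function(cells) {
  stopifnot(nrow(cells) >= 1L,
            all(c("origin", "n_processes") %in% names(cells)))
  if (is.null(cells$treatment)) cells$treatment <- "all"
  out <- lapply(split(cells, cells$treatment), function(g) {
    n <- nrow(g)
    cnt <- function(k) sum(g$origin == k)
    multi <- sum(g$n_processes >= 2)
    data.frame(treatment = g$treatment[1], n = n,
               n_ventral = cnt("ventral"), n_dorsal = cnt("dorsal"),
               n_middle = cnt("middle"),
               frac_ventral = cnt("ventral") / n,
               frac_dorsal = cnt("dorsal") / n,
               frac_middle = cnt("middle") / n,
               n_single = n - multi, n_multi = multi,
               frac_multi = multi / n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Flip an object along the dorsoventral axis
#'
#' Mirrors image content or trace geometry along the DV (y) axis while
#' keeping the coordinate convention fixed, so dorsal content becomes
#' ventral content and vice versa.
#'
#' @param x a `volume_stack`, `projection2d`, `neuron_trace` or
#'   `sim_config`.
#' @param ... unused.
#' @return The flipped object. For a `sim_config`, the geometry is mirrored
#'   and the dorsal-direction flag toggled, so rendering the flipped config
#'   reproduces the DV-flip of the rendered stack (noise aside).
#' @export
flip_dv <- function(x, ...) UseMethod("flip_dv")

#' @export
flip_dv.volume_stack <- function(x, ...) {
  ny <- dim(x$voxels)[1]
  if (length(dim(x$voxels)) == 4L)
    x$voxels <- x$voxels[ny:1, , , , drop = FALSE]
  else
    x$voxels <- x$voxels[ny:1, , , drop = FALSE]
  x
}

#' @export
flip_dv.projection2d <- function(x, ...) {
  ny <- nrow(x$pixels)
  x$pixels <- x$pixels[ny:1, , drop = FALSE]
  if (!is.null(x$mask)) x$mask <- x$mask[ny:1, , drop = FALSE]
  x
}

#' @export
flip_dv.neuron_trace <- function(x, ny = NULL, ...) {
  s <- x$soma
  if (is.list(s)) {
    if (is.null(ny)) stop("ny (image height) required for contour traces")
    x$soma <- lapply(s, function(sl) {
      sl$points[, 1] <- ny + 1 - sl$points[, 1]; sl
    })
  } else {
    ny <- dim(s)[1]
    x$soma <- if (length(dim(s)) == 3L) s[ny:1, , , drop = FALSE]
              else s[ny:1, , drop = FALSE]
  }
  x$processes <- lapply(x$processes, function(p) {
    p$path[, 1] <- ny + 1 - p$path[, 1]
    p$origin[1] <- ny + 1 - p$origin[1]
    p
  })
  x
}

#' @export
flip_dv.sim_config <- function(x, ...) {
  ny <- x$image_shape[["y"]]
  fy <- function(y) ny + 1 - y
  x$soma_cluster$center[1] <- fy(x$soma_cluster$center[1])
  x$soma_cluster$centers[, 1] <- fy(x$soma_cluster$centers[, 1])
  x$ventral_tracts <- lapply(x$ventral_tracts, function(tr) {
    tr$path[, 1] <- fy(tr$path[, 1]); tr
  })
  if (!is.null(x$dorsal_process$path))
    x$dorsal_process$path[, 1] <- fy(x$dorsal_process$path[, 1])
  x$dv_dorsal <- if (x$dv_dorsal == "low") "high" else "low"
  x
}
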