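#' Configuration for the synthetic confocal stack generator
#'
#' Builds the parameter set for [render_embryo()] and
#' [render_single_neuron()]. The defaults emulate a frontal-view stack of a
#' labeled dorsal-telencephalic neuron cluster: a group of bright somata in
#' the dorsal region, two ventrally projecting tracts (anterior-commissure /
#' supraoptic-tract analogs), and an optional aberrant dorsally projecting
#' process whose integrated projected signal mass is the severity knob. The
#' rendered geometry is convolved with an anisotropic Gaussian point-spread
#' function and corrupted with Poisson shot noise plus additive Gaussian
#' read noise on top of a constant background.
#'
#' Coordinates are 1-based voxel indices `(y, x)` (plus slice `z` where
#' needed). The dorsoventral axis is the image `y` axis; with
#' `dv_dorsal = "low"` dorsal is toward row 1, matching frontal mounting with
#' dorsal at the top.
#'
#' @param image_shape named integer vector `c(y=, x=, z=)`; voxel counts.
#' @param n_channels number of channels; the signal is rendered into
#'   `signal_channel`, remaining channels contain background plus their
#'   `channel_offsets` entry only.
#' @param signal_channel index of the channel carrying the labeled signal.
#' @param channel_offsets constant ADU added per channel (length
#'   `n_channels`); useful to make channels distinguishable in tests.
#' @param bit_depth 8 or 16; output stacks are clipped and rounded to this
#'   unsigned range.
#' @param soma_cluster list with `center` (y,x), `radius` (cluster extent,
#'   px), `n_somata`, `soma_radius` (px), `peak_intensity` (ADU).
#' @param ventral_tracts list of tract specs, each a list with `path`
#'   (polyline matrix, columns y,x), `width` (px), `intensity` (ADU).
#' @param dorsal_process list with `mass` (target integrated projected signal
#'   in ADU outside the soma mask; 0 disables the process), `path` (polyline,
#'   `NULL` for the default dorsolateral course) and `width` (px).
#' @param psf_sigma Gaussian PSF standard deviations `c(y=, x=, z=)` in px.
#' @param noise list with `enabled`, `poisson_scale` (photons per ADU used
#'   for shot noise), `gaussian_sd` (ADU), `background` (ADU).
#' @param dv_dorsal `"low"` if dorsal is toward row 1, `"high"` otherwise.
#' @param seed master seed; together with the config it fully determines the
#'   rendered stack. Geometry jitter and noise use sub-streams derived from
#'   it, so the same geometry can be re-rendered under different noise.
#'
#' @return An object of class `sim_config`.
#' @seealso [render_embryo()], [render_single_neuron()], [make_cohort()]
#' @export
sim_config <- function(image_shape = c(y = 128L, x = 128L, z = 12L),
                       n_channels = 1L,
                       signal_channel = 1L,
                       channel_offsets = NULL,
                       bit_depth = 8L,
                       soma_cluster = list(center = c(y = 48, x = 64),
                                           radius = 9, n_somata = 6,
                                           soma_radius = 3,
                                           peak_intensity = 180),
                       ventral_tracts = list(
                         list(path = rbind(c(56, 60), c(85, 44), c(115, 36)),
                              width = 3, intensity = 120),
                         list(path = rbind(c(56, 68), c(85, 84), c(115, 92)),
                              width = 3, intensity = 120)),
                       dorsal_process = list(mass = 0, path = NULL, width = 7),
                       psf_sigma = c(y = 1.2, x = 1.2, z = 1),
                       noise = list(enabled = TRUE, poisson_scale = 1,
                                    gaussian_sd = 2, background = 5),
                       dv_dorsal = c("low", "high"),
                       seed = 1L) {
  dv_dorsal <- match.arg(dv_dorsal)
  image_shape <- as.integer(image_shape)
  names(image_shape) <- c("y", "x", "z")
  if (is.null(channel_offsets)) channel_offsets <- rep(0, n_channels)
  if (!is.null(dorsal_process$mass) && dorsal_process$mass > 0 &&
      is.null(dorsal_process$path)) {
    dorsal_process$path <- default_dorsal_path(image_shape, soma_cluster,
                                               dv_dorsal)
  }
  if (is.null(soma_cluster$centers)) {
    # jittered soma positions are drawn once, at construction, from the
    # geometry sub-stream; they are part of the config from then on so that
    # geometric transforms of the config act on them too
    soma_cluster$centers <- with_seed(seed * 2 + 11, {
      n <- soma_cluster$n_somata
      ang <- stats::runif(n, 0, 2 * pi)
      rad <- soma_cluster$radius * sqrt(stats::runif(n))
      cbind(y = soma_cluster$center[1] + rad * cos(ang),
            x = soma_cluster$center[2] + rad * sin(ang),
            dz = stats::runif(n, -1, 1))
    })
  }
  cfg <- structure(list(image_shape = image_shape,
                        n_channels = as.integer(n_channels),
                        signal_channel = as.integer(signal_channel),
                        channel_offsets = channel_offsets,
                        bit_depth = as.integer(bit_depth),
                        soma_cluster = soma_cluster,
                        ventral_tracts = ventral_tracts,
                        dorsal_process = dorsal_process,
                        psf_sigma = psf_sigma,
                        noise = noise,
                        dv_dorsal = dv_dorsal,
                        seed = as.integer(seed)),
                   class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

# Default course of the aberrant process: from the dorsal edge of the soma
# cluster dorsolaterally toward the top corner of the frame.
default_dorsal_path <- function(shape, soma_cluster, dv_dorsal) {
  cy <- soma_cluster$center[1]; cx <- soma_cluster$center[2]
  r <- soma_cluster$radius
  p <- rbind(c(cy - r + 1, cx + 4),
             c(cy - r - 15, cx + 22),
             c(max(4, cy - r - 29), cx + 44))
  if (dv_dorsal == "high") p[, 1] <- shape["y"] + 1 - p[, 1]
  p[, 2] <- pmin(p[, 2], shape["x"] - 3)
  p
}

validate_sim_config <- function(cfg) {
  s <- cfg$image_shape
  if (any(s < 1L)) stop("image_shape must be positive")
  if (!cfg$bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  if (cfg$signal_channel > cfg$n_channels) stop("signal_channel out of range")
  if (length(cfg$channel_offsets) != cfg$n_channels)
    stop("channel_offsets must have one entry per channel")
  inside <- function(p) all(p[, 1] >= 1 & p[, 1] <= s["y"] &
                            p[, 2] >= 1 & p[, 2] <= s["x"])
  sc <- cfg$soma_cluster
  if (sc$peak_intensity < 0) stop("intensities must be non-negative")
  ext <- sc$radius + sc$soma_radius
  if (sc$center[1] - ext < 1 || sc$center[1] + ext > s["y"] ||
      sc$center[2] - ext < 1 || sc$center[2] + ext > s["x"])
    stop("soma cluster extends outside the image volume")
  for (tr in cfg$ventral_tracts) {
    if (tr$intensity < 0) stop("intensities must be non-negative")
    if (!inside(tr$path)) stop("ventral tract path outside the image volume")
  }
  dp <- cfg$dorsal_process
  if (dp$mass < 0) stop("dorsal_process mass must be non-negative")
  if (dp$mass > 0 && !inside(dp$path))
    stop("dorsal process path outside the image volume")
  if (any(cfg$psf_sigma < 0) || cfg$noise$gaussian_sd < 0 ||
      cfg$noise$background < 0 || cfg$noise$poisson_scale <= 0)
    stop("psf/noise parameters out of range")
  invisible(cfg)
}

# --- rasterisation -----------------------------------------------------------

# Solid balls of constant value in a (y,x,z) volume.
raster_balls <- function(shape, centers, radius, value) {
  vol <- array(0, shape)
  gy <- seq_len(shape[1]); gx <- seq_len(shape[2]); gz <- seq_len(shape[3])
  for (i in seq_len(nrow(centers))) {
    c0 <- centers[i, ]
    dy2 <- (gy - c0[1])^2; dx2 <- (gx - c0[2])^2; dz2 <- (gz - c0[3])^2
    hit <- outer(outer(dy2, dx2, "+"), dz2, "+") <= radius^2
    vol[hit] <- value
  }
  vol
}

# Constant-intensity tube: discs of diameter `width` swept along a 2D
# polyline, occupying `thickness` z-slices centred on `zc`.
raster_tube <- function(shape, path, width, value, zc, thickness = 3L) {
  plane <- matrix(0, shape[1], shape[2])
  gy <- seq_len(shape[1]); gx <- seq_len(shape[2])
  half <- width / 2
  for (i in seq_len(nrow(path) - 1L)) {
    a <- path[i, ]; b <- path[i + 1L, ]
    # squared distance of every pixel to segment ab
    ab <- b - a
    len2 <- sum(ab^2)
    PY <- matrix(gy - a[1], shape[1], shape[2])
    PX <- matrix(gx - a[2], shape[1], shape[2], byrow = TRUE)
    t_ <- if (len2 > 0) pmin(pmax((PY * ab[1] + PX * ab[2]) / len2, 0), 1) else 0
    d2 <- (PY - t_ * ab[1])^2 + (PX - t_ * ab[2])^2
    plane[d2 <= half^2] <- value
  }
  vol <- array(0, shape)
  zs <- intersect(seq(zc - (thickness - 1L) %/% 2L, length.out = thickness),
                  seq_len(shape[3]))
  for (z in zs) vol[, , z] <- plane
  vol
}

clip_quantize <- function(x, bit_depth) {
  top <- 2^bit_depth - 1
  storage <- round(pmin(pmax(x, 0), top))
  array(as.integer(storage), dim(x))
}

apply_noise <- function(scene, noise, bit_depth, seed) {
  x <- scene + noise$background
  if (isTRUE(noise$enabled)) {
    x <- with_seed(seed, {
      ps <- noise$poisson_scale
      shot <- stats::rpois(length(x), lambda = as.vector(x) * ps) / ps
      shot + stats::rnorm(length(x), sd = noise$gaussian_sd)
    })
    x <- array(x, dim(scene))
  }
  clip_quantize(x, bit_depth)
}

# 2D max projection of a (y,x,z) volume (internal; the user-facing
# max_project_z wraps provenance around this).
project_max <- function(vol) {
  d <- dim(vol)
  out <- matrix(vol[, , 1L], d[1], d[2])
  if (d[3] > 1L) for (z in 2L:d[3]) out <- pmax(out, matrix(vol[, , z],
                                                            d[1], d[2]))
  out
}

dilate_mask <- function(mask, px) {
  if (px < 1) return(mask)
  brush <- EBImage::makeBrush(2L * as.integer(px) + 1L, shape = "disc")
  EBImage::dilate(mask * 1, brush) > 0.5
}

# --- rendering ---------------------------------------------------------------

#' Render a synthetic labeled embryo stack with ground truth
#'
#' Renders the noise-free geometry of a `sim_config` (blurred soma spheres
#' and swept-tube processes), derives the ground truth from that noise-free
#' intermediate, and only then applies the camera-noise model. The dorsal
#' process is rendered at unit intensity and scaled linearly so that its
#' integrated intensity in the max projection, outside the (dilated) soma
#' footprint, equals the configured target mass exactly; ground truth is
#' therefore exact by construction up to bit-depth clipping.
#'
#' @param config a [sim_config()].
#' @return A list with `stack` (a `volume_stack`) and `truth` (a
#'   `ground_truth` list: `axon_centerlines`, `soma_mask` (3D, geometric),
#'   `soma_mask_proj` (2D, PSF-dilated footprint used for mass exclusion),
#'   `expected_dorsal_mass`, `origin_points`, `n_processes`).
#' @export
render_embryo <- function(config) {
  validate_sim_config(config)
  s <- config$image_shape
  shape <- unname(s[c("y", "x", "z")])
  zc <- max(1L, (s[["z"]] + 1L) %/% 2L)
  sc <- config$soma_cluster

  centers <- cbind(sc$centers[, 1], sc$centers[, 2], zc + sc$centers[, 3])
  soma_geom <- raster_balls(shape, centers, sc$soma_radius, 1)
  soma_scene <- blur_volume(soma_geom * sc$peak_intensity, config$psf_sigma)

  soma_mask <- soma_geom > 0
  soma_mask_proj <- dilate_mask(project_max(soma_mask),
                                ceiling(2 * max(config$psf_sigma[1:2])))

  tract_scene <- array(0, shape)
  for (tr in config$ventral_tracts) {
    tube <- raster_tube(shape, tr$path, tr$width, tr$intensity, zc)
    tract_scene <- pmax(tract_scene, tube)
  }
  tract_scene <- blur_volume(tract_scene, config$psf_sigma)

  dp <- config$dorsal_process
  dorsal_mass <- 0
  dorsal_scene <- array(0, shape)
  if (dp$mass > 0) {
    unit <- blur_volume(raster_tube(shape, dp$path, dp$width, 1, zc),
                        config$psf_sigma)
    unit_mass <- sum(project_max(unit)[!soma_mask_proj])
    if (unit_mass <= 0) stop("dorsal process fully inside the soma footprint")
    dorsal_scene <- (dp$mass / unit_mass) * unit
    dorsal_mass <- sum(project_max(dorsal_scene)[!soma_mask_proj])
  }

  scene <- soma_scene + tract_scene + dorsal_scene
  channels <- vector("list", config$n_channels)
  for (ch in seq_len(config$n_channels)) {
    base <- if (ch == config$signal_channel) scene else array(0, shape)
    channels[[ch]] <- apply_noise(base + config$channel_offsets[ch],
                                  config$noise, config$bit_depth,
                                  config$seed + 1000003L * ch)
  }
  vox <- array(0L, c(shape, config$n_channels))
  for (ch in seq_len(config$n_channels)) vox[, , , ch] <- channels[[ch]]

  centerlines <- lapply(config$ventral_tracts, function(tr)
    list(path = tr$path, class = "ventral"))
  origins <- lapply(config$ventral_tracts, function(tr)
    c(y = tr$path[1, 1], x = tr$path[1, 2], z = zc))
  if (dp$mass > 0) {
    centerlines <- c(centerlines, list(list(path = dp$path, class = "dorsal")))
    origins <- c(origins, list(c(y = dp$path[1, 1], x = dp$path[1, 2], z = zc)))
  }

  stack <- volume_stack(vox, bit_depth = config$bit_depth,
                        dv_dorsal = config$dv_dorsal,
                        channel_names = paste0("ch", seq_len(config$n_channels)))
  truth <- structure(list(axon_centerlines = centerlines,
                          soma_mask = soma_mask,
                          soma_mask_proj = soma_mask_proj,
                          expected_dorsal_mass = dorsal_mass,
                          origin_points = origins,
                          n_processes = length(centerlines),
                          seed = config$seed),
                     class = "ground_truth")
  list(stack = stack, truth = truth)
}

#' Render a single labeled neuron with controllable axon origins
#'
#' Renders one soma (radius `soma_cluster$soma_radius`, intensity
#' `peak_intensity`) at the cluster center with `n_processes` straight radial
#' processes emerging at the given perimeter angles. Angles are measured in
#' the image plane with 0 degrees at the dorsal pole of the soma and 180
#' degrees at the ventral pole (90 degrees is lateral, on the +x side).
#'
#' @param config a [sim_config()]; tracts and dorsal process are ignored.
#' @param origin_angle numeric vector of perimeter angles in degrees, one per
#'   process (a scalar is recycled only when `n_processes == 1`).
#' @param n_processes number of processes, 1 to 4.
#' @param process_length radial length of each process in px.
#' @param process_width tube diameter in px.
#' @return As [render_embryo()]: list with `stack` and `truth`; truth
#'   `origin_points` are the emergence voxels on the geometric soma surface
#'   and each centerline carries its construction class (`dorsal` /
#'   `ventral`) from the sign of its endpoint displacement.
#' @export
render_single_neuron <- function(config, origin_angle, n_processes = 1L,
                                 process_length = 20, process_width = 2) {
  validate_sim_config(config)
  if (n_processes < 1L || n_processes > 4L)
    stop("n_processes must be between 1 and 4")
  if (length(origin_angle) != n_processes)
    stop("origin_angle must supply one angle per process")
  s <- config$image_shape
  shape <- unname(s[c("y", "x", "z")])
  zc <- max(1L, (s[["z"]] + 1L) %/% 2L)
  sc <- config$soma_cluster
  r <- sc$soma_radius

  # reject emergence sites closer along the perimeter than the tube width
  if (n_processes > 1L) {
    a <- sort(origin_angle %% 360)
    gaps <- c(diff(a), 360 - (a[n_processes] - a[1]))
    if (any(r * gaps * pi / 180 < process_width))
      stop("emergence angles closer than the tube width")
  }

  dsign <- if (config$dv_dorsal == "low") -1 else 1
  theta <- origin_angle * pi / 180
  dir_y <- dsign * cos(theta)
  dir_x <- sin(theta)
  cen <- c(sc$center[1], sc$center[2])

  soma_geom <- raster_balls(shape, cbind(cen[1], cen[2], zc), r, 1)
  scene <- blur_volume(soma_geom * sc$peak_intensity, config$psf_sigma)

  paths <- vector("list", n_processes)
  origins <- vector("list", n_processes)
  classes <- character(n_processes)
  for (i in seq_len(n_processes)) {
    o <- unname(cen + r * c(dir_y[i], dir_x[i]))
    e <- unname(cen + (r + process_length) * c(dir_y[i], dir_x[i]))
    e[1] <- min(max(e[1], 2), shape[1] - 1)
    e[2] <- min(max(e[2], 2), shape[2] - 1)
    paths[[i]] <- rbind(o, e)
    origins[[i]] <- c(y = o[1], x = o[2], z = zc)
    # dorsalward displacement of the endpoint relative to the soma centre
    disp <- if (config$dv_dorsal == "low") cen[1] - e[1] else e[1] - cen[1]
    classes[i] <- if (disp > 0) "dorsal" else "ventral"
    tube <- raster_tube(shape, paths[[i]], process_width,
                        sc$peak_intensity * 0.7, zc)
    scene <- scene + blur_volume(tube, config$psf_sigma)
  }

  vox <- array(apply_noise(scene, config$noise, config$bit_depth,
                           config$seed + 1000003L), c(shape, 1L))
  stack <- volume_stack(vox, bit_depth = config$bit_depth,
                        dv_dorsal = config$dv_dorsal, channel_names = "ch1")
  truth <- structure(list(
    axon_centerlines = Map(function(p, cl) list(path = p, class = cl),
                           paths, classes),
    soma_mask = soma_geom > 0,
    soma_mask_proj = dilate_mask(project_max(soma_geom > 0),
                                 ceiling(2 * max(config$psf_sigma[1:2]))),
    expected_dorsal_mass = 0,
    origin_points = origins,
    n_processes = n_processes,
    seed = config$seed), class = "ground_truth")
  list(stack = stack, truth = truth)
}

#' Write a simulated cohort of embryos to disk
#'
#' Renders one stack per entry and writes a multi-page TIFF (plus JSON
#' sidecar) per embryo together with a ground-truth table. Deterministic
#' given the per-embryo seeds.
#'
#' @param entries list; each element a list with `config` (a [sim_config()]),
#'   `embryo_id`, `treatment`, `dose_ng`, `replicate`.
#' @param outdir output directory (created if needed).
#' @return Invisibly, a list with `truth` (the truth data.frame) and `files`.
#'   The truth table is also written to `file.path(outdir, "truth.csv")` with
#'   columns `embryo_id,treatment,dose_ng,replicate,expected_dorsal_mass,
#'   n_processes,seed`.
#' @export
make_cohort <- function(entries, outdir) {
  if (length(entries) < 1L) stop("cohort must contain at least one entry")
  ids <- vapply(entries, function(e) as.character(e$embryo_id), "")
  if (anyDuplicated(ids)) stop("duplicate embryo ids in cohort")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", length(entries))
  files <- character(length(entries))
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    res <- render_embryo(e$config)
    files[i] <- file.path(outdir, paste0(ids[i], ".tif"))
    write_stack(res$stack, files[i])
    rows[[i]] <- data.frame(embryo_id = ids[i],
                            treatment = e$treatment,
                            dose_ng = e$dose_ng,
                            replicate = e$replicate,
                            expected_dorsal_mass = res$truth$expected_dorsal_mass,
                            n_processes = res$truth$n_processes,
                            seed = e$config$seed,
                            stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, rows)
  utils::write.csv(truth, file.path(outdir, "truth.csv"), row.names = FALSE)
  invisible(list(truth = truth, files = files))
}
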