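# Independent brute-force oracles used to validate the vectorised
# implementations; all deliberately written as plain loops.

oracle_max_project <- function(vol) {
  d <- dim(vol)
  out <- matrix(-Inf, d[1], d[2])
  for (y in seq_len(d[1])) for (x in seq_len(d[2])) for (z in seq_len(d[3]))
    out[y, x] <- max(out[y, x], vol[y, x, z])
  out
}

# reflective (edge-duplicating) index as used by the package
oracle_reflect <- function(i, n) {
  if (i < 1) i <- 1 - i
  if (i > n) i <- 2 * n + 1 - i
  min(max(i, 1), n)
}

# naive O(n w^2) local-mean threshold with mask exclusion
oracle_adaptive_map <- function(px, mask, window, offset) {
  ny <- nrow(px); nx <- ncol(px)
  p <- (window - 1) / 2
  map <- matrix(FALSE, ny, nx)
  for (y in seq_len(ny)) for (x in seq_len(nx)) {
    if (mask[y, x]) next
    s <- 0; k <- 0
    for (dy in -p:p) for (dx in -p:p) {
      yy <- oracle_reflect(y + dy, ny)
      xx <- oracle_reflect(x + dx, nx)
      if (!mask[yy, xx]) {
        s <- s + px[yy, xx]
        k <- k + 1
      }
    }
    if (k > 0 && px[y, x] > s / k + offset) map[y, x] <- TRUE
  }
  map
}

oracle_score <- function(px, map) {
  s <- 0
  for (y in seq_len(nrow(px))) for (x in seq_len(ncol(px)))
    if (map[y, x]) s <- s + px[y, x]
  s
}

# exact two-tailed Mann-Whitney p by enumeration, with U computed by pair
# counting (independent of the rank-sum formula used in the package)
oracle_mw_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  v <- c(a, b)
  u_of <- function(ia) {
    av <- v[ia]; bv <- v[-ia]
    u <- 0
    for (x in av) for (y in bv) u <- u + (x > y) + 0.5 * (x == y)
    u
  }
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * n2 / 2
  sets <- utils::combn(n1 + n2, n1)
  us <- apply(sets, 2, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# small, quick simulator configs ---------------------------------------------

tiny_cfg <- function(mass = 0, seed = 1, noise = TRUE, ...) {
  sim_config(dorsal_process = list(mass = mass, path = NULL, width = 7),
             noise = list(enabled = noise, poisson_scale = 1,
                          gaussian_sd = 2, background = 5),
             seed = seed, ...)
}

single_cfg <- function(seed = 1, noise = TRUE, soma_radius = 6) {
  sim_config(image_shape = c(y = 64, x = 64, z = 8),
             soma_cluster = list(center = c(y = 32, x = 32), radius = 1,
                                 n_somata = 1, soma_radius = soma_radius,
                                 peak_intensity = 180),
             ventral_tracts = list(),
             noise = list(enabled = noise, poisson_scale = 1,
                          gaussian_sd = 2, background = 5),
             seed = seed)
}

# soma mask plus the ventral half, so that only dorsal signal is scored
dorsal_scoring_mask <- function(truth, cfg) {
  mask <- truth$soma_mask_proj
  cy <- cfg$soma_cluster$center[1]
  mask[cy:nrow(mask), ] <- TRUE
  mask
}
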