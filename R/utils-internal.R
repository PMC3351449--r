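# Internal numeric helpers shared by the simulator and the quantification
# stages. All 2D objects are (y, x) matrices; volumes are (y, x, z) arrays.

# Map out-of-range indices onto 1..n by symmetric (edge-duplicating) reflection.
reflect_index <- function(i, n) {
  i <- ifelse(i < 1L, 1L - i, i)
  i <- ifelse(i > n, 2L * n + 1L - i, i)
  # a second pass covers pads wider than the image (not used in practice)
  pmin(pmax(i, 1L), n)
}

# Normalised 1D Gaussian kernel truncated at 3 sigma.
gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# Dense n x n convolution operator for a symmetric kernel with reflective
# boundary handling; applying it as K %*% v convolves along that axis.
conv_operator <- function(n, kernel) {
  r <- (length(kernel) - 1L) / 2L
  K <- matrix(0, n, n)
  for (j in seq_along(kernel)) {
    src <- reflect_index(seq_len(n) + (j - r - 1L), n)
    K[cbind(seq_len(n), src)] <- K[cbind(seq_len(n), src)] + kernel[j]
  }
  K
}

# Separable Gaussian blur of a (y, x, z) volume; sigma = c(y, x, z) in voxels.
blur_volume <- function(vol, sigma) {
  d <- dim(vol)
  if (sigma[1] > 0) {
    Ky <- conv_operator(d[1], gauss_kernel(sigma[1]))
    for (z in seq_len(d[3])) vol[, , z] <- Ky %*% vol[, , z]
  }
  if (sigma[2] > 0) {
    Kx <- conv_operator(d[2], gauss_kernel(sigma[2]))
    for (z in seq_len(d[3])) vol[, , z] <- vol[, , z] %*% t(Kx)
  }
  if (sigma[3] > 0 && d[3] > 1L) {
    Kz <- conv_operator(d[3], gauss_kernel(sigma[3]))
    vol <- array(matrix(vol, d[1] * d[2], d[3]) %*% t(Kz), d)
  }
  vol
}

# Sliding-window sum over an odd square window with reflective padding,
# computed with a summed-area table.
box_sum <- function(m, window) {
  stopifnot(window %% 2L == 1L, window >= 1L)
  p <- (window - 1L) / 2L
  ny <- nrow(m); nx <- ncol(m)
  pad <- m[reflect_index(seq(1L - p, ny + p), ny),
           reflect_index(seq(1L - p, nx + p), nx), drop = FALSE]
  S <- apply(apply(pad, 2L, cumsum), 1L, cumsum)  # transposed SAT
  S <- t(S)
  S <- rbind(0, cbind(0, S))
  i0 <- seq_len(ny); j0 <- seq_len(nx)
  S[i0 + window, j0 + window, drop = FALSE] -
    S[i0, j0 + window, drop = FALSE] -
    S[i0 + window, j0, drop = FALSE] +
    S[i0, j0, drop = FALSE]
}

# Deterministic evaluation under a local RNG seed.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
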