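rand_proj <- function(ny, nx, top = 255) {
  projection2d(matrix(sample(0:top, ny * nx, replace = TRUE), ny, nx))
}

test_that("channel selection returns the requested channel unchanged", {
  vox <- array(0L, c(6, 5, 3, 2))
  vox[, , , 1] <- 10L
  vox[, , , 2] <- 77L
  st <- volume_stack(vox, channel_names = c("green", "red"))
  expect_equal(unique(as.vector(select_channel(st, 2)$voxels)), 77L)
  expect_equal(unique(as.vector(select_channel(st, "green")$voxels)), 10L)
  # single-channel selection is the identity
  st1 <- volume_stack(array(3L, c(4, 4, 2)))
  expect_equal(select_channel(st1, 1)$voxels, st1$voxels)
  expect_error(select_channel(st, 3), "out of range")
})

test_that("max projection equals the per-column maximum", {
  # single slice: identity
  sl <- matrix(sample(0:255, 30), 5, 6)
  expect_equal(max_project_z(array(sl, c(5, 6, 1)))$pixels, sl)
  # one bright voxel survives projection
  vol <- array(0, c(8, 8, 4)); vol[3, 5, 2] <- 201
  pr <- max_project_z(vol)$pixels
  expect_equal(sum(pr > 0), 1L)
  expect_equal(pr[3, 5], 201)
  # random volumes against the triple-loop oracle
  set.seed(7)
  for (i in 1:5) {
    vol <- array(sample(0:255, 5 * 8 * 8, replace = TRUE), c(5, 8, 8))
    expect_equal(max_project_z(vol)$pixels, oracle_max_project(vol))
  }
  expect_error(max_project_z(array(numeric(0), c(0, 0, 0))), "empty")
})

test_that("projection of 16-bit input is rescaled to 8-bit by default", {
  vox <- array(as.integer(c(0, 65535)), c(1, 2, 1))
  st <- volume_stack(vox, bit_depth = 16L)
  pr <- max_project_z(st)
  expect_equal(as.vector(pr$pixels), c(0, 255))
  expect_true(pr$provenance$rescaled)
  prn <- max_project_z(st, rescale_8bit = FALSE)
  expect_equal(max(prn$pixels), 65535)
})

test_that("crop extracts the half-open rectangle and rejects bad rects", {
  pr <- rand_proj(12, 12)
  expect_equal(crop(pr, crop_rect(0, 12, 0, 12))$pixels, pr$pixels)
  cr <- crop(pr, crop_rect(2, 7, 3, 9))
  expect_equal(cr$pixels, pr$pixels[3:7, 4:9])
  expect_error(crop_rect(5, 5, 0, 3), "degenerate")
  expect_error(crop(pr, crop_rect(0, 20, 0, 4)), "out of bounds")
})

test_that("crop-then-score equals scoring restricted to the rectangle", {
  # threshold neighborhood fully inside the rect on both paths
  set.seed(9)
  px <- matrix(0, 40, 40)
  px[15:25, 15:25] <- sample(80:255, 121, replace = TRUE)
  pr <- projection2d(px)
  rect <- crop_rect(5, 35, 5, 35)
  full_map <- adaptive_threshold(pr, window = 7, offset = 10)$map
  in_rect <- matrix(FALSE, 40, 40); in_rect[6:35, 6:35] <- TRUE
  score_full <- sum(px[full_map & in_rect])
  crp <- crop(pr, rect)
  s2 <- score_projection(crp, adaptive_threshold(crp, window = 7, offset = 10))
  expect_equal(s2$score, score_full)
})

test_that("soma masking zeroes pixels, is recorded, and bounds the score", {
  pr <- rand_proj(16, 16)
  # empty mask: identity on pixels
  pr0 <- apply_soma_mask(pr, matrix(FALSE, 16, 16))
  expect_equal(pr0$pixels, pr$pixels)
  # full mask: everything zero, downstream score 0
  pr1 <- apply_soma_mask(pr, matrix(TRUE, 16, 16))
  expect_true(all(pr1$pixels == 0))
  sc <- score_projection(pr1, adaptive_threshold(pr1, window = 5, offset = 1))
  expect_equal(sc$score, 0)
  expect_error(apply_soma_mask(pr, matrix(TRUE, 4, 4)), "shape")
  # mask dominance: enlarging the mask can only reduce the score
  set.seed(31)
  for (i in 1:20) {
    px <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
    m1 <- matrix(runif(400) < 0.2, 20, 20)
    m2 <- m1 | matrix(runif(400) < 0.2, 20, 20)
    s1 <- score_projection(projection2d(px),
      adaptive_threshold(apply_soma_mask(projection2d(px), m1), 5, 10))
    s2 <- score_projection(projection2d(px),
      adaptive_threshold(apply_soma_mask(projection2d(px), m2), 5, 10))
    expect_lte(s2$score, s1$score)
  }
})

test_that("adaptive threshold matches the naive local-mean oracle", {
  # constant image with positive offset: nothing indexed
  pc <- projection2d(matrix(100, 10, 10))
  expect_false(any(adaptive_threshold(pc, 3, 1)$map))
  # a single bright pixel in a dark background is indexed
  px <- matrix(0, 11, 11); px[6, 6] <- 200
  expect_true(adaptive_threshold(projection2d(px), 5, 10)$map[6, 6])
  # randomized instances, with and without masks
  set.seed(13)
  for (i in 1:10) {
    px <- matrix(sample(0:255, 256, replace = TRUE), 16, 16)
    mask <- matrix(runif(256) < 0.15, 16, 16)
    w <- sample(c(3, 5, 7), 1)
    pr <- apply_soma_mask(projection2d(px), mask)
    got <- adaptive_threshold(pr, window = w, offset = 10)$map
    want <- oracle_adaptive_map(pr$pixels, mask, w, 10)
    expect_identical(got, want)
    expect_false(any(got & mask))  # masked pixels never indexed
  }
  expect_error(adaptive_threshold(pc, 4, 1), "odd")
  expect_error(adaptive_threshold(pc, 21, 1), "larger")
})

test_that("scoring sums indexed intensities and matches the loop oracle", {
  px <- matrix(0, 5, 5); px[cbind(1:3, 1:3)] <- c(10, 20, 30)
  map <- px > 0
  sc <- score_projection(projection2d(px), map)
  expect_equal(sc$score, 60)
  expect_equal(sc$n_indexed_pixels, 3L)
  expect_equal(score_projection(projection2d(px),
                                matrix(FALSE, 5, 5))$score, 0)
  set.seed(19)
  for (i in 1:20) {
    px <- matrix(sample(0:255, 144, replace = TRUE), 12, 12)
    map <- matrix(runif(144) < 0.3, 12, 12)
    expect_equal(score_projection(projection2d(px), map)$score,
                 oracle_score(px, map))
  }
})

test_that("score is additive over disjoint maps and monotone", {
  set.seed(29)
  px <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  pr <- projection2d(px)
  m1 <- matrix(runif(400) < 0.3, 20, 20)
  m2 <- matrix(runif(400) < 0.3, 20, 20) & !m1
  expect_equal(score_projection(pr, m1 | m2)$score,
               score_projection(pr, m1)$score +
                 score_projection(pr, m2)$score)
  # raising an indexed pixel's intensity never decreases the score
  idx <- which(m1, arr.ind = TRUE)[1, , drop = FALSE]
  px2 <- px; px2[idx] <- px2[idx] + 50
  expect_gte(score_projection(projection2d(px2), m1)$score,
             score_projection(pr, m1)$score)
  # enlarging the index map never decreases the score
  expect_gte(score_projection(pr, m1 | m2)$score,
             score_projection(pr, m1)$score)
})

test_that("auto soma mask keeps bright compact discs and spares thin tubes", {
  # all-zero image: empty mask
  expect_false(any(auto_soma_mask(projection2d(matrix(0, 40, 40)))))
  # bright disc of ~200 px is nearly fully covered
  px <- matrix(0, 48, 48)
  cc <- expand.grid(y = 1:48, x = 1:48)
  disc <- (cc$y - 24)^2 + (cc$x - 24)^2 <= 8^2
  px[cbind(cc$y[disc], cc$x[disc])] <- 220
  m <- auto_soma_mask(projection2d(px), min_area = 50,
                      intensity_quantile = 0.85)
  expect_gte(sum(m & px > 0) / sum(px > 0), 0.95)
  # a 3-px-wide tube is rejected by the compactness filter
  px2 <- matrix(0, 60, 60)
  px2[10:12, 5:55] <- 220
  m2 <- auto_soma_mask(projection2d(px2), min_area = 20,
                       intensity_quantile = 0.9, compactness_min = 0.25)
  expect_false(any(m2 & px2 > 0))
})

test_that("the composed pipeline recovers ground truth severity", {
  # severity ladder: mean scores strictly increase with class
  classes <- list(c(0, 2000), c(8000, 20000), c(28000, 42000),
                  c(48000, 62000))
  means <- vapply(seq_along(classes), function(ci) {
    sc <- vapply(1:3, function(s) {
      set.seed(100 * ci + s)
      mass <- runif(1, classes[[ci]][1], classes[[ci]][2])
      cfg <- tiny_cfg(mass = mass, seed = 100 * ci + s)
      r <- render_embryo(cfg)
      quantify_embryo(r$stack, mask = dorsal_scoring_mask(r$truth, cfg))$score
    }, numeric(1))
    mean(sc)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  # absolute accuracy at a representative severity
  cfg <- tiny_cfg(mass = 30000, seed = 77)
  r <- render_embryo(cfg)
  sc <- quantify_embryo(r$stack, mask = dorsal_scoring_mask(r$truth, cfg),
                        embryo_id = "acc")
  expect_lt(abs(sc$score - r$truth$expected_dorsal_mass) /
              r$truth$expected_dorsal_mass, 0.15)
  # all-zero stack scores zero
  z <- volume_stack(array(0L, c(32, 32, 4)))
  expect_equal(quantify_embryo(z, window = 9)$score, 0)
})
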