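test_that("rendering is fully determined by config and seed", {
  cfg <- tiny_cfg(mass = 20000, seed = 5)
  a <- render_embryo(cfg)
  b <- render_embryo(cfg)
  expect_identical(a$stack$voxels, b$stack$voxels)
  expect_identical(a$truth$expected_dorsal_mass, b$truth$expected_dorsal_mass)
  # a different seed changes the noise realisation
  c_ <- render_embryo(tiny_cfg(mass = 20000, seed = 6))
  expect_false(identical(a$stack$voxels, c_$stack$voxels))
})

test_that("zero configurations render zero", {
  # no dorsal mass: ground truth mass is exactly 0
  r0 <- render_embryo(tiny_cfg(mass = 0, seed = 2))
  expect_identical(r0$truth$expected_dorsal_mass, 0)
  # all intensities zero, noise off: all-zero stack
  cfg <- sim_config(soma_cluster = list(center = c(y = 48, x = 64), radius = 9,
                                        n_somata = 6, soma_radius = 3,
                                        peak_intensity = 0),
                    ventral_tracts = list(),
                    dorsal_process = list(mass = 0, path = NULL, width = 7),
                    noise = list(enabled = FALSE, poisson_scale = 1,
                                 gaussian_sd = 0, background = 0),
                    seed = 1)
  expect_true(all(render_embryo(cfg)$stack$voxels == 0))
})

test_that("expected dorsal mass matches brute-force summation over the tube footprint", {
  # straight dorsal tube, PSF on, noise off
  path <- rbind(c(40, 70), c(12, 90))
  cfg <- sim_config(dorsal_process = list(mass = 25000, path = path,
                                          width = 7),
                    ventral_tracts = list(),
                    noise = list(enabled = FALSE, poisson_scale = 1,
                                 gaussian_sd = 0, background = 0),
                    seed = 3)
  r <- render_embryo(cfg)
  # brute force: sum the noise-free projection over the dilated tube
  # footprint, away from the soma
  proj <- max_project_z(r$stack)$pixels
  ny <- nrow(proj); nx <- ncol(proj)
  cc <- expand.grid(y = seq_len(ny), x = seq_len(nx))
  seg_d2 <- function(py, px_, a, b) {
    ab <- b - a; len2 <- sum(ab^2)
    t_ <- pmin(pmax(((py - a[1]) * ab[1] + (px_ - a[2]) * ab[2]) / len2, 0), 1)
    (py - a[1] - t_ * ab[1])^2 + (px_ - a[2] - t_ * ab[2])^2
  }
  near_tube <- seg_d2(cc$y, cc$x, path[1, ], path[2, ]) <= (7 / 2 + 5)^2
  footprint <- matrix(near_tube, ny, nx) & !r$truth$soma_mask_proj
  brute <- sum(proj[footprint])
  expect_lt(abs(brute - r$truth$expected_dorsal_mass) /
              r$truth$expected_dorsal_mass, 0.02)
})

test_that("ground-truth mass strictly increases with the severity knob", {
  masses <- c(1000, 8000, 20000, 45000)
  got <- vapply(masses, function(m)
    render_embryo(tiny_cfg(mass = m, seed = 9))$truth$expected_dorsal_mass,
    numeric(1))
  expect_true(all(diff(got) > 0))
})

test_that("background-only noise is unbiased within 3 SE over replicates", {
  cfg0 <- sim_config(image_shape = c(y = 24, x = 24, z = 3),
                     soma_cluster = list(center = c(y = 12, x = 12),
                                         radius = 2, n_somata = 1,
                                         soma_radius = 1, peak_intensity = 0),
                     ventral_tracts = list(),
                     dorsal_process = list(mass = 0, path = NULL, width = 7),
                     noise = list(enabled = TRUE, poisson_scale = 1,
                                  gaussian_sd = 2, background = 12),
                     seed = 1)
  means <- vapply(1:100, function(s) {
    cfg <- cfg0; cfg$seed <- s
    mean(render_embryo(cfg)$stack$voxels)
  }, numeric(1))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 12), 3 * se)
})

test_that("DV-flipping the config is equivalent to flipping the rendered stack", {
  cfg <- sim_config(dorsal_process = list(mass = 15000, path = NULL,
                                          width = 7),
                    noise = list(enabled = FALSE, poisson_scale = 1,
                                 gaussian_sd = 0, background = 0),
                    seed = 4)
  a <- flip_dv(render_embryo(cfg)$stack)
  b <- render_embryo(flip_dv(cfg))$stack
  expect_identical(a$voxels, b$voxels)
})

test_that("geometry outside the volume is rejected with a clear message", {
  expect_error(sim_config(soma_cluster = list(center = c(y = 3, x = 64),
                                              radius = 9, n_somata = 6,
                                              soma_radius = 3,
                                              peak_intensity = 180)),
               "outside")
  expect_error(tiny_cfg(mass = -5), "non-negative")
  expect_error(sim_config(ventral_tracts = list(
    list(path = rbind(c(10, 10), c(200, 10)), width = 3, intensity = 50))),
    "outside")
})

test_that("single-neuron rendering places origins as constructed", {
  cfg <- single_cfg(seed = 11)
  # ventral-pole origin lands on the ventral half of the soma boundary
  rv <- render_single_neuron(cfg, origin_angle = 180, n_processes = 1)
  o <- rv$truth$origin_points[[1]]
  expect_gt(o["y"], cfg$soma_cluster$center[1])  # ventral = larger y
  expect_equal(rv$truth$n_processes, 1L)
  # two processes, one dorsal one ventral
  r2 <- render_single_neuron(cfg, origin_angle = c(0, 180), n_processes = 2)
  expect_equal(r2$truth$n_processes, 2L)
  cls <- vapply(r2$truth$axon_centerlines, function(p) p$class, "")
  expect_setequal(cls, c("dorsal", "ventral"))
  # angles closer than the tube width are rejected
  expect_error(render_single_neuron(cfg, origin_angle = c(10, 15),
                                    n_processes = 2, process_width = 2),
               "closer than")
  expect_error(render_single_neuron(cfg, origin_angle = 1:5, n_processes = 5),
               "between 1 and 4")
})

test_that("DV-flipping a single-neuron render maps dorsal truth to ventral", {
  cfg <- single_cfg(seed = 13, noise = FALSE)
  r <- render_single_neuron(cfg, origin_angle = 0, n_processes = 1)
  tr <- as_neuron_trace(r$truth)
  expect_equal(classify_origin(tr)$call, "dorsal")
  trf <- flip_dv(tr)
  expect_equal(classify_origin(trf)$call, "ventral")
  expect_equal(classify_trajectory(trf)$call, "ventral")
})

test_that("make_cohort writes one TIFF and one truth row per embryo, deterministically", {
  entries <- lapply(1:3, function(i)
    list(config = tiny_cfg(mass = c(3000, 30000, 50000)[i], seed = i),
         embryo_id = sprintf("e%02d", i), treatment = "dcc-MO",
         dose_ng = 6, replicate = 1 + i %% 2))
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  res <- make_cohort(entries, d1)
  expect_length(res$files, 3L)
  expect_true(all(file.exists(res$files)))
  expect_equal(nrow(res$truth), 3L)
  expect_equal(colnames(res$truth),
               c("embryo_id", "treatment", "dose_ng", "replicate",
                 "expected_dorsal_mass", "n_processes", "seed"))
  make_cohort(entries, d2)
  expect_identical(readLines(file.path(d1, "truth.csv")),
                   readLines(file.path(d2, "truth.csv")))
  # duplicate ids are rejected
  expect_error(make_cohort(c(entries, entries[1]), tempdir()), "duplicate")
  # class counts in the truth table match the requested design
  grades <- assign_grade(res$truth$expected_dorsal_mass)
  expect_equal(grades, c(0L, 2L, 3L))
})
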