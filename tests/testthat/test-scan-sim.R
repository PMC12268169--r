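test_that("particle paths: immobile limit, Brownian step size, exchange", {
  g <- small_geometry(32)
  set.seed(1)
  p0 <- simulate_particle_paths(20, D = 0, g, n_frames = 2,
                                box_um = c(2, 2, 2))
  expect_true(all(p0$x == p0$x[, 1]))
  expect_true(all(p0$z == p0$z[, 1]))

  # per-line Brownian steps have sd sqrt(2 D dt) per axis
  set.seed(2)
  p1 <- simulate_particle_paths(50, D = 2, g, n_frames = 4,
                                box_um = c(50, 50, 50))
  dz <- diff(t(p1$z))  # z has no wrapping for a huge box
  expect_equal(stats::sd(dz), sqrt(2 * 2 * g$line_time_s), tolerance = 0.03)

  # two-state exchange with k_on = k_off = 1/s equilibrates at 1/2
  set.seed(3)
  p2 <- simulate_particle_paths(200, D = 1, g, n_frames = 40,
                                box_um = c(5, 5, 5),
                                k_on_s = 1, k_off_s = 1, bound0 = FALSE)
  total_t <- ncol(p2$bound) * g$line_time_s
  frac <- mean(p2$bound[, -(1:(5 * 32))])  # discard burn-in
  n_eff <- 200 * total_t * 1  # ~one transition per particle per second
  se <- sqrt(0.25 / n_eff)
  expect_lt(abs(frac - 0.5), 3 * se + 0.01)

  expect_error(simulate_particle_paths(5, 2, g, 2, box_um = c(-1, 1, 1)),
               "positive")
  expect_error(simulate_particle_paths(5, 2, g, 2, box_um = c(1, 1, 1),
                                       k_on_s = -2), "negative")
})

test_that("rendered frames follow the Gaussian PSF and detector model", {
  g <- small_geometry(64)
  p <- psf_model()
  dr <- g$pixel_size_um
  center <- (32 - 0.5) * dr  # center of pixel (32, 32)
  img <- render_raster_frame(matrix(c(center, center, 0), 1), 500, g, p)
  expect_equal(which(img == max(img), arr.ind = TRUE)[1, ],
               c(row = 32, col = 32))
  expect_equal(max(img), 500)  # discretized Gaussian peaks at brightness
  # closed-form Gaussian integral: sum = eps * pi w0^2 / (2 dr^2)
  expect_equal(sum(img), 500 * pi * p$w0_um^2 / (2 * dr^2),
               tolerance = 0.02)

  # empty particle set with background and no noise: constant frame
  img0 <- render_raster_frame(matrix(numeric(0), 0, 3), 500, g, p,
                              background = 120)
  expect_true(all(img0 == 120))

  # doubling particle number doubles the mean intensity
  set.seed(9)
  pos <- cbind(stats::runif(400, 0, 64 * dr), stats::runif(400, 0, 64 * dr),
               stats::runif(400, -1, 1))
  m1 <- mean(render_raster_frame(pos[1:200, ], 500, g, p))
  m2 <- mean(render_raster_frame(pos, 500, g, p))
  expect_equal(m2 / m1, 2, tolerance = 0.1)
})

test_that("detector noise variance is proportional to the mean", {
  g <- small_geometry(64)
  p <- psf_model()
  set.seed(4)
  levels <- seq(1000, 5000, length.out = 9)
  v <- vapply(levels, function(b) {
    fr <- render_raster_frame(matrix(numeric(0), 0, 3), 0, g, p,
                              background = b, s_detector = 400)
    stats::var(as.numeric(fr))
  }, numeric(1))
  fit <- stats::lm(v ~ levels)
  expect_equal(unname(stats::coef(fit)[2]), 400, tolerance = 0.05)
})

test_that("simulated movies are stationary and carry consistent truth", {
  g <- small_geometry(64)
  nuc <- default_nuclei(g, 1, 20)
  # the OLS slope of a short correlated intensity series is noisy (a few
  # percent per seed even for a generator that is stationary by
  # construction), so the bound reflects the seed-averaged noise floor
  drift <- vapply(1:6, function(seed) {
    tr <- sim_truth(n_free = 200, n_immobile = 200, seed = seed)
    sim <- simulate_timeseries(tr, g, psf_pair(), n_frames = 50,
                               nuclei = nuc, seed = seed)
    mk <- sim$mask_truth > 0
    means <- apply(sim$green, 3, function(f) mean(f[mk]))
    unname(stats::coef(stats::lm(means ~ seq_along(means)))[2] * 50 /
             mean(means))
  }, numeric(1))
  expect_lt(abs(mean(drift)), 0.02)

  # concentration truth is count / (N_A * V)
  tr <- recovery_truth(C_nM = 30, phi = 0.5, psi = 0.3, nuclei = nuc,
                       geometry = g)
  vol <- pi * nuc$r_um^2 * 2 * tr$half_depth_um
  expect_equal(tr$C_tot_nM, tr$n_green / (0.602214076 * vol),
               tolerance = 1e-10)
  expect_equal(tr$C_tot_nM, 30, tolerance = 0.02)
  expect_equal(tr$phi, 0.5, tolerance = 0.02)

  # overlapping nuclei are rejected
  bad <- data.frame(cx_px = c(20, 30), cy_px = c(20, 20), r_px = 10,
                    cx_um = c(20, 30) * g$pixel_size_um,
                    cy_um = 20 * g$pixel_size_um,
                    r_um = 10 * g$pixel_size_um)
  expect_error(simulate_timeseries(tr, g, psf_pair(), 7, bad), "overlap")
})

test_that("bead stacks have the protocol spacing and generating axial width", {
  st <- simulate_bead_stack(offset_nm = c(0, 0, 0), z_step_um = 0.05,
                            z_half_um = 3.2, n_beads = 3, s_detector = 0,
                            seed = 2)
  # slice count = range / step (+1 fencepost)
  expect_equal(length(st$z_um), 2 * 3.2 / 0.05 + 1)
  # axial FWHM of the rendered profile matches the generating Gaussian
  b <- 1
  ij <- round(st$centers_um[b, ] / (st$pixel_size_nm / 1000))
  prof <- st$green[ij[2], ij[1], ]
  half <- max(prof) / 2
  above <- range(which(prof >= half))
  fwhm <- (diff(above)) * 0.05
  expect_equal(fwhm, 1.5 * sqrt(2 * log(2)), tolerance = 0.02)
  # beads closer than 3 w0 are rejected
  expect_error(simulate_bead_stack(centers_um = rbind(c(1, 1), c(1.2, 1)),
                                   n_beads = 2), "3\\*w0")
})

test_that("movies round-trip through 16-bit TIFF with YAML sidecar", {
  g <- small_geometry(32)
  nuc <- default_nuclei(g, 1, 10)
  tr <- sim_truth(n_free = 20, seed = 5)
  sim <- simulate_timeseries(tr, g, psf_pair(), n_frames = 2, nuclei = nuc,
                             seed = 5)
  dir <- tempfile("movie")
  write_movie_tiff(sim, dir)
  back <- read_movie_tiff(dir)
  expect_equal(back$green, sim$green)
  expect_equal(back$red, sim$red)
  expect_equal(back$geometry$line_time_s, g$line_time_s)
  unlink(dir, recursive = TRUE)
})
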