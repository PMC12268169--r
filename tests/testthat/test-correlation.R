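test_that("direct oracle reproduces hand-computed values", {
  # 2x2 image [[1,2],[3,4]]: lag (1,0) pairs are 1*2 and 3*4
  img <- matrix(c(1, 3, 2, 4), 2)
  s <- direct_correlation_oracle(img, img, matrix(TRUE, 2, 2), max_lag = 1,
                                 min_pairs = 1)
  expect_equal(s$values[s$dy == 0, s$dx == 1], (2 + 12) / 2 / 2.5^2 - 1)
  expect_equal(s$values[s$dy == 0, s$dx == 1], 0.12)

  # constant image: zero fluctuation everywhere
  cs <- direct_correlation_oracle(matrix(5, 8, 8), matrix(5, 8, 8),
                                  matrix(TRUE, 8, 8), 3, min_pairs = 1)
  expect_true(all(cs$values == 0))

  # single bright pixel among zeros: G(0,0) = n - 1
  one <- matrix(0, 10, 10); one[4, 6] <- 7
  s1 <- direct_correlation_oracle(one, one, matrix(TRUE, 10, 10), 2,
                                  min_pairs = 1)
  expect_equal(s1$values[s1$dy == 0, s1$dx == 0], 100 - 1)

  # G(0,0) is variance / mean^2 over the mask
  set.seed(1)
  r <- matrix(rexp(144, 1 / 50), 12)
  m <- matrix(runif(144) > 0.2, 12)
  sr <- direct_correlation_oracle(r, r, m, 1, min_pairs = 1)
  n <- sum(m)
  expect_equal(sr$values[sr$dy == 0, sr$dx == 0],
               stats::var(r[m]) * (n - 1) / n / mean(r[m])^2)
})

test_that("FFT estimator equals the direct sum on random masked inputs", {
  set.seed(42)
  for (i in 1:20) {
    a <- matrix(rnorm(32 * 32, 100, 12), 32)
    b <- matrix(rnorm(32 * 32, 80, 9), 32)
    m <- matrix(runif(32 * 32) > runif(1, 0.1, 0.5), 32)
    pair <- sample(c("gg", "gc"), 1)
    if (pair == "gg") b <- a
    s_fft <- masked_correlation_2d(a, b, m, max_lag = 8, pair = pair,
                                   min_pairs = 1)
    s_dir <- direct_correlation_oracle(a, b, m, max_lag = 8, pair = pair,
                                       min_pairs = 1)
    expect_lt(max(abs(s_fft$values - s_dir$values), na.rm = TRUE), 1e-10)
    expect_equal(is.na(s_fft$values), is.na(s_dir$values))
  }
})

test_that("cross-correlation of independent noise stays at the noise floor", {
  set.seed(7)
  a <- matrix(rnorm(64 * 64, 200, 10), 64)
  b <- matrix(rnorm(64 * 64, 150, 10), 64)
  m <- matrix(TRUE, 64, 64)
  s <- masked_correlation_2d(a, b, m, max_lag = 10, pair = "gc")
  bound <- 3 / sqrt(s$n_pairs) * (10 / 200) * (10 / 150) * 200 * 150 /
    (200 * 150)  # 3 sigma of the G estimator
  ok <- abs(s$values) < 3 * (10 * 10) / (200 * 150) / sqrt(s$n_pairs)
  expect_gt(mean(ok), 0.98)
  expect_true(all(abs(s$values) <
                    5 * (10 * 10) / (200 * 150) / sqrt(s$n_pairs)))
})

test_that("auto surfaces peak at zero lag and are lag-symmetric", {
  g <- small_geometry(96)
  p <- psf_model()
  # static particles filling the field: a stationary image with no nuclear
  # edges, so the surface shape is the pure PSF kernel
  set.seed(3)
  n <- 1500
  fov <- 96 * g$pixel_size_um
  pos <- cbind(stats::runif(n, 0, fov), stats::runif(n, 0, fov),
               stats::runif(n, -2, 2))
  f <- render_raster_frame(pos, 1000, g, p)
  mk <- matrix(FALSE, 96, 96); mk[11:86, 11:86] <- TRUE
  s <- masked_correlation_2d(f, f, mk, max_lag = 16)
  i0 <- match(0, s$dx)
  expect_equal(which.max(s$values[1, ]), i0)
  expect_true(all(s$values[1, i0] >= s$values, na.rm = TRUE))
  # G(dx, 0) == G(-dx, 0) for an autocorrelation
  expect_equal(s$values[1, ], rev(s$values[1, ]))

  # noise-free immobile surface matches the pure Gaussian PSF kernel
  fa <- fit_fast_axis(s, p, g)
  expect_equal(fa$w0_adj_um, p$w0_um, tolerance = 0.05)
  pred <- model_rics_acf(matrix(s$dx, length(s$dy), length(s$dx),
                                byrow = TRUE),
                         matrix(s$dy, length(s$dy), length(s$dx)),
                         A = fa$A, D = 0, g, p, B = fa$B,
                         w0 = fa$w0_adj_um)
  keep <- !is.na(s$values) &
    outer(s$dy, s$dx, function(Y, X) abs(X) <= 8 & Y <= 8)
  keep[1, i0] <- FALSE  # zero lag carries the shot noise
  r2 <- 1 - sum((s$values[keep] - pred[keep])^2) /
    sum((s$values[keep] - mean(s$values[keep]))^2)
  expect_gt(r2, 0.99)
})

test_that("correlation amplitude is gain-invariant and scales as 1/N", {
  g <- small_geometry(96)
  nuc <- default_nuclei(g, 1, 30)
  # gain invariance: rescaling both channels leaves G unchanged
  set.seed(8)
  a <- matrix(rexp(96^2, 1 / 300), 96)
  m <- nuclei_mask(nuc, g) > 0
  s1 <- masked_correlation_2d(a, a, m, 6)
  s2 <- masked_correlation_2d(2.3 * a, 2.3 * a, m, 6)
  expect_equal(s1$values, s2$values, tolerance = 1e-12)

  # amplitude ~ 1/N across particle counts (log-log slope -1)
  A_of_n <- vapply(c(25, 50, 100, 200), function(n) {
    acc <- 0
    for (seed in 1:2) {
      tr <- sim_truth(n_free = n, background = 0, s_detector = 0,
                      seed = seed)
      sim <- simulate_timeseries(tr, g, psf_pair(), n_frames = 6,
                                 nuclei = nuc, seed = seed * 100 + n)
      s <- NULL
      for (f in 1:6) {
        sf <- masked_correlation_2d(sim$green[, , f], sim$green[, , f],
                                    sim$mask_truth > 0, 16)
        s <- if (is.null(s)) sf$values else s + sf$values
      }
      sf$values <- s / 6
      acc <- acc + fit_fast_axis(sf, psf_model(), g)$A
    }
    acc / 2
  }, numeric(1))
  slope <- stats::coef(stats::lm(log(A_of_n) ~ log(c(25, 50, 100, 200))))[2]
  expect_equal(unname(slope), -1, tolerance = 0.15)
})

test_that("group averaging propagates surfaces and missing bins", {
  # identical member frames: average equals any member
  set.seed(5)
  f <- matrix(rexp(64^2, 1 / 200), 64)
  mk <- matrix(0L, 64, 64); mk[10:50, 10:50] <- 1L
  grp <- structure(list(members = 1:7, time_s = 0, cycle = NA,
                        geometry = small_geometry(64), mask = mk,
                        green = list(detrended = rep(list(f), 7))),
                   class = "frame_group")
  sa <- average_group_correlation(grp, "gg", max_lag = 8, min_pairs = 1)
  s1 <- masked_correlation_2d(f, f, mk > 0, max_lag = 8, min_pairs = 1)
  expect_equal(sa$values, s1$values)
  # bins with too few pairs are missing everywhere
  s_small <- average_group_correlation(grp, "gg", max_lag = 8,
                                       min_pairs = 1e7)
  expect_true(all(is.na(s_small$values)))
  expect_error(average_group_correlation(
    structure(grp[c("members", "mask", "geometry")], class = "frame_group"),
    "rr"), "channel")
})

test_that("far-lag baseline subtraction recenters the pedestal", {
  g <- small_geometry(64)
  # immobile surface: the kernel carries no mass in the far-lag annulus
  s <- model_surface(A = 0.1, D = 2, phi = 1, g, psf_model(),
                     B = -0.004)
  s2 <- subtract_surface_baseline(s, r_min = 24)
  expect_equal(attr(s2, "baseline"), -0.004, tolerance = 0.05)
  expect_lt(abs(mean(s2$values[, abs(s2$dx) >= 30])), 2e-4)
  s3 <- crop_surface(s2, 10, 5)
  expect_equal(dim(s3$values), c(6, 21))
  expect_equal(range(s3$dx), c(-10, 10))
})
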