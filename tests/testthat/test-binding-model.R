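test_that("Hill occupancy: half-saturation, saturation, sigmoidal pool", {
  expect_equal(hill_bound(10, KD = 10, CB = 40), 20)
  expect_equal(hill_bound(1e9, KD = 10, CB = 40), 40, tolerance = 1e-6)
  # sigmoidal inactive pool at its dissociation constant
  expect_equal(hill_bound(24, KD = 24, CB = 34, n = 2), 17)
  expect_equal(hill_bound(0, 5, 35), 0)
})

test_that("power-law site capacity", {
  expect_equal(power_law_sites(0), 0)
  expect_equal(power_law_sites(1), 420)
  expect_equal(power_law_sites(2) / power_law_sites(1), 2^0.7)
})

test_that("free-concentration solver inverts the conservation relation", {
  gaf <- binding_params(KD_active = 5, CB_active = 35,
                        KD_inactive = 0.4, CB_inactive = 9)
  expect_equal(unlist(solve_free_concentration(0, gaf)[1, -1]),
               c(C_free = 0, C_active = 0, C_inactive = 0))
  none <- binding_params(KD_active = 5, CB_active = 0,
                         KD_inactive = 1, CB_inactive = 0)
  expect_equal(solve_free_concentration(c(1, 7, 80), none)$C_free,
               c(1, 7, 80))
  # forward-evaluate at C_free = 5, then invert
  ct <- 5 + hill_bound(5, 5, 35) + hill_bound(5, 0.4, 9)
  expect_equal(solve_free_concentration(ct, gaf)$C_free, 5,
               tolerance = 1e-10)
})

test_that("conservation holds and the solver matches brute force", {
  set.seed(11)
  for (i in 1:50) {
    pr <- binding_params(KD_active = exp(runif(1, log(0.1), log(100))),
                         CB_active = exp(runif(1, log(1), log(200))),
                         KD_inactive = exp(runif(1, log(0.1), log(100))),
                         CB_inactive = exp(runif(1, log(1), log(200))),
                         n_active = sample(1:2, 1),
                         n_inactive = sample(1:2, 1))
    ct <- exp(runif(1, log(0.5), log(500)))
    sol <- solve_free_concentration(ct, pr)
    expect_lt(abs(sol$C_free + sol$C_active + sol$C_inactive - ct), 1e-9)
    expect_lt(abs(sol$C_free - brute_force_free(ct, pr)), 1e-6)
  }
})

test_that("solved pools are nondecreasing in total concentration", {
  pr <- binding_params(KD_active = 17, CB_active = 50, KD_inactive = 24,
                       CB_inactive = 34, n_inactive = 2)
  sol <- solve_free_concentration(seq(0, 300, length.out = 60), pr)
  expect_true(all(diff(sol$C_active) >= -1e-9))
  expect_true(all(diff(sol$C_inactive) >= -1e-9))
  expect_true(all(diff(sol$C_free) >= -1e-9))
})

test_that("equilibrium fit recovers Hill parameters from noisy records", {
  gaf <- binding_params(KD_active = 5, CB_active = 35,
                        KD_inactive = 0.4, CB_inactive = 9)
  ct <- exp(seq(log(0.5), log(60), length.out = 30))
  truth <- solve_free_concentration(ct, gaf)

  # noise-free records reproduce themselves almost exactly
  clean <- data.frame(C_tot_nM = ct, C_active_nM = truth$C_active,
                      C_inactive_nM = truth$C_inactive)
  fit0 <- fit_equilibrium_model(clean, n_starts = 8, seed = 1)
  expect_lt(attr(fit0, "ssr"), 1e-8)

  set.seed(42)
  noisy <- data.frame(C_tot_nM = ct,
                      C_active_nM = truth$C_active *
                        (1 + rnorm(30, 0, 0.05)),
                      C_inactive_nM = truth$C_inactive *
                        (1 + rnorm(30, 0, 0.05)))
  fit <- fit_equilibrium_model(noisy, n_starts = 20, seed = 1)
  expect_equal(fit$KD_active, 5, tolerance = 0.25)
  expect_equal(fit$CB_active, 35, tolerance = 0.25)
  expect_equal(fit$KD_inactive, 0.4, tolerance = 0.25)
  expect_equal(fit$CB_inactive, 9, tolerance = 0.25)
})

test_that("cycle exclusions drop early and short-cycle records", {
  gaf <- binding_params(KD_active = 5, CB_active = 35,
                        KD_inactive = 0.4, CB_inactive = 9)
  ct <- exp(seq(log(0.5), log(60), length.out = 24))
  truth <- solve_free_concentration(ct, gaf)
  rec <- data.frame(C_tot_nM = ct, C_active_nM = truth$C_active,
                    C_inactive_nM = truth$C_inactive,
                    cycle = rep(c(10, 12, 13), each = 8))
  fit <- fit_equilibrium_model(rec, n_starts = 6, seed = 1)
  # cycle 10 dropped entirely, first two of each remaining cycle dropped
  expect_equal(attr(fit, "n_used"), 12)
  expect_error(fit_equilibrium_model(rec[rec$cycle == 10, ], seed = 1),
               ">= 8")
})

test_that("power-law equilibrium fit recovers the active dissociation constant", {
  prz <- binding_params(KD_active = 17, KD_inactive = 24, CB_inactive = 34,
                        n_inactive = 2, power_law = TRUE, pl_a = 4,
                        pl_k = 0.7)
  ct <- exp(seq(log(5), log(300), length.out = 30))
  truth <- solve_free_concentration(ct, prz)
  set.seed(7)
  rec <- data.frame(C_tot_nM = ct,
                    C_active_nM = truth$C_active * (1 + rnorm(30, 0, 0.05)),
                    C_inactive_nM = truth$C_inactive *
                      (1 + rnorm(30, 0, 0.05)))
  fit <- fit_equilibrium_model(rec, n_inactive = 2, power_law = TRUE,
                               n_starts = 20, seed = 1, fix_pl_k = 0.7,
                               weights = "relative")
  expect_equal(fit$KD_active, 17, tolerance = 0.3)
  expect_equal(fit$pl_a, 4, tolerance = 0.3)
  expect_equal(fit$KD_inactive, 24, tolerance = 0.3)
})

test_that("site concentrations and dissociation-constant back-out", {
  expect_equal(sites_concentration(0.602214076, 1, ploidy = 1), 1)
  l1 <- sites_concentration(12135, 435, ploidy = 1)
  expect_equal(l1, 46.3, tolerance = 0.002)
  expect_equal(sites_concentration(12135, 435, ploidy = 2), 2 * l1)

  # K_D back-out round-trips the n = 1 Hill model
  L <- 92.68; KD <- 17; cf <- 40
  cb <- hill_bound(cf, KD, L)
  expect_equal(kd_from_occupancy(cf, cb, L), KD)
})

test_that("accessible-site time course inverts the occupancy model", {
  KD <- 17
  # saturation: C_free >> K_D means sites ~ bound
  out <- accessible_sites_timecourse(C_active = 20, C_free = 1e6, KD)
  expect_equal(out$C_B_nM, 20, tolerance = 1e-4)
  # half-occupancy round trip
  out2 <- accessible_sites_timecourse(C_active = 46.34, C_free = KD, KD)
  expect_equal(out2$C_B_nM, 2 * 46.34)
  # a decreasing true site capacity yields a decreasing estimate
  cb_true <- seq(90, 40, length.out = 8)
  cf <- seq(10, 45, length.out = 8)
  ca <- hill_bound(cf, KD, cb_true)
  est <- accessible_sites_timecourse(ca, cf, KD, volume_um3 = 435)
  expect_equal(est$C_B_nM, cb_true)
  expect_true(all(diff(est$C_B_nM) < 0))
  expect_equal(est$n_sites, cb_true * 0.602214076 * 435 / 2)
  # zero free concentration is missing, not infinite
  expect_true(is.na(accessible_sites_timecourse(1, 0, KD)$C_B_nM))
})

test_that("Smoluchowski on-rate and residence times", {
  kon <- smoluchowski_kon(D_um2_s = 2, b_nm = 0.34, a = 0.2)
  expect_equal(kon, 1.03e-3, tolerance = 0.01)
  expect_equal(smoluchowski_kon(2, 0.34, 0.5), 2.57e-3, tolerance = 0.01)
  # linear in every factor
  expect_equal(smoluchowski_kon(4, 0.34, 0.2) / kon, 2)
  expect_equal(smoluchowski_kon(2, 0.68, 0.2) / kon, 2)

  expect_equal(residence_time(20, 1e-3), 50)
  expect_equal(residence_time(20, 1e-4), 500)
  expect_equal(residence_time(20, 1e-1), 0.5)
  # tau = 1/k_off identity
  expect_equal(residence_time(20, kon), 1 / (kon * 20))
})
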