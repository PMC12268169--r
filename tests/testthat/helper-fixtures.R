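# Shared fixtures: small geometries, model-generated surfaces, and a cache
# for the expensive end-to-end recovery runs so several test files can share
# them.

small_geometry <- function(n_px = 64) {
  scan_geometry(line_time_s = 4.94e-3, n_rows = n_px, n_cols = n_px,
                frame_time_s = n_px * 4.94e-3)
}

reference_geometry <- function() {
  scan_geometry(pixel_size_nm = 31.95, pixel_dwell_s = 2.06e-6,
                frame_time_s = 5.06, n_rows = 1024L, n_cols = 1024L)
}

# noise-free surface synthesized from the two-component RICS model
model_surface <- function(A, D, phi, geometry, psf, B = 0, max_lag = 32) {
  dx <- -max_lag:max_lag
  dy <- 0:max_lag
  vals <- outer(dy, dx, function(Y, X)
    model_rics_two_component(X, Y, A = A, D = D, phi = phi,
                             geometry = geometry, psf = psf, B = B))
  ricsbind:::new_correlation_surface(vals, matrix(1e6, length(dy),
                                                  length(dx)),
                                     dx, dy, "gg", 1L, geometry)
}

# end-to-end recovery run, cached across test files (helpers are sourced
# once per test_dir run, so the environment persists)
.e2e_cache <- new.env(parent = emptyenv())

e2e_recovery <- function(seed) {
  key <- as.character(seed)
  if (!is.null(.e2e_cache[[key]])) return(.e2e_cache[[key]])
  res <- run_full_pipeline(default_run_config(seed = seed))
  out <- list(summary = c(C = mean(res$records$C_tot_nM),
                          phi = mean(res$records$phi),
                          D = mean(res$records$D_um2_s),
                          psi = mean(res$records$psi)),
              records = res$records, brightness = res$brightness,
              truth = res$truth)
  .e2e_cache[[key]] <- out
  out
}

e2e_medians <- function(seeds = 1:5) {
  m <- t(vapply(seeds, function(s) e2e_recovery(s)$summary, numeric(4)))
  apply(m, 2, stats::median)
}

# brute-force conservation solver: staged grid refinement of the residual
brute_force_free <- function(C_tot, params, stages = 4, width = NULL) {
  lo <- 0; hi <- C_tot
  for (s in seq_len(stages)) {
    grid <- seq(lo, hi, length.out = 2001)
    resid <- abs(grid +
                   hill_bound(grid, params$KD_inactive, params$CB_inactive,
                              params$n_inactive) +
                   hill_bound(grid, params$KD_active,
                              if (params$power_law)
                                power_law_sites(grid, params$pl_a,
                                                params$pl_k)
                              else params$CB_active, params$n_active) -
                   C_tot)
    i <- which.min(resid)
    step <- grid[2] - grid[1]
    lo <- max(0, grid[i] - step)
    hi <- min(C_tot, grid[i] + step)
  }
  (lo + hi) / 2
}
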