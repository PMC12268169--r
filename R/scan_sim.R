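# Synthetic two-channel raster-scan movies with known ground truth.
#
# The simulator emulates the statistical structure the RICS analysis assumes:
# nuclei containing freely diffusing, quasi-immobile and co-bound fluorescent
# particles, rendered line-by-line through a 3D Gaussian PSF with raster-scan
# timing and an analog detector whose noise variance is proportional to the
# mean (variance = S_true * mean).

#' Ground truth for a simulated movie
#'
#' Particle counts are totals across all nuclei. Green-channel particles are
#' `n_free` (Brownian, diffusivity `D_free_um2_s`), `n_immobile`
#' (quasi-immobile binders) and `n_cobound` (quasi-immobile binders rendered
#' in both channels, i.e. bound to the same structure as a red label). The
#' red channel additionally contains `n_red_only` quasi-immobile particles.
#'
#' Quasi-immobile binders hold a fixed position and relocate to a uniformly
#' drawn position in their nucleus with rate `k_off_s` (unbinding followed by
#' fast rebinding at a new site). The default `k_off_s = NULL` resolves to
#' `1 / frame_time` at simulation time, fast enough that the moving-average
#' detrend does not remove the bound pool, slow enough that a particle is
#' immobile on the timescale of the correlation window. `k_on_s` is the
#' rebinding rate used by the explicit two-state mobility model of
#' [simulate_particle_paths()].
#'
#' Derived fractions: `phi = (n_immobile + n_cobound) / n_green`,
#' `psi = n_cobound / n_green`.
#'
#' @param n_free,n_immobile,n_cobound,n_red_only particle counts (>= 0).
#' @param D_free_um2_s free-pool diffusivity (um^2/s).
#' @param brightness,brightness_red mean detector counts per particle per
#'   dwell at the PSF center, per channel; with the default detector the
#'   defaults give a molecular brightness Q near 0.8, typical of a bright
#'   fluorescent-protein fusion on an analog detector.
#' @param background constant detector background offset b0 (counts).
#' @param s_detector analog-detector S factor: pixel noise variance equals
#'   `s_detector * mean` (counts).
#' @param k_off_s relocation (unbinding) rate of bound particles, 1/s.
#' @param k_on_s rebinding rate for the two-state mobility model, 1/s.
#' @param half_depth_um particles occupy z in `[-half_depth, half_depth]`.
#' @param channel_offset_nm red-channel PSF center displacement (x, y, z).
#' @param seed integer seed attached to the truth record.
#' @return A `sim_truth` list including derived fractions `phi`, `psi`.
#' @export
sim_truth <- function(n_free, n_immobile = 0, n_cobound = 0, n_red_only = 0,
                      D_free_um2_s = 2, brightness = 1000,
                      brightness_red = 1000, background = 3000,
                      s_detector = 400, k_off_s = NULL, k_on_s = 16,
                      half_depth_um = 2, channel_offset_nm = c(0, 0, 0),
                      seed = 1L) {
  counts <- c(n_free, n_immobile, n_cobound, n_red_only)
  if (any(counts < 0)) stop("sim_truth: counts must be >= 0")
  if (D_free_um2_s < 0) stop("sim_truth: D_free must be >= 0")
  if (!is.null(k_off_s) && k_off_s < 0) stop("sim_truth: negative rate")
  if (k_on_s < 0) stop("sim_truth: negative rate")
  n_green <- n_free + n_immobile + n_cobound
  structure(list(
    n_free = n_free, n_immobile = n_immobile, n_cobound = n_cobound,
    n_red_only = n_red_only, n_green = n_green,
    n_red = n_cobound + n_red_only,
    D_free_um2_s = D_free_um2_s, brightness = brightness,
    brightness_red = brightness_red, background = background,
    s_detector = s_detector, k_off_s = k_off_s, k_on_s = k_on_s,
    half_depth_um = half_depth_um,
    channel_offset_nm = channel_offset_nm, seed = as.integer(seed),
    phi = if (n_green > 0) (n_immobile + n_cobound) / n_green else NA_real_,
    psi = if (n_green > 0) n_cobound / n_green else NA_real_),
    class = "sim_truth")
}

#' Ground truth matching target concentrations and fractions
#'
#' Converts target total concentration `C_nM`, immobile fraction `phi` and
#' co-bound fraction `psi` into particle counts for a given nuclear layout,
#' using `C = N / (N_A * V)` with `V` the total nuclear volume. The red
#' channel is filled to the same total concentration as the green channel.
#'
#' @param C_nM target green-channel total concentration (nM).
#' @param phi target immobile fraction (co-bound particles included).
#' @param psi target co-bound fraction (must not exceed `phi`).
#' @param nuclei nuclear layout from [default_nuclei()].
#' @param geometry a [scan_geometry()].
#' @param ... passed to [sim_truth()].
#' @inheritParams sim_truth
#' @return A `sim_truth` with an added `C_tot_nM` field (the realized
#'   concentration after rounding counts).
#' @export
recovery_truth <- function(C_nM = 30, phi = 0.5, psi = 0.3,
                           nuclei, geometry, half_depth_um = 2, ...) {
  stopifnot(psi <= phi, phi <= 1)
  vol <- sum(pi * nuclei$r_um^2) * 2 * half_depth_um
  n <- round(C_nM * MOLEC_PER_UM3_PER_NM * vol)
  n_co <- round(psi * n)
  n_imm <- round(phi * n) - n_co
  tr <- sim_truth(n_free = n - n_imm - n_co, n_immobile = n_imm,
                  n_cobound = n_co, n_red_only = n - n_co,
                  half_depth_um = half_depth_um, ...)
  tr$C_tot_nM <- n / (MOLEC_PER_UM3_PER_NM * vol)
  tr$nuclear_volume_um3 <- vol
  tr
}

#' Disk-shaped nuclear layout
#'
#' Places `n` non-overlapping disk nuclei of the given radius on a regular
#' grid inside the field of view.
#'
#' @param geometry a [scan_geometry()].
#' @param n number of nuclei (>= 1).
#' @param radius_px nuclear radius in pixels.
#' @return data.frame with pixel and um center coordinates and radii.
#' @export
default_nuclei <- function(geometry, n = 4, radius_px = 60) {
  stopifnot(n >= 1)
  k <- ceiling(sqrt(n))
  rows <- ceiling(n / k)
  dr <- geometry$pixel_size_um
  cx <- cy <- numeric(n)
  for (i in seq_len(n)) {
    gx <- (i - 1) %% k
    gy <- (i - 1) %/% k
    cx[i] <- (gx + 0.5) * geometry$n_cols / k
    cy[i] <- (gy + 0.5) * geometry$n_rows / rows
  }
  nuc <- data.frame(cx_px = cx, cy_px = cy, r_px = radius_px,
                    cx_um = cx * dr, cy_um = cy * dr, r_um = radius_px * dr)
  check_nuclei(nuc)
  nuc
}

check_nuclei <- function(nuclei) {
  n <- nrow(nuclei)
  if (n > 1) {
    d <- as.matrix(stats::dist(nuclei[, c("cx_um", "cy_um")]))
    rs <- outer(nuclei$r_um, nuclei$r_um, "+")
    diag(d) <- Inf
    if (any(d < rs)) stop("overlapping nuclei are not supported")
  }
  invisible(nuclei)
}

#' Rasterize the true nuclear masks
#'
#' @param nuclei layout from [default_nuclei()].
#' @param geometry a [scan_geometry()].
#' @return integer label matrix (`n_rows` x `n_cols`), 0 outside nuclei.
#' @export
nuclei_mask <- function(nuclei, geometry) {
  lab <- matrix(0L, geometry$n_rows, geometry$n_cols)
  xs <- matrix(seq_len(geometry$n_cols) - 0.5, geometry$n_rows,
               geometry$n_cols, byrow = TRUE)
  ys <- matrix(seq_len(geometry$n_rows) - 0.5, geometry$n_rows,
               geometry$n_cols)
  for (i in seq_len(nrow(nuclei))) {
    inside <- (xs - nuclei$cx_px[i])^2 + (ys - nuclei$cy_px[i])^2 <=
      nuclei$r_px[i]^2
    lab[inside] <- i
  }
  lab
}

uniform_in_disk <- function(n, cx, cy, r) {
  th <- stats::runif(n, 0, 2 * pi)
  rad <- r * sqrt(stats::runif(n))
  cbind(cx + rad * cos(th), cy + rad * sin(th))
}

#' Brownian / two-state particle paths at line-time resolution
#'
#' Propagates particle positions once per scanned line (interval
#' `line_time_s`). Free particles take Gaussian steps with per-axis variance
#' `2 D dt`; bound particles hold their position. With positive exchange
#' rates, particles switch mobility as a two-state Markov process
#' (bound -> free with rate `k_off`, free -> bound with rate `k_on`).
#' Boundaries are periodic in x and y and reflecting in z.
#'
#' This explicit-path generator is the reference model for small problems;
#' [simulate_timeseries()] uses a streaming equivalent that never stores
#' full paths.
#'
#' @param n number of particles.
#' @param D diffusivity (um^2/s).
#' @param geometry a [scan_geometry()]; sets the update interval.
#' @param n_frames number of frames (>= 1); steps = `n_frames * n_rows`.
#' @param box_um c(Lx, Ly, Lz) extents in um; all positive.
#' @param k_on_s,k_off_s exchange rates (1/s, >= 0); both zero disables
#'   switching.
#' @param bound0 logical vector (recycled): initial mobility state.
#' @return list with `x`, `y`, `z` (`n` x `n_steps` matrices, um), `bound`
#'   (logical matrix), and `dt_s`.
#' @export
simulate_particle_paths <- function(n, D, geometry, n_frames, box_um,
                                    k_on_s = 0, k_off_s = 0,
                                    bound0 = FALSE) {
  if (any(box_um <= 0)) stop("box extents must be positive")
  if (k_on_s < 0 || k_off_s < 0) stop("negative exchange rates rejected")
  if (n_frames < 1) stop("n_frames must be >= 1")
  dt <- geometry$line_time_s
  n_steps <- n_frames * geometry$n_rows
  x <- matrix(0, n, n_steps); y <- matrix(0, n, n_steps)
  z <- matrix(0, n, n_steps)
  bound <- matrix(FALSE, n, n_steps)
  pos <- cbind(stats::runif(n, 0, box_um[1]), stats::runif(n, 0, box_um[2]),
               stats::runif(n, -box_um[3] / 2, box_um[3] / 2))
  state <- rep_len(as.logical(bound0), n)
  p_off <- 1 - exp(-k_off_s * dt)
  p_on <- 1 - exp(-k_on_s * dt)
  sd_step <- sqrt(2 * D * dt)
  for (s in seq_len(n_steps)) {
    if (p_off > 0 || p_on > 0) {
      u <- stats::runif(n)
      state <- ifelse(state, u >= p_off, u < p_on)
    }
    mob <- !state
    if (any(mob) && sd_step > 0) {
      nm <- sum(mob)
      pos[mob, 1] <- (pos[mob, 1] + stats::rnorm(nm, 0, sd_step)) %% box_um[1]
      pos[mob, 2] <- (pos[mob, 2] + stats::rnorm(nm, 0, sd_step)) %% box_um[2]
      zi <- pos[mob, 3] + stats::rnorm(nm, 0, sd_step)
      half <- box_um[3] / 2
      zi <- ifelse(zi > half, 2 * half - zi, ifelse(zi < -half,
                                                   -2 * half - zi, zi))
      pos[mob, 3] <- pmin(pmax(zi, -half), half)
    }
    x[, s] <- pos[, 1]; y[, s] <- pos[, 2]; z[, s] <- pos[, 3]
    bound[, s] <- state
  }
  list(x = x, y = y, z = z, bound = bound, dt_s = dt)
}

#' Apply the analog detector model
#'
#' Adds the constant background offset and Gaussian noise with variance
#' `s_detector * mean` (the linear shot-noise law of an analog
#' photodetector), then quantizes to non-negative 16-bit integers.
#'
#' @param clean noise-free photon-rate image (counts).
#' @param background constant offset b0 (counts).
#' @param s_detector detector S factor; 0 disables noise.
#' @return integer-valued matrix in `[0, 65535]`.
#' @export
apply_detector <- function(clean, background = 0, s_detector = 0) {
  img <- clean + background
  if (s_detector > 0)
    img <- img + stats::rnorm(length(img), 0, sqrt(s_detector * pmax(img, 0)))
  img <- round(img)
  img[img < 0] <- 0
  img[img > 65535] <- 65535
  img
}

#' Render one raster-scanned frame
#'
#' Pixel (i, j) integrates the Gaussian-PSF-weighted brightness of every
#' particle at the position it holds while line i is scanned. `positions`
#' may be a static `n x 3` matrix (columns x, y, z in um) or a list with
#' `x`, `y`, `z` matrices of size `n x n_rows` giving per-line positions.
#'
#' @param positions particle positions (um), static or per-line.
#' @param brightness per-particle brightness (counts per dwell), recycled.
#' @param geometry a [scan_geometry()].
#' @param psf a [psf_model()].
#' @param background,s_detector detector model, see [apply_detector()].
#' @param cutoff_um lateral support radius of the rendered PSF.
#' @return matrix of detector counts (`n_rows` x `n_cols`).
#' @export
render_raster_frame <- function(positions, brightness, geometry, psf,
                                background = 0, s_detector = 0,
                                cutoff_um = 2.5 * psf$w0_um) {
  if (is.matrix(positions)) {
    n <- nrow(positions)
    pxl <- matrix(positions[, 1], n, geometry$n_rows)
    pyl <- matrix(positions[, 2], n, geometry$n_rows)
    pzl <- matrix(positions[, 3], n, geometry$n_rows)
  } else {
    pxl <- positions$x; pyl <- positions$y; pzl <- positions$z
    n <- nrow(pxl)
    stopifnot(ncol(pxl) == geometry$n_rows)
  }
  if (n == 0) {
    clean <- matrix(0, geometry$n_rows, geometry$n_cols)
  } else {
    brightness <- rep_len(brightness, n)
    clean <- cpp_render_lines(pxl, pyl, pzl, brightness, geometry$n_rows,
                              geometry$n_cols, geometry$pixel_size_um,
                              psf$w0_um, psf$wz_um, cutoff_um)
  }
  apply_detector(clean, background, s_detector)
}

#' Simulate a two-channel raster-scan time series
#'
#' Generates a movie with known ground truth: free, quasi-immobile and
#' co-bound particles confined to disk nuclei, propagated line-by-line and
#' rendered through per-channel PSFs (the red channel displaced by the
#' configured channel offset), with analog detector noise.
#'
#' @param truth a [sim_truth()] (or [recovery_truth()]).
#' @param geometry a [scan_geometry()].
#' @param psf a [psf_pair()].
#' @param n_frames number of frames.
#' @param nuclei layout from [default_nuclei()].
#' @param seed RNG seed; defaults to `truth$seed`.
#' @param cycle nuclear-cycle metadata label attached to the movie.
#' @return list with `green` and `red` count arrays
#'   (`n_rows x n_cols x n_frames`), the rasterized `mask_truth`, and the
#'   `truth`, `nuclei`, `geometry`, `psf`, `cycle` used.
#' @export
simulate_timeseries <- function(truth, geometry, psf = psf_pair(),
                                n_frames = 30, nuclei = NULL,
                                seed = truth$seed, cycle = 13L) {
  if (is.null(nuclei)) nuclei <- default_nuclei(geometry)
  check_nuclei(nuclei)
  set.seed(seed)
  k_off <- if (is.null(truth$k_off_s)) 1 / geometry$frame_time_s else
    truth$k_off_s
  pools <- c(free = truth$n_free, imm = truth$n_immobile,
             co = truth$n_cobound, red = truth$n_red_only)
  n <- sum(pools)
  species <- rep(c(0L, 1L, 1L, 1L), pools)
  bright_g <- rep(c(truth$brightness, truth$brightness, truth$brightness, 0),
                  pools)
  bright_r <- rep(c(0, 0, truth$brightness_red, truth$brightness_red), pools)
  # round-robin nucleus assignment per pool keeps per-nucleus composition even
  nuc_idx <- unlist(lapply(pools, function(k)
    rep_len(seq_len(nrow(nuclei)), k)), use.names = FALSE)
  pos <- matrix(0, n, 3)
  for (i in seq_len(nrow(nuclei))) {
    sel <- which(nuc_idx == i)
    pos[sel, 1:2] <- uniform_in_disk(length(sel), nuclei$cx_um[i],
                                     nuclei$cy_um[i], nuclei$r_um[i])
  }
  half <- truth$half_depth_um
  pos[, 3] <- stats::runif(n, -half, half)
  step_sd <- sqrt(2 * truth$D_free_um2_s * geometry$line_time_s)
  p_jump <- 1 - exp(-k_off * geometry$line_time_s)
  off_r <- truth$channel_offset_nm / 1000
  nmat <- as.matrix(nuclei[, c("cx_um", "cy_um", "r_um")])
  green <- array(0, c(geometry$n_rows, geometry$n_cols, n_frames))
  red <- green
  px <- pos[, 1]; py <- pos[, 2]; pz <- pos[, 3]
  cutoff <- 2.5 * max(psf$green$w0_um, psf$red$w0_um)
  for (f in seq_len(n_frames)) {
    fr <- cpp_advance_render_frame(px, py, pz, species, nuc_idx - 1L,
                                   bright_g, bright_r, nmat, -half, half,
                                   step_sd, p_jump, geometry$n_rows,
                                   geometry$n_cols, geometry$pixel_size_um,
                                   psf$green$w0_um, psf$green$wz_um,
                                   psf$red$w0_um, psf$red$wz_um, off_r,
                                   cutoff)
    px <- fr$px; py <- fr$py; pz <- fr$pz
    green[, , f] <- apply_detector(fr$green, truth$background,
                                   truth$s_detector)
    red[, , f] <- apply_detector(fr$red, truth$background, truth$s_detector)
  }
  vol <- sum(pi * nuclei$r_um^2) * 2 * half
  truth$k_off_resolved_s <- k_off
  truth$nuclear_volume_um3 <- vol
  truth$C_tot_nM <- truth$n_green / (MOLEC_PER_UM3_PER_NM * vol)
  list(green = green, red = red, mask_truth = nuclei_mask(nuclei, geometry),
       truth = truth, nuclei = nuclei, geometry = geometry, psf = psf,
       cycle = cycle)
}

#' Simulate a two-channel bead z-stack for channel registration
#'
#' Each bead is rendered as a 3D Gaussian in both channels; the red channel
#' is displaced by `offset_nm`. Used to calibrate the inter-channel axial
#' displacement entering the ccRICS amplitude correction.
#'
#' @param offset_nm red-channel displacement c(dx, dy, dz) in nm.
#' @param psf a [psf_pair()].
#' @param z_step_um spacing between slices (um).
#' @param z_half_um half-extent of the stack; total range must cover at
#'   least 4 axial radii.
#' @param n_beads number of beads.
#' @param n_px lateral image size (pixels).
#' @param pixel_size_nm lateral pixel size (nm).
#' @param brightness peak bead intensity (counts).
#' @param background,s_detector detector model.
#' @param centers_um optional `n_beads x 2` matrix of bead centers (um);
#'   beads closer than `3 * w0` are rejected.
#' @param seed RNG seed for bead placement and noise.
#' @return list with `green`, `red` arrays (`n_px x n_px x n_z`), slice
#'   positions `z_um`, true `centers_um`, and the inputs.
#' @export
simulate_bead_stack <- function(offset_nm = c(0, 0, 100), psf = psf_pair(),
                                z_step_um = 0.05, z_half_um = 3.2,
                                n_beads = 5, n_px = 128,
                                pixel_size_nm = 31.95, brightness = 5000,
                                background = 100, s_detector = 4,
                                centers_um = NULL, seed = 1L) {
  wz_max <- max(psf$green$wz_um, psf$red$wz_um)
  if (2 * z_half_um < 4 * wz_max)
    stop("z range must cover at least 4 axial PSF radii")
  set.seed(seed)
  dr <- pixel_size_nm / 1000
  fov <- n_px * dr
  min_sep <- 3 * max(psf$green$w0_um, psf$red$w0_um)
  if (is.null(centers_um)) {
    centers_um <- matrix(NA_real_, n_beads, 2)
    margin <- 0.15 * fov
    for (i in seq_len(n_beads)) {
      repeat {
        cand <- stats::runif(2, margin, fov - margin)
        if (i == 1 || all(sqrt(colSums((t(centers_um[seq_len(i - 1), ,
          drop = FALSE]) - cand)^2)) >= min_sep)) break
      }
      centers_um[i, ] <- cand
    }
  } else {
    centers_um <- as.matrix(centers_um)
    if (nrow(centers_um) > 1) {
      d <- as.matrix(stats::dist(centers_um)); diag(d) <- Inf
      if (any(d < min_sep)) stop("beads closer than 3*w0 rejected")
    }
  }
  z_um <- seq(-z_half_um, z_half_um, by = z_step_um)
  zc <- stats::runif(n_beads, -0.3, 0.3)  # true axial centers near focus
  xs <- (seq_len(n_px) - 0.5) * dr
  render <- function(p, off) {
    arr <- array(0, c(n_px, n_px, length(z_um)))
    for (b in seq_len(n_beads)) {
      gx <- exp(-2 * (xs - centers_um[b, 1] - off[1])^2 / p$w0_um^2)
      gy <- exp(-2 * (xs - centers_um[b, 2] - off[2])^2 / p$w0_um^2)
      gz <- exp(-2 * (z_um - zc[b] - off[3])^2 / p$wz_um^2)
      for (k in which(gz > 1e-6))
        arr[, , k] <- arr[, , k] + brightness * gz[k] * outer(gy, gx)
    }
    arr
  }
  off_um <- offset_nm / 1000
  g <- render(psf$green, c(0, 0, 0))
  r <- render(psf$red, off_um)
  g[] <- apply_detector(g, background, s_detector)
  r[] <- apply_detector(r, background, s_detector)
  list(green = g, red = r, z_um = z_um, centers_um = centers_um,
       z_centers_um = zc, offset_nm = offset_nm, pixel_size_nm = pixel_size_nm,
       z_step_um = z_step_um, psf = psf)
}

#' Write a simulated movie to disk
#'
#' Writes one 16-bit multi-page TIFF per channel, a YAML sidecar with the
#' scan geometry, and a CSV with the ground truth.
#'
#' @param sim result of [simulate_timeseries()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_movie_tiff <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(green = file.path(dir, "green.tif"),
                red = file.path(dir, "red.tif"),
                geometry = file.path(dir, "geometry.yaml"),
                truth = file.path(dir, "truth.csv"))
  for (ch in c("green", "red")) {
    pages <- lapply(seq_len(dim(sim[[ch]])[3]),
                    function(f) sim[[ch]][, , f] / 65535)
    tiff::writeTIFF(pages, paths[[ch]], bits.per.sample = 16L)
  }
  yaml::write_yaml(unclass(sim$geometry), paths$geometry)
  tr <- sim$truth
  flat <- tr[vapply(tr, function(x) is.numeric(x) && length(x) == 1,
                    logical(1))]
  utils::write.csv(as.data.frame(flat), paths$truth, row.names = FALSE)
  invisible(paths)
}

#' Read a movie written by [write_movie_tiff()]
#'
#' @param dir directory containing `green.tif`, `red.tif`, `geometry.yaml`.
#' @return list with `green`, `red` count arrays and `geometry`.
#' @export
read_movie_tiff <- function(dir) {
  rd <- function(p) {
    pages <- tiff::readTIFF(p, all = TRUE)
    arr <- array(0, c(dim(pages[[1]]), length(pages)))
    for (f in seq_along(pages)) arr[, , f] <- round(pages[[f]] * 65535)
    arr
  }
  gy <- yaml::read_yaml(file.path(dir, "geometry.yaml"))
  geom <- scan_geometry(pixel_size_nm = gy$pixel_size_nm,
                        pixel_dwell_s = gy$pixel_dwell_s,
                        line_time_s = gy$line_time_s,
                        frame_time_s = gy$frame_time_s,
                        n_rows = gy$n_rows, n_cols = gy$n_cols)
  list(green = rd(file.path(dir, "green.tif")),
       red = rd(file.path(dir, "red.tif")), geometry = geom)
}
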