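# RICS / ccRICS model fitting: ACF kernels, two-step amplitude + mobility
# fits, cross-correlation fits, amplitude-to-concentration conversion and
# bead-stack channel registration.

#' Normalized RICS autocorrelation kernel
#'
#' The standard raster-scan ACF for a species of diffusivity `D`:
#' diffusion factors
#' `[1 + 4 D tau / w0^2]^-1 * [1 + 4 D tau / wz^2]^-1/2` with
#' `tau = |tau_p dx + tau_l dy|`, times the Gaussian scanning factor
#' `exp(-(dr^2 (dx^2 + dy^2) / w0^2) / (1 + 4 D tau / w0^2))`.
#' Normalized so the kernel equals 1 at zero lag. `D = 0` reduces to the
#' pure PSF Gaussian (the immobile kernel).
#'
#' @param dx,dy pixel lags (vectors of equal length, or matrices).
#' @param D diffusivity (um^2/s, >= 0).
#' @param geometry a [scan_geometry()].
#' @param psf a [psf_model()]; `w0_um` may be overridden via `w0`.
#' @param w0 lateral 1/e^2 radius (um) to use, default `psf$w0_um`.
#' @return kernel values with the shape of `dx`.
#' @export
rics_kernel <- function(dx, dy, D, geometry, psf, w0 = psf$w0_um) {
  stopifnot(D >= 0)
  tau <- abs(geometry$pixel_dwell_s * dx + geometry$line_time_s * dy)
  p <- 4 * D * tau
  f1 <- 1 / (1 + p / w0^2)
  f2 <- 1 / sqrt(1 + p / psf$wz_um^2)
  dr <- geometry$pixel_size_um
  f1 * f2 * exp(-(dr^2 * (dx^2 + dy^2) / w0^2) * f1)
}

#' RICS ACF model with amplitude and background
#'
#' `A * G_n(dx, dy) + B` with `G_n` the kernel of [rics_kernel()].
#'
#' @inheritParams rics_kernel
#' @param A amplitude (> 0).
#' @param B background constant.
#' @return model surface values.
#' @export
model_rics_acf <- function(dx, dy, A, D, geometry, psf, B = 0,
                           w0 = psf$w0_um) {
  stopifnot(A > 0)
  A * rics_kernel(dx, dy, D, geometry, psf, w0) + B
}

#' Two-component RICS model surface
#'
#' `A * [phi * G_imm + (1 - phi) * G_dif(D)] + B`, the linear combination
#' of an immobile (D = 0) and a freely diffusing component.
#'
#' @inheritParams model_rics_acf
#' @param phi immobile fraction in `[0, 1]`.
#' @export
model_rics_two_component <- function(dx, dy, A, D, phi, geometry, psf,
                                     B = 0, w0 = psf$w0_um) {
  g_imm <- rics_kernel(dx, dy, 0, geometry, psf, w0)
  g_dif <- rics_kernel(dx, dy, D, geometry, psf, w0)
  A * (phi * g_imm + (1 - phi) * g_dif) + B
}

surface_long <- function(surface, drop_zero = TRUE) {
  dxm <- matrix(surface$dx, length(surface$dy), length(surface$dx),
                byrow = TRUE)
  dym <- matrix(surface$dy, length(surface$dy), length(surface$dx))
  keep <- !is.na(surface$values)
  if (drop_zero) keep <- keep & !(dxm == 0 & dym == 0)
  data.frame(dx = dxm[keep], dy = dym[keep], g = surface$values[keep])
}

# robust noise floor from the outer lag bins of a surface
surface_noise_floor <- function(surface, frac = 0.75) {
  dxm <- matrix(surface$dx, length(surface$dy), length(surface$dx),
                byrow = TRUE)
  dym <- matrix(surface$dy, length(surface$dy), length(surface$dx))
  rmax <- max(abs(surface$dx))
  outer_bins <- sqrt(dxm^2 + dym^2) > frac * rmax
  v <- surface$values[outer_bins]
  stats::sd(v[!is.na(v)])
}

#' Fast-axis Gaussian fit of the ACF amplitude
#'
#' First step of the two-step RICS fit: least-squares fit of
#' `A * exp(-dr^2 dx^2 / w0^2) + B` to the fast-axis cut `G(dx, 0)` with
#' the zero-lag bin excluded (it is dominated by shot noise). `B` is
#' constrained to `|B| < B_max` and `w0` may vary within `w0_tol` of the
#' configured PSF radius. The fit is flagged when it fails to converge or
#' when the recovered amplitude is indistinguishable from the surface's
#' noise floor.
#'
#' @param surface a `correlation_surface` (auto pair).
#' @param psf a [psf_model()].
#' @param geometry a [scan_geometry()]; defaults to the surface's.
#' @param B_max background constraint (default 1e-3).
#' @param w0_tol relative w0 adjustment allowed (default 0.3).
#' @return list with `A`, `B`, `w0_adj_um`, `resid_norm`, `noise_floor`,
#'   `converged`, `flagged`.
#' @export
fit_fast_axis <- function(surface, psf, geometry = surface$geometry,
                          B_max = 1e-3, w0_tol = 0.3) {
  iy <- which(surface$dy == 0)
  g <- surface$values[iy, ]
  keep <- !is.na(g) & surface$dx != 0
  if (sum(keep) < 15) stop("need >= 15 non-missing fast-axis lags")
  dx <- surface$dx[keep]; g <- g[keep]
  dr <- geometry$pixel_size_um
  a0 <- max(mean(g[abs(dx) == 1]), 1e-6)
  fit <- minpack.lm::nls.lm(
    par = list(A = a0, B = 0, w0 = psf$w0_um),
    fn = function(p) g - (p$A * exp(-dr^2 * dx^2 / p$w0^2) + p$B),
    lower = c(1e-12, -B_max, (1 - w0_tol) * psf$w0_um),
    upper = c(Inf, B_max, (1 + w0_tol) * psf$w0_um),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  nf <- surface_noise_floor(surface)
  converged <- fit$info %in% 1:4
  A <- fit$par$A
  flagged <- !converged || A <= 0 || (is.finite(nf) && A < 3 * nf)
  list(A = A, B = fit$par$B, w0_adj_um = fit$par$w0,
       resid_norm = sqrt(sum(fit$fvec^2)), noise_floor = nf,
       converged = converged, flagged = flagged)
}

multistart_grid <- function(n, lower, upper, log_scale) {
  # deterministic staggered grid across the box
  out <- matrix(NA_real_, n, length(lower))
  for (j in seq_along(lower)) {
    fr <- ((seq_len(n) - 0.5) / n + (j - 1) * 0.37) %% 1
    out[, j] <- if (log_scale[j])
      exp(log(lower[j]) + fr * (log(upper[j]) - log(lower[j])))
    else lower[j] + fr * (upper[j] - lower[j])
  }
  out
}

#' Two-component RICS fit (mobility step)
#'
#' Second step of the two-step fit: with the amplitude `A_fixed` held at
#' the fast-axis estimate, fits the full 2D surface with the linear
#' combination of an immobile and a diffusing kernel, yielding the
#' immobile fraction `phi` and the diffusivity `D`. Bounded least squares
#' with deterministic multistarts; the best residual wins and ties go to
#' the smallest `D`.
#'
#' @param surface a `correlation_surface` (auto pair); the zero-lag bin is
#'   excluded.
#' @param A_fixed amplitude from [fit_fast_axis()].
#' @param geometry a [scan_geometry()].
#' @param psf a [psf_model()].
#' @param w0 lateral radius used in the kernels (um); pass the adjusted
#'   value from the fast-axis fit.
#' @param D_bounds diffusivity bounds (um^2/s).
#' @param B_max background constraint.
#' @param n_starts number of multistarts.
#' @return list with `D`, `phi`, `B`, `ssr`, `converged`, `flagged`,
#'   `boundary` (TRUE when `phi` pinned at 0 or 1).
#' @export
fit_two_component <- function(surface, A_fixed, geometry = surface$geometry,
                              psf, w0 = psf$w0_um, D_bounds = c(0.01, 100),
                              B_max = 1e-3, n_starts = 8) {
  stopifnot(A_fixed > 0)
  d <- surface_long(surface, drop_zero = TRUE)
  g_imm <- rics_kernel(d$dx, d$dy, 0, geometry, psf, w0)
  resid <- function(p)
    d$g - (A_fixed * (p$phi * g_imm +
           (1 - p$phi) * rics_kernel(d$dx, d$dy, p$D, geometry, psf, w0)) +
           p$B)
  starts <- multistart_grid(n_starts, c(D_bounds[1], 0.05, 0),
                            c(D_bounds[2], 0.95, 0),
                            log_scale = c(TRUE, FALSE, FALSE))
  best <- NULL
  for (i in seq_len(n_starts)) {
    fit <- try(minpack.lm::nls.lm(
      par = list(D = starts[i, 1], phi = starts[i, 2], B = 0),
      fn = resid, lower = c(D_bounds[1], 0, -B_max),
      upper = c(D_bounds[2], 1, B_max),
      control = minpack.lm::nls.lm.control(maxiter = 300)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best$ssr * (1 - 1e-9) ||
        (abs(ssr - best$ssr) <= 1e-9 * max(ssr, 1e-300) &&
         fit$par$D < best$par$D)) {
      best <- list(par = fit$par, ssr = ssr, info = fit$info)
    }
  }
  if (is.null(best)) return(list(D = NA_real_, phi = NA_real_, B = NA_real_,
                                 ssr = NA_real_, converged = FALSE,
                                 flagged = TRUE, boundary = FALSE))
  boundary <- best$par$phi <= 1e-6 || best$par$phi >= 1 - 1e-6
  if (boundary)
    warning("two-component fit: phi pinned at a boundary")
  list(D = best$par$D, phi = best$par$phi, B = best$par$B, ssr = best$ssr,
       converged = best$info %in% 1:4, flagged = !(best$info %in% 1:4),
       boundary = boundary)
}

#' Cross-correlation (ccRICS) surface fit
#'
#' Fits the displaced immobile-kernel cross model
#' `A_cc * exp(-((dr dx - dx0)^2 + (dr dy - dy0)^2) / w0_avg^2) + B`
#' with `w0_avg^2 = (w0_g^2 + w0_r^2) / 2` to the full cross surface
#' (zero lag included; the two detector channels have independent shot
#' noise). The lateral PSF displacements `dx0`, `dy0` are free parameters;
#' the axial displacement enters through the multiplicative
#' `axial_factor` from [axial_displacement_factor()]. A fitted amplitude
#' below 3x the surface noise floor is reported as 0 (no detectable
#' co-binding). A slowly diffusing cross term can be enabled with
#' `cross_D`.
#'
#' @param surface a `correlation_surface` with pair `"gc"`.
#' @param psf_green,psf_red per-channel [psf_model()]s.
#' @param geometry a [scan_geometry()].
#' @param axial_factor amplitude correction for the axial PSF displacement.
#' @param max_disp_px bound on the fitted lateral displacements (pixels).
#' @param B_max background constraint.
#' @param n_starts number of multistarts.
#' @param cross_D optional diffusivity of the co-bound species; `NULL`
#'   (default) uses the immobile kernel, as the co-bound pool is
#'   chromatin-associated.
#' @return list with `A_cc`, `A_cc_corrected`, `dx0_nm`, `dy0_nm`, `B`,
#'   `noise_floor`, `detected`, `converged`.
#' @export
fit_ccf <- function(surface, psf_green, psf_red,
                    geometry = surface$geometry, axial_factor = 1,
                    max_disp_px = 10, B_max = 1e-3, n_starts = 8,
                    cross_D = NULL) {
  d <- surface_long(surface, drop_zero = FALSE)
  dr <- geometry$pixel_size_um
  w0a <- sqrt((psf_green$w0_um^2 + psf_red$w0_um^2) / 2)
  psf_avg <- psf_model(w0a, sqrt((psf_green$wz_um^2 + psf_red$wz_um^2) / 2),
                       psf_green$gamma)
  dmax <- max_disp_px * dr
  kern <- function(p) {
    if (is.null(cross_D))
      exp(-((dr * d$dx - p$dx0)^2 + (dr * d$dy - p$dy0)^2) / w0a^2)
    else {
      tau <- abs(geometry$pixel_dwell_s * d$dx + geometry$line_time_s * d$dy)
      f1 <- 1 / (1 + 4 * cross_D * tau / w0a^2)
      f2 <- 1 / sqrt(1 + 4 * cross_D * tau / psf_avg$wz_um^2)
      f1 * f2 * exp(-((dr * d$dx - p$dx0)^2 + (dr * d$dy - p$dy0)^2) /
                      w0a^2 * f1)
    }
  }
  resid <- function(p) d$g - (p$A * kern(p) + p$B)
  imax <- which.max(d$g)
  starts <- rbind(c(max(d$g[imax], 1e-6), dr * d$dx[imax], dr * d$dy[imax]),
                  c(max(max(d$g), 1e-6), 0, 0))
  extra <- multistart_grid(max(0, n_starts - 2), c(1e-5, -dmax / 2, -dmax / 2),
                           c(0.5, dmax / 2, dmax / 2), c(TRUE, FALSE, FALSE))
  starts <- rbind(starts, extra)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- try(minpack.lm::nls.lm(
      par = list(A = starts[i, 1], dx0 = starts[i, 2], dy0 = starts[i, 3],
                 B = 0),
      fn = resid, lower = c(0, -dmax, -dmax, -B_max),
      upper = c(Inf, dmax, dmax, B_max),
      control = minpack.lm::nls.lm.control(maxiter = 300)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best$ssr) best <- list(par = fit$par,
                                                      ssr = ssr,
                                                      info = fit$info)
  }
  if (is.null(best)) return(list(A_cc = NA_real_, A_cc_corrected = NA_real_,
                                 dx0_nm = NA_real_, dy0_nm = NA_real_,
                                 B = NA_real_, noise_floor = NA_real_,
                                 detected = FALSE, converged = FALSE))
  nf <- surface_noise_floor(surface)
  A_cc <- best$par$A
  detected <- is.finite(nf) && A_cc >= 3 * nf
  if (!detected) A_cc <- 0
  list(A_cc = A_cc, A_cc_corrected = A_cc * axial_factor,
       dx0_nm = best$par$dx0 * 1000, dy0_nm = best$par$dy0 * 1000,
       B = best$par$B, noise_floor = nf, detected = detected,
       converged = best$info %in% 1:4)
}

#' Chromatin-correlated ("active") fraction
#'
#' `psi = A_cc / A_red`, the fraction of green-channel molecules whose
#' fluctuations co-vary with the red (chromatin) channel, clipped to
#' `[0, 1]`.
#'
#' @param A_cc_corrected cross amplitude, axial-factor corrected.
#' @param A_red red-channel autocorrelation amplitude (> 0); pass `NA` for
#'   a flagged red fit to propagate missingness.
#' @return psi in `[0, 1]`, or `NA`.
#' @export
compute_psi <- function(A_cc_corrected, A_red) {
  if (is.na(A_cc_corrected) || is.na(A_red) || A_red <= 0) return(NA_real_)
  min(max(A_cc_corrected / A_red, 0), 1)
}

#' Convert an ACF amplitude to molecule number and concentration
#'
#' `N = gamma / A` is the mean number of molecules in the
#' illumination-weighted sampling volume `integral(W) = gamma * V_PSF`
#' (`V_PSF = pi^{3/2} w0^2 wz`), so the concentration
#' `C = N / (N_A * gamma * V_PSF) = 1 / (A N_A V_PSF)` is independent of
#' the shape factor.
#'
#' @param A fitted ACF amplitude (> 0).
#' @param psf a [psf_model()].
#' @param gamma illumination shape factor, default `psf$gamma`.
#' @return list with `N` (molecules), `C_nM`, `V_psf_um3` and the sampling
#'   volume `V_samp_um3`.
#' @export
amplitude_to_concentration <- function(A, psf, gamma = psf$gamma) {
  stopifnot(A > 0)
  N <- gamma / A
  v_samp <- gamma * psf_volume(psf)
  list(N = N, C_nM = N / (MOLEC_PER_UM3_PER_NM * v_samp),
       V_psf_um3 = psf_volume(psf), V_samp_um3 = v_samp)
}

#' Axial-displacement amplitude factor
#'
#' Correction for the axial offset between the two channels' PSF centers:
#' `exp(2 dz0^2 / (wz_g^2 + wz_r^2))`, equal to 1 at zero offset and
#' monotonically increasing in `|dz0|`. Multiplies the fitted cross
#' amplitude before computing psi.
#'
#' @param dz0_um axial displacement (um).
#' @param wz_green,wz_red axial 1/e^2 radii (um, > 0).
#' @return factor >= 1.
#' @export
axial_displacement_factor <- function(dz0_um, wz_green, wz_red) {
  stopifnot(wz_green > 0, wz_red > 0)
  exp(2 * dz0_um^2 / (wz_green^2 + wz_red^2))
}

#' Assemble a per-time-point concentration pool record
#'
#' Converts the fitted amplitudes and fractions of one frame group into the
#' concentration pools: total (from the green amplitude), immobile
#' (`phi * C_tot`), active (`psi * C_tot`), inactive
#' (`(phi - psi) * C_tot`) and free (`(1 - phi) * C_tot`). When `psi`
#' exceeds `phi` the record is flagged and the inactive pool reported as 0
#' rather than negative.
#'
#' @param time_s group midpoint time (s).
#' @param cycle nuclear-cycle metadata label.
#' @param A_green,A_red,A_cc fitted amplitudes (`A_cc` axial-corrected).
#' @param phi immobile fraction from [fit_two_component()].
#' @param D_um2_s fitted diffusivity.
#' @param psf green-channel [psf_model()].
#' @param gamma illumination shape factor.
#' @param flags character vector of upstream flags.
#' @return one-row data.frame (a PoolRecord).
#' @export
pool_record <- function(time_s, cycle, A_green, A_red, A_cc, phi, D_um2_s,
                        psf, gamma = psf$gamma, flags = character()) {
  psi <- compute_psi(A_cc, A_red)
  conv <- amplitude_to_concentration(A_green, psf, gamma)
  C_tot <- conv$C_nM
  C_imm <- phi * C_tot
  C_act <- if (is.na(psi)) NA_real_ else psi * C_tot
  if (!is.na(psi) && psi > phi) {
    flags <- c(flags, "psi_gt_phi")
    C_ina <- 0
  } else C_ina <- C_imm - C_act
  data.frame(time_s = time_s, cycle = cycle, A_green = A_green,
             A_red = A_red, A_cc = A_cc, phi = phi, psi = psi,
             N_psf = conv$N, C_tot_nM = C_tot,
             C_free_nM = (1 - phi) * C_tot, C_immobile_nM = C_imm,
             C_active_nM = C_act, C_inactive_nM = C_ina,
             D_um2_s = D_um2_s,
             flags = paste(flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

fit_one_bead <- function(sub, xs, ys, zs) {
  z0i <- which.max(apply(sub, 3, max))
  pl <- sub[, , z0i]
  tot <- sum(pl)
  cx <- sum(outer(rep(1, length(ys)), xs) * pl) / tot
  cy <- sum(outer(ys, rep(1, length(xs))) * pl) / tot
  off0 <- min(sub)
  amp0 <- max(sub) - off0
  grid <- expand.grid(y = ys, x = xs, z = zs)
  v <- as.numeric(sub)
  fit <- minpack.lm::nls.lm(
    par = list(amp = amp0, x0 = cx, y0 = cy, z0 = zs[z0i],
               w0 = diff(range(xs)) / 4, wz = diff(range(zs)) / 6,
               off = off0),
    fn = function(p) v - (p$off + p$amp *
      exp(-2 * ((grid$x - p$x0)^2 + (grid$y - p$y0)^2) / p$w0^2 -
            2 * (grid$z - p$z0)^2 / p$wz^2)),
    lower = c(0, min(xs), min(ys), min(zs), 1e-3, 1e-3, -Inf),
    upper = c(Inf, max(xs), max(ys), max(zs), diff(range(xs)),
              diff(range(zs)), Inf),
    control = minpack.lm::nls.lm.control(maxiter = 300))
  if (!(fit$info %in% 1:4)) return(NULL)
  with(fit$par, list(x = x0, y = y0, z = z0, w0 = w0, wz = wz,
                     fwhm_z = wz * sqrt(2 * log(2))))
}

#' Fit 3D Gaussians to a two-channel bead z-stack
#'
#' Detects beads in the z-averaged image, fits a 3D Gaussian to each bead
#' in each channel (initialized from the centroid and the
#' highest-intensity z plane), and reports per-bead center differences,
#' per-channel axial FWHM, and the aggregate axial displacement `dz0`
#' (mean over beads after dropping >3 MAD outliers).
#'
#' @param stack list with `green`, `red` arrays, `z_um`, `pixel_size_nm`
#'   (as produced by [simulate_bead_stack()]).
#' @param crop_px half-width of the per-bead lateral crop (pixels).
#' @param min_beads minimum number of detected beads (default 3).
#' @return list with `beads` (per-bead data.frame of centers, differences
#'   and FWHM), aggregates `dz0_um`, `dx0_um`, `dy0_um` and
#'   `fwhm_z_green_um`, `fwhm_z_red_um`.
#' @export
fit_bead_3d <- function(stack, crop_px = 10, min_beads = 3) {
  dr <- stack$pixel_size_nm / 1000
  zproj <- apply(stack$green, c(1, 2), mean)
  thr <- mean(zproj) + 4 * stats::sd(zproj)
  lab <- EBImage::bwlabel(EBImage::Image(zproj > thr))
  lab <- EBImage::imageData(lab)
  ids <- setdiff(sort(unique(as.integer(lab))), 0L)
  if (length(ids) < min_beads)
    stop(sprintf("detected %d beads; need >= %d", length(ids), min_beads))
  nr <- nrow(zproj); nc <- ncol(zproj)
  rows <- list()
  for (id in ids) {
    w <- which(lab == id, arr.ind = TRUE)
    ci <- round(colMeans(w))
    r1 <- max(1, ci[1] - crop_px):min(nr, ci[1] + crop_px)
    c1 <- max(1, ci[2] - crop_px):min(nc, ci[2] + crop_px)
    ys <- (r1 - 0.5) * dr
    xs <- (c1 - 0.5) * dr
    fg <- fit_one_bead(stack$green[r1, c1, , drop = FALSE], xs, ys,
                       stack$z_um)
    fr <- fit_one_bead(stack$red[r1, c1, , drop = FALSE], xs, ys,
                       stack$z_um)
    if (is.null(fg) || is.null(fr)) next  # divergent fit: bead dropped
    rows[[length(rows) + 1]] <- data.frame(
      bead = id, x_g = fg$x, y_g = fg$y, z_g = fg$z,
      x_r = fr$x, y_r = fr$y, z_r = fr$z,
      dx_um = fr$x - fg$x, dy_um = fr$y - fg$y, dz_um = fr$z - fg$z,
      fwhm_z_g = fg$fwhm_z, fwhm_z_r = fr$fwhm_z)
  }
  beads <- do.call(rbind, rows)
  if (is.null(beads) || nrow(beads) < min_beads)
    stop("too few beads survived fitting")
  robust_mean <- function(x) {
    md <- stats::median(x); s <- stats::mad(x)
    keep <- if (s > 0) abs(x - md) <= 3 * s else rep(TRUE, length(x))
    mean(x[keep])
  }
  list(beads = beads,
       dx0_um = robust_mean(beads$dx_um),
       dy0_um = robust_mean(beads$dy_um),
       dz0_um = robust_mean(beads$dz_um),
       fwhm_z_green_um = robust_mean(beads$fwhm_z_g),
       fwhm_z_red_um = robust_mean(beads$fwhm_z_r))
}
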