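# Apparent and molecular brightness, detector S factor, and brightness-based
# corrections of the ACF amplitude and immobile fraction.

#' Apparent brightness of the nuclear particles
#'
#' `B_app = (sigma^2 - sigma0^2) / I` where `sigma^2` is the variance of
#' the nuclear pixel intensities, `sigma0^2` the variance of the
#' lowest-intensity (background) pixels, and `I` the mean nuclear
#' intensity.
#'
#' @param I mean nuclear intensity (> 0).
#' @param var nuclear pixel variance.
#' @param var0 zero-intensity (background) variance.
#' @return apparent brightness (counts).
#' @export
apparent_brightness <- function(I, var, var0) {
  if (any(I <= 0)) stop("mean intensity must be positive")
  (var - var0) / I
}

#' Shot-noise variance
#'
#' The particle-fluctuation variance equals the RICS ACF amplitude times
#' the squared intensity, so the detector shot noise is
#' `sigma_shot^2 = sigma^2 - A * I^2`. A negative result indicates an
#' inconsistent amplitude/variance pair and is flagged with a warning.
#'
#' @param var nuclear pixel variance.
#' @param A ACF amplitude of the same group.
#' @param I mean nuclear intensity.
#' @return shot-noise variance (possibly negative, with a warning).
#' @export
shot_noise <- function(var, A, I) {
  out <- var - A * I^2
  if (any(out < 0))
    warning("negative shot-noise estimate: amplitude/variance inconsistency")
  out
}

#' Detector S factor from a shot-noise vs intensity regression
#'
#' Ordinary least-squares line `sigma_shot^2 = S * I + b`; the slope is
#' the analog-detector S factor and the intercept `b` is a free parameter
#' kept for robustness (it absorbs, e.g., offset-driven noise).
#'
#' @param shot shot-noise variances (>= 10 points).
#' @param I mean intensities spanning at least a ~2-fold range.
#' @return list with `S`, `b` and the `lm` fit.
#' @export
estimate_s_factor <- function(shot, I) {
  stopifnot(length(shot) == length(I))
  if (length(I) < 10) stop("need >= 10 time points")
  if (min(I) <= 0 || max(I) / min(I) < 1.05)
    stop("degenerate intensity range")
  if (max(I) / min(I) < 2)
    warning("intensity range below 2-fold; S estimate may be unstable")
  fit <- stats::lm(shot ~ I)
  list(S = unname(stats::coef(fit)[2]), b = unname(stats::coef(fit)[1]),
       fit = fit)
}

#' Molecular brightness
#'
#' Converts apparent brightness to molecular brightness for an analog
#' detector: `Q = (B_app - S) / S`, clipped at 0.
#'
#' @param B_app apparent brightness.
#' @param S detector S factor (> 0).
#' @return molecular brightness `Q >= 0`.
#' @export
molecular_brightness <- function(B_app, S) {
  stopifnot(S > 0)
  pmax((B_app - S) / S, 0)
}

#' Normalized brightness trace q(t)
#'
#' `q(t) = Q(t) / Q_min` with `Q_min` the maximum molecular brightness
#' observed inside a designated reference window (within the reference
#' window brightness variation is treated as constant, so no correction is
#' applied there); values below 1 are set to 1.
#'
#' @param Q molecular-brightness trace.
#' @param ref_idx indices of the reference window.
#' @return list with `q` (>= 1 everywhere) and `Q_min`.
#' @export
normalize_brightness <- function(Q, ref_idx) {
  stopifnot(length(ref_idx) >= 1, all(ref_idx %in% seq_along(Q)))
  Q_min <- max(Q[ref_idx])
  if (Q_min <= 0) stop("reference window has non-positive brightness")
  list(q = pmax(Q / Q_min, 1), Q_min = Q_min)
}

#' Brightness correction of amplitude and immobile fraction
#'
#' When particles brighten (q > 1), the apparent amplitude and immobile
#' fraction overcount molecules; corrected values are obtained by dividing
#' by q: `A_new = A_old / q`, `phi_new = phi_old / q`. `q = 1` is the
#' identity, and larger q never increases either output.
#'
#' @param q normalized brightness (>= 1).
#' @param A_old,phi_old uncorrected amplitude and immobile fraction.
#' @return list with `A_new` and `phi_new`.
#' @export
brightness_correction <- function(q, A_old, phi_old) {
  if (any(q < 1)) stop("q must be >= 1 (clip before correcting)")
  list(A_new = A_old / q, phi_new = phi_old / q)
}

#' Per-group brightness record
#'
#' Computes the brightness quantities of one preprocessed frame group:
#' mean nuclear intensity and pixel variance pooled over the background-
#' subtracted member frames, the single-frame background-mode variance as
#' the zero-intensity variance, and the apparent brightness.
#'
#' `var_fluct` is the temporal fluctuation variance: the variance of the
#' nuclear pixels after subtracting the group-average frame, rescaled by
#' `n / (n - 1)` so it is unbiased for temporally white fluctuations. It
#' excludes static spatial structure (nuclear-edge gradients, immobile
#' texture) that inflates the raw variance, and is the quantity to pair
#' with a detrend-attenuated ACF amplitude (`A * n / (n - 1)`) when
#' isolating detector shot noise.
#'
#' @param group a `frame_group`.
#' @param channel `"green"` or `"red"`.
#' @return one-row data.frame with `time_s`, `cycle`, `I`, `var`,
#'   `var_fluct`, `var0`, `n_members`, `B_app`.
#' @export
group_brightness <- function(group, channel = "green") {
  ch <- group[[channel]]
  mk <- group$mask > 0
  if (!any(mk)) stop("empty mask")
  avg0 <- ch$avg  # background-subtracted
  n <- length(ch$detrended)
  # raw (bg-subtracted, non-detrended) members: invert the detrend
  raw <- lapply(ch$detrended, function(f) f + avg0 - ch$mean)
  px <- unlist(lapply(raw, function(f) f[mk]))
  I <- mean(px)
  v <- stats::var(px)
  vf <- mean(vapply(raw, function(f) stats::var((f - avg0)[mk]),
                    numeric(1))) * n / (n - 1)
  var0 <- ch$var0
  data.frame(time_s = group$time_s, cycle = group$cycle, I = I, var = v,
             var_fluct = vf, var0 = var0, n_members = n,
             B_app = apparent_brightness(I, v, var0))
}
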