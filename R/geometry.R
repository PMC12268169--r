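# Scan geometry and PSF models shared by the simulator and the fitters.

# molecules per um^3 per nM (N_A * 1e-9 mol/L / 1e15 um^3/L)
MOLEC_PER_UM3_PER_NM <- 0.602214076

#' Raster-scan geometry
#'
#' Describes the timing and sampling of a confocal raster scan: pixel size,
#' pixel dwell time, line period and frame period. These set the two time
#' axes of the RICS correlation surface: adjacent pixels along the fast
#' (x) axis are `pixel_dwell_s` apart, adjacent lines along the slow (y)
#' axis are `line_time_s` apart.
#'
#' If `line_time_s` is missing it is derived from the frame period as
#' `frame_time_s / n_rows` (the scanner spends one line period per image
#' row); if `frame_time_s` is missing it is `n_rows * line_time_s`.
#'
#' @param pixel_size_nm pixel size in nm (default 31.95, a 1024x1024 field
#'   at 5x zoom on a typical point-scanning confocal).
#' @param pixel_dwell_s pixel dwell time in seconds (default 2.06e-6).
#' @param line_time_s line period in seconds, or `NULL` to derive it.
#' @param frame_time_s frame period in seconds, or `NULL` to derive it.
#' @param n_rows,n_cols image size in pixels.
#' @return A `scan_geometry` list with fields `pixel_size_nm`,
#'   `pixel_size_um`, `pixel_dwell_s`, `line_time_s`, `frame_time_s`,
#'   `n_rows`, `n_cols`.
#' @export
#' @examples
#' g <- scan_geometry(frame_time_s = 5.06, n_rows = 1024, n_cols = 1024)
#' g$line_time_s # ~5 ms
scan_geometry <- function(pixel_size_nm = 31.95, pixel_dwell_s = 2.06e-6,
                          line_time_s = NULL, frame_time_s = NULL,
                          n_rows = 1024L, n_cols = 1024L) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (is.null(line_time_s) && is.null(frame_time_s))
    frame_time_s <- 5.06
  if (is.null(line_time_s))
    line_time_s <- frame_time_s / n_rows
  if (is.null(frame_time_s))
    frame_time_s <- n_rows * line_time_s
  g <- structure(list(pixel_size_nm = pixel_size_nm,
                      pixel_size_um = pixel_size_nm / 1000,
                      pixel_dwell_s = pixel_dwell_s,
                      line_time_s = line_time_s,
                      frame_time_s = frame_time_s,
                      n_rows = n_rows, n_cols = n_cols),
                 class = "scan_geometry")
  validate_scan_geometry(g)
  g
}

validate_scan_geometry <- function(g) {
  with(g, {
    if (any(c(pixel_size_nm, pixel_dwell_s, line_time_s, frame_time_s,
              n_rows, n_cols) <= 0))
      stop("scan_geometry: all fields must be positive")
    if (line_time_s < n_cols * pixel_dwell_s)
      stop("scan_geometry: line_time_s must be >= n_cols * pixel_dwell_s")
    if (frame_time_s < 0.99 * n_rows * line_time_s)
      stop("scan_geometry: frame_time_s shorter than the scanned lines allow")
  })
  invisible(g)
}

#' Line period implied by a frame period
#'
#' The line period of a raster scan is the frame period divided by the
#' number of image rows (any retrace time is folded in).
#'
#' @param frame_time_s frame period in seconds.
#' @param n_rows number of image rows.
#' @return line period in seconds.
#' @export
line_time_from_frame <- function(frame_time_s, n_rows) {
  stopifnot(frame_time_s > 0, n_rows >= 1)
  frame_time_s / n_rows
}

#' 3D Gaussian point-spread-function model
#'
#' The detection profile is modeled as
#' `W(r) = exp(-2 (x^2 + y^2) / w0^2 - 2 z^2 / wz^2)` with lateral 1/e^2
#' radius `w0` and axial 1/e^2 radius `wz`. `gamma` is the illumination
#' shape factor relating the fitted correlation amplitude to the mean
#' molecule number (`2^-3/2` for a 3D Gaussian).
#'
#' @param w0_um lateral 1/e^2 radius in um.
#' @param wz_um axial 1/e^2 radius in um (must exceed `w0_um`).
#' @param gamma illumination shape factor in (0, 1].
#' @return A `psf_model` list.
#' @export
psf_model <- function(w0_um = 0.25, wz_um = 1.5, gamma = 2^-1.5) {
  if (!(w0_um > 0 && wz_um > w0_um)) stop("psf_model: need 0 < w0 < wz")
  if (!(gamma > 0 && gamma <= 1)) stop("psf_model: need 0 < gamma <= 1")
  structure(list(w0_um = w0_um, wz_um = wz_um, gamma = gamma),
            class = "psf_model")
}

#' Green/red PSF pair
#'
#' Convenience constructor for the per-channel PSF variants used by the
#' cross-correlation model. The default uses matched channels: with
#' matched effective volumes the amplitude ratio `A_cc / A_red` equals the
#' co-moving fraction exactly, with no PSF-volume correction. Pass a
#' larger red PSF to emulate the chromatic mismatch of a real instrument.
#'
#' @param green,red `psf_model` objects.
#' @return list with elements `green` and `red`.
#' @export
psf_pair <- function(green = psf_model(), red = green) {
  stopifnot(inherits(green, "psf_model"), inherits(red, "psf_model"))
  list(green = green, red = red)
}

#' Effective PSF volumes
#'
#' `psf_volume()` returns the conventional confocal volume
#' `V_PSF = pi^{3/2} w0^2 wz`; `psf_sampling_volume()` returns the
#' illumination-weighted volume `integral(W) = (pi/2)^{3/2} w0^2 wz
#' = gamma * V_PSF`, the volume in which `gamma / A` molecules reside.
#'
#' @param psf a `psf_model`.
#' @return volume in um^3.
#' @export
psf_volume <- function(psf) pi^1.5 * psf$w0_um^2 * psf$wz_um

#' @rdname psf_volume
#' @export
psf_sampling_volume <- function(psf) (pi / 2)^1.5 * psf$w0_um^2 * psf$wz_um
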