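# 2D spatial auto- and cross-correlation of masked, detrended frames.
#
# The masked estimator correlates fluctuation images restricted to the
# nuclear mask and normalizes every lag bin by the exact number of valid
# pixel pairs (the autocorrelation of the mask), so it equals the direct
# double-sum definition for arbitrarily shaped masks.

new_correlation_surface <- function(values, n_pairs, dx, dy, pair,
                                    n_frames = 1L, geometry = NULL) {
  structure(list(values = values, n_pairs = n_pairs, dx = dx, dy = dy,
                 pair = pair, n_frames = n_frames, geometry = geometry),
            class = "correlation_surface")
}

#' @export
print.correlation_surface <- function(x, ...) {
  cat(sprintf("correlation_surface [%s] %d x %d lags, %d frame(s)\n",
              x$pair, length(x$dy), length(x$dx), x$n_frames))
  invisible(x)
}

pad_dim <- function(n, max_lag) stats::nextn(n + max_lag + 1, c(2, 3, 5))

#' Masked spatial correlation of two frames (FFT estimator)
#'
#' Computes `G(dx, dy) = <dIa(x, y) dIb(x + dx, y + dy)> / (<Ia><Ib>)`
#' where the averages run only over pixel pairs with both members inside
#' the mask and `dI = I - <I>_mask`. Implemented with zero-padded FFTs of
#' the masked fluctuation images and of the mask itself (pairwise-count
#' normalization); identical to the direct-sum definition.
#'
#' @param frame_a,frame_b frames of equal shape (use the same frame twice
#'   for an autocorrelation).
#' @param mask logical or 0/1 matrix of the same shape; must be nonempty.
#' @param max_lag maximum lag L: dx in -L..L; dy in 0..L for auto pairs,
#'   -L..L for cross pairs.
#' @param pair tag: `"gg"`, `"rr"` (auto) or `"gc"` (cross).
#' @param min_pairs lag bins supported by fewer valid pixel pairs are set
#'   to missing.
#' @param geometry optional [scan_geometry()] carried on the result.
#' @return a `correlation_surface` (values matrix indexed `[dy, dx]`).
#' @export
masked_correlation_2d <- function(frame_a, frame_b, mask, max_lag = 32,
                                  pair = "gg", min_pairs = 100,
                                  geometry = NULL) {
  stopifnot(all(dim(frame_a) == dim(frame_b)),
            all(dim(frame_a) == dim(mask)))
  m <- (mask > 0) * 1
  if (sum(m) == 0) stop("mask is empty")
  auto <- pair != "gc"
  dxs <- -max_lag:max_lag
  dys <- if (auto) 0:max_lag else -max_lag:max_lag
  ma <- sum(frame_a * m) / sum(m)
  mb <- sum(frame_b * m) / sum(m)
  da <- (frame_a - ma) * m
  db <- (frame_b - mb) * m
  P1 <- pad_dim(nrow(m), max_lag)
  P2 <- pad_dim(ncol(m), max_lag)
  pad <- function(x) {
    out <- matrix(0, P1, P2)
    out[seq_len(nrow(x)), seq_len(ncol(x))] <- x
    out
  }
  Fa <- stats::fft(pad(da))
  Fb <- stats::fft(pad(db))
  Fm <- stats::fft(pad(m))
  num <- Re(stats::fft(Conj(Fa) * Fb, inverse = TRUE)) / (P1 * P2)
  cnt <- round(Re(stats::fft(Conj(Fm) * Fm, inverse = TRUE)) / (P1 * P2))
  ri <- (dys %% P1) + 1   # row shift = dy
  ci <- (dxs %% P2) + 1   # col shift = dx
  vals <- num[ri, ci, drop = FALSE]
  np <- cnt[ri, ci, drop = FALSE]
  G <- vals / np / (ma * mb)
  G[np < min_pairs] <- NA_real_
  new_correlation_surface(G, np, dxs, dys, pair, 1L, geometry)
}

#' Direct double-sum correlation (test oracle)
#'
#' Literal implementation of the masked correlation definition by explicit
#' summation over pixel pairs. Intended for small images only; it is the
#' independence oracle against which the FFT estimator is verified.
#'
#' @inheritParams masked_correlation_2d
#' @return a `correlation_surface`.
#' @export
direct_correlation_oracle <- function(frame_a, frame_b, mask, max_lag = 32,
                                      pair = "gg", min_pairs = 100) {
  stopifnot(nrow(frame_a) <= 64, ncol(frame_a) <= 64)
  m <- mask > 0
  if (sum(m) == 0) stop("mask is empty")
  auto <- pair != "gc"
  dxs <- -max_lag:max_lag
  dys <- if (auto) 0:max_lag else -max_lag:max_lag
  ma <- mean(frame_a[m]); mb <- mean(frame_b[m])
  da <- frame_a - ma; db <- frame_b - mb
  nr <- nrow(frame_a); nc <- ncol(frame_a)
  G <- matrix(NA_real_, length(dys), length(dxs))
  np <- matrix(0, length(dys), length(dxs))
  for (iy in seq_along(dys)) for (ix in seq_along(dxs)) {
    dy <- dys[iy]; dx <- dxs[ix]
    r1 <- max(1, 1 - dy):min(nr, nr - dy)
    c1 <- max(1, 1 - dx):min(nc, nc - dx)
    if (length(r1) == 0 || length(c1) == 0) next
    valid <- m[r1, c1, drop = FALSE] & m[r1 + dy, c1 + dx, drop = FALSE]
    n <- sum(valid)
    np[iy, ix] <- n
    if (n >= min_pairs) {
      s <- sum(da[r1, c1, drop = FALSE][valid] *
                 db[r1 + dy, c1 + dx, drop = FALSE][valid])
      G[iy, ix] <- s / n / (ma * mb)
    }
  }
  new_correlation_surface(G, np, dxs, dys, pair)
}

#' Subtract the far-lag baseline of a correlation surface
#'
#' Mean-centering over a finite nuclear mask biases every lag bin of the
#' masked correlation downward by roughly (total correlation mass) /
#' (mask area), a pedestal that is large for desk-scale masks and varies
#' slowly across the lag plane. This estimates the pedestal as the mean
#' over the far-lag annulus `max(|dx|, |dy|) >= r_min` — where the RICS
#' kernels carry under ~0.2% of their amplitude — and subtracts it.
#'
#' @param surface a `correlation_surface`.
#' @param r_min inner radius (pixels, Chebyshev) of the baseline annulus.
#' @return the surface with the baseline removed and recorded in the
#'   `baseline` attribute.
#' @export
subtract_surface_baseline <- function(surface, r_min = 24) {
  dxm <- matrix(surface$dx, length(surface$dy), length(surface$dx),
                byrow = TRUE)
  dym <- matrix(surface$dy, length(surface$dy), length(surface$dx))
  ann <- pmax(abs(dxm), abs(dym)) >= r_min
  if (!any(ann & !is.na(surface$values)))
    stop("no usable bins in the baseline annulus; increase max_lag")
  b <- mean(surface$values[ann], na.rm = TRUE)
  surface$values <- surface$values - b
  attr(surface, "baseline") <- b
  surface
}

#' Crop a correlation surface to a lag window
#'
#' @param surface a `correlation_surface`.
#' @param dx_max,dy_max window half-widths (pixels); `dy` keeps
#'   `[-dy_max, dy_max]` intersected with the surface's range.
#' @return the cropped surface.
#' @export
crop_surface <- function(surface, dx_max, dy_max) {
  kx <- abs(surface$dx) <= dx_max
  ky <- abs(surface$dy) <= dy_max
  new_correlation_surface(surface$values[ky, kx, drop = FALSE],
                          surface$n_pairs[ky, kx, drop = FALSE],
                          surface$dx[kx], surface$dy[ky], surface$pair,
                          surface$n_frames, surface$geometry)
}

#' Group-averaged correlation surface
#'
#' Computes the per-frame masked correlation for every labeled nuclear
#' region and every member frame of a group, and averages the surfaces
#' pointwise. Lag bins missing in every contributing surface stay missing.
#'
#' @param group a `frame_group` from [make_frame_groups()].
#' @param pair `"gg"`, `"rr"` or `"gc"` (green x red cross-correlation).
#' @param max_lag maximum pixel lag.
#' @param min_pairs per-surface missing-bin threshold.
#' @return a `correlation_surface` averaged over frames and nuclei, or
#'   `NULL` when the group mask is empty.
#' @export
average_group_correlation <- function(group, pair = c("gg", "rr", "gc"),
                                      max_lag = 32, min_pairs = 100) {
  pair <- match.arg(pair)
  labels <- setdiff(sort(unique(as.integer(group$mask))), 0L)
  if (length(labels) == 0) return(NULL)
  fa_list <- switch(pair, gg = group$green$detrended,
                    rr = group$red$detrended, gc = group$green$detrended)
  fb_list <- switch(pair, gg = group$green$detrended,
                    rr = group$red$detrended, gc = group$red$detrended)
  if (is.null(fa_list) || is.null(fb_list))
    stop("required channel missing from group")
  if (length(fa_list) < 7) stop("groups must have >= 7 member frames")
  acc <- NULL; cnt <- NULL; template <- NULL
  for (lab in labels) {
    mk <- group$mask == lab
    for (f in seq_along(fa_list)) {
      s <- masked_correlation_2d(fa_list[[f]], fb_list[[f]], mk, max_lag,
                                 pair, min_pairs, group$geometry)
      if (is.null(acc)) {
        acc <- matrix(0, nrow(s$values), ncol(s$values))
        cnt <- acc
        template <- s
      }
      ok <- !is.na(s$values)
      acc[ok] <- acc[ok] + s$values[ok]
      cnt <- cnt + ok
    }
  }
  vals <- acc / cnt
  vals[cnt == 0] <- NA_real_
  new_correlation_surface(vals, cnt, template$dx, template$dy, pair,
                          n_frames = length(fa_list) * length(labels),
                          geometry = group$geometry)
}
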