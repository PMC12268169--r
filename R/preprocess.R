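# Preprocessing: background subtraction, frame grouping, nuclear
# segmentation and moving-average detrending.

#' Estimate the detector background of an image
#'
#' Models the pixel histogram as a mixture of at most two Gaussian modes
#' and returns the center and width of the lowest-intensity mode — the
#' out-of-cell detector background of a confocal frame. Subtracting the
#' returned mean re-centers that mode at zero. A unimodal image is treated
#' as pure background when its histogram is symmetric (e.g. a constant
#' plus noise); a unimodal but strongly right-skewed image has no
#' resolvable background mode, is flagged, and falls back to the
#' 1st-percentile pixel value.
#'
#' @param image numeric matrix with at least 1000 pixels.
#' @param max_pixels histogram fit uses at most this many pixels
#'   (deterministic stride subsampling).
#' @return list with `mean`, `sd` (of the background mode), `flagged`
#'   (TRUE when the fallback was used) and `method`.
#' @export
estimate_background <- function(image, max_pixels = 20000) {
  v <- as.numeric(image)
  if (length(v) < 1000) stop("image must have >= 1000 pixels")
  if (max(v) == min(v))
    return(list(mean = v[1], sd = 0, flagged = FALSE, method = "constant"))
  if (length(v) > max_pixels)
    v <- v[seq(1, length(v), length.out = max_pixels)]
  fallback <- list(mean = unname(stats::quantile(v, 0.01)),
                   sd = stats::sd(v), flagged = TRUE, method = "percentile")
  fit <- try(suppressWarnings(
    Mclust(v, G = 1:2, modelNames = "V", verbose = FALSE)),
    silent = TRUE)
  if (inherits(fit, "try-error") || is.null(fit)) return(fallback)
  if (fit$G == 1) {
    skew <- (mean(v) - stats::median(v)) / stats::sd(v)
    if (skew > 0.3) return(fallback)  # bright unimodal: no background mode
    return(list(mean = unname(fit$parameters$mean[1]),
                sd = sqrt(fit$parameters$variance$sigmasq[1]),
                flagged = FALSE, method = "gaussian-mode"))
  }
  lo <- which.min(fit$parameters$mean)
  sig <- fit$parameters$variance$sigmasq
  if (length(sig) == 1) sig <- rep(sig, fit$G)
  list(mean = unname(fit$parameters$mean[lo]), sd = sqrt(sig[lo]),
       flagged = FALSE, method = "gaussian-mixture")
}

#' Partition movie frames into analysis groups
#'
#' Frames are divided into consecutive, non-overlapping groups of
#' `group_size` (default 10). A trailing remainder shorter than 7 frames is
#' topped up by borrowing frames from the preceding groups so that every
#' group stays within 7-12 members; if that is impossible the remainder is
#' merged into the final group.
#'
#' @param n_frames total number of frames (must be >= 7).
#' @param group_size nominal group size in 7..12.
#' @return list of integer index vectors, one per group.
#' @export
plan_frame_groups <- function(n_frames, group_size = 10) {
  stopifnot(group_size >= 7, group_size <= 12)
  if (n_frames < 7) stop("movies shorter than 7 frames are rejected")
  sizes <- rep(group_size, n_frames %/% group_size)
  rem <- n_frames %% group_size
  if (rem > 0) sizes <- c(sizes, rem)
  k <- length(sizes)
  while (k > 1 && sizes[k] < 7) {
    donor <- k - 1
    moved <- FALSE
    while (donor >= 1 && sizes[k] < 7) {
      if (sizes[donor] > 7) {
        sizes[donor] <- sizes[donor] - 1
        sizes[k] <- sizes[k] + 1
        moved <- TRUE
      } else donor <- donor - 1
    }
    if (sizes[k] < 7 && !moved) {   # cannot rebalance: merge into previous
      sizes[k - 1] <- sizes[k - 1] + sizes[k]
      sizes <- sizes[-k]
    }
    k <- length(sizes)
  }
  ends <- cumsum(sizes)
  mapply(function(a, b) a:b, ends - sizes + 1, ends, SIMPLIFY = FALSE)
}

#' Segment nuclei in a background-subtracted average frame
#'
#' Standard robust recipe: Gaussian smoothing, Otsu threshold, distance
#' transform, h-maxima-seeded watershed, then removal of small regions and
#' optional removal of border-touching regions. The returned mask is eroded
#' slightly to keep steep edge gradients out of the correlation analysis.
#'
#' @param avg_frame background-subtracted average frame.
#' @param smooth_sigma Gaussian smoothing sigma (pixels).
#' @param h_frac h-maxima depth as a fraction of the distance-map maximum.
#' @param min_area minimum region area (pixels).
#' @param erode_px radius of the final mask erosion (pixels, 0 disables).
#' @param discard_border drop regions touching the image border.
#' @return integer label matrix; 0 outside nuclei. Empty (all-zero) when no
#'   region is found, with a warning.
#' @export
segment_nuclei <- function(avg_frame, smooth_sigma = 2, h_frac = 0.1,
                           min_area = 500, erode_px = 2,
                           discard_border = FALSE) {
  rng <- range(avg_frame)
  if (diff(rng) == 0) {
    warning("blank frame: no nuclei found")
    return(matrix(0L, nrow(avg_frame), ncol(avg_frame)))
  }
  img <- EBImage::Image((avg_frame - rng[1]) / diff(rng))
  sm <- EBImage::gblur(img, sigma = smooth_sigma)
  thr <- EBImage::otsu(sm)
  bin <- sm > thr
  if (sum(bin) == 0) {
    warning("no foreground after thresholding")
    return(matrix(0L, nrow(avg_frame), ncol(avg_frame)))
  }
  dm <- EBImage::distmap(bin)
  lab <- EBImage::watershed(dm, tolerance = h_frac * max(dm), ext = 1)
  lab <- EBImage::imageData(lab)
  # drop small regions
  tab <- tabulate(lab[lab > 0])
  keep <- which(tab >= min_area)
  lab[!(lab %in% keep)] <- 0L
  if (discard_border && any(lab > 0)) {
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    lab[lab %in% setdiff(border, 0L)] <- 0L
  }
  if (erode_px > 0 && any(lab > 0)) {
    brush <- EBImage::makeBrush(2 * erode_px + 1, shape = "disc")
    er <- EBImage::erode(EBImage::Image(lab > 0), brush)
    lab[EBImage::imageData(er) == 0] <- 0L
  }
  if (!any(lab > 0)) warning("no nuclei found")
  # relabel 1..k
  ids <- sort(unique(lab[lab > 0]))
  out <- matrix(0L, nrow(lab), ncol(lab))
  for (i in seq_along(ids)) out[lab == ids[i]] <- i
  out
}

#' Remove quasi-static structure from the frames of a group
#'
#' Subtracts the group-average frame pixel-by-pixel from each member and
#' adds back the scalar mean intensity of the average frame, so that
#' slowly varying (immobile over the whole group) structure is removed
#' while the mean intensity is preserved. Fluctuations from species that
#' move or exchange within the group survive. When a nuclear mask is
#' supplied the added-back scalar is the mean over the mask — the mean the
#' correlation functions of the nuclear pixels are normalized by.
#'
#' @param frames list of member frames (matrices of equal shape).
#' @param avg_frame their pixelwise mean (computed if `NULL`).
#' @param mask optional mask restricting the scalar mean.
#' @return list of detrended frames.
#' @export
detrend_frames <- function(frames, avg_frame = NULL, mask = NULL) {
  if (is.null(avg_frame)) avg_frame <- Reduce(`+`, frames) / length(frames)
  m <- if (is.null(mask) || !any(mask > 0)) mean(avg_frame) else
    mean(avg_frame[mask > 0])
  lapply(frames, function(f) f - avg_frame + m)
}

#' Build preprocessed frame groups from a two-channel movie
#'
#' Runs the full preprocessing chain: frame grouping, per-group background
#' estimation on the average frame (applied to all members), nuclear
#' segmentation of the average frame of the chosen channel, and
#' moving-average detrending of the member frames.
#'
#' @param green,red count arrays (`rows x cols x frames`); `red` may be
#'   `NULL` for single-channel analyses.
#' @param geometry a [scan_geometry()].
#' @param group_size nominal frames per group (7-12).
#' @param segment_on channel used for segmentation (`"red"` is the
#'   chromatin marker and the default when present).
#' @param cycle nuclear-cycle metadata label(s), recycled across groups.
#' @param ... passed to [segment_nuclei()].
#' @return list of `frame_group` objects with members, background-subtracted
#'   average and detrended member frames per channel, scalar means, the
#'   nuclear label mask, midpoint time stamps and cycle labels.
#' @export
make_frame_groups <- function(green, red = NULL, geometry,
                              group_size = 10, segment_on = c("red", "green"),
                              cycle = NA, ...) {
  segment_on <- match.arg(segment_on)
  if (is.null(red)) segment_on <- "green"
  n_frames <- dim(green)[3]
  plan <- plan_frame_groups(n_frames, group_size)
  cycle <- rep_len(cycle, length(plan))
  out <- vector("list", length(plan))
  for (gi in seq_along(plan)) {
    idx <- plan[[gi]]
    grp <- list(members = idx,
                time_s = (mean(idx) - 0.5) * geometry$frame_time_s,
                cycle = cycle[gi], geometry = geometry)
    raw <- list()
    for (ch in c("green", "red")) {
      mov <- if (ch == "green") green else red
      if (is.null(mov)) next
      frames <- lapply(idx, function(f) mov[, , f])
      avg_raw <- Reduce(`+`, frames) / length(frames)
      bg <- estimate_background(avg_raw)
      # zero-intensity variance must come from a single frame: averaging
      # suppresses detector noise by the group size
      bg_frame <- estimate_background(frames[[1]])
      raw[[ch]] <- lapply(frames, function(f) f - bg$mean)
      grp[[ch]] <- list(avg = avg_raw - bg$mean, bg = bg,
                        var0 = bg_frame$sd^2)
    }
    grp$mask <- segment_nuclei(grp[[segment_on]]$avg, ...)
    if (!any(grp$mask > 0))
      warning(sprintf("group %d: empty mask, group will be skipped", gi))
    for (ch in names(raw)) {
      grp[[ch]]$mean <- if (any(grp$mask > 0))
        mean(grp[[ch]]$avg[grp$mask > 0]) else mean(grp[[ch]]$avg)
      grp[[ch]]$detrended <- detrend_frames(raw[[ch]], grp[[ch]]$avg,
                                            grp$mask)
    }
    out[[gi]] <- structure(grp, class = "frame_group")
  }
  out
}
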