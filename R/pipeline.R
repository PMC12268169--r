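# End-to-end orchestration: simulate (or load) -> preprocess -> correlate ->
# fit -> brightness -> optional binding fit, with reproducible seeding and
# provenance.

#' Analyze one preprocessed frame group
#'
#' Computes the gg, rr and gc correlation surfaces of a group, removes
#' their far-lag baselines ([subtract_surface_baseline()]), runs the
#' two-step ACF fit on the green channel, the amplitude fit on the red
#' channel and the cross fit, and assembles the concentration pool record
#' and the brightness record. The mobility (two-component) fit uses a
#' restricted lag window (`fit_window`): the diffusion information lives
#' in the first ~16 line lags while the far bins carry mostly residual
#' baseline structure.
#'
#' @param group a `frame_group` from [make_frame_groups()].
#' @param psf a [psf_pair()].
#' @param gamma illumination shape factor.
#' @param max_lag maximum pixel lag of the correlation surfaces.
#' @param axial_factor ccRICS axial displacement factor.
#' @param fit_window c(dx, dy) window for the two-component fit.
#' @param B_max_2d background bound of the 2D (two-component and cross)
#'   fits; the fast-axis fit keeps the tight 1e-3 constraint.
#' @param keep_surfaces attach the three surfaces to the result.
#' @return list with `record` (PoolRecord row), `brightness` row, fit
#'   details, or `NULL` when the group has an empty mask.
#' @export
analyze_group <- function(group, psf = psf_pair(), gamma = psf$green$gamma,
                          max_lag = 32, axial_factor = 1,
                          fit_window = c(24, 16), B_max_2d = 5e-3,
                          keep_surfaces = FALSE) {
  if (!any(group$mask > 0)) return(NULL)
  two_channel <- !is.null(group$red)
  s_gg <- subtract_surface_baseline(
    average_group_correlation(group, "gg", max_lag))
  fa_g <- fit_fast_axis(s_gg, psf$green, group$geometry)
  tc <- fit_two_component(crop_surface(s_gg, fit_window[1], fit_window[2]),
                          fa_g$A, group$geometry, psf$green,
                          w0 = fa_g$w0_adj_um, B_max = B_max_2d)
  flags <- character()
  if (fa_g$flagged) flags <- c(flags, "A_green_flagged")
  if (tc$flagged) flags <- c(flags, "two_component_flagged")
  if (tc$boundary) flags <- c(flags, "phi_boundary")
  A_red <- NA_real_; A_cc <- NA_real_; cc <- NULL; fa_r <- NULL
  if (two_channel) {
    s_rr <- subtract_surface_baseline(
      average_group_correlation(group, "rr", max_lag))
    fa_r <- fit_fast_axis(s_rr, psf$red, group$geometry)
    A_red <- if (fa_r$flagged) NA_real_ else fa_r$A
    if (fa_r$flagged) flags <- c(flags, "A_red_flagged")
    s_gc <- subtract_surface_baseline(
      average_group_correlation(group, "gc", max_lag))
    cc <- fit_ccf(s_gc, psf$green, psf$red, group$geometry, axial_factor,
                  B_max = B_max_2d)
    A_cc <- cc$A_cc_corrected
  }
  rec <- pool_record(group$time_s, group$cycle, fa_g$A, A_red, A_cc,
                     tc$phi, tc$D, psf$green, gamma, flags)
  br <- group_brightness(group, "green")
  out <- list(record = rec, brightness = br, fast_axis_green = fa_g,
              two_component = tc, fast_axis_red = fa_r, ccf = cc)
  if (keep_surfaces)
    out$surfaces <- list(gg = s_gg,
                         rr = if (two_channel) s_rr else NULL,
                         gc = if (two_channel) s_gc else NULL)
  out
}

#' Analyze a two-channel movie
#'
#' Preprocesses the movie ([make_frame_groups()]) and runs
#' [analyze_group()] on every group.
#'
#' @param green,red count arrays (`rows x cols x frames`).
#' @param geometry a [scan_geometry()].
#' @param psf a [psf_pair()].
#' @param group_size frames per group.
#' @param cycle cycle metadata, recycled across groups.
#' @param gamma illumination shape factor.
#' @param max_lag maximum correlation lag.
#' @param axial_factor ccRICS axial amplitude correction.
#' @param fit_window,B_max_2d see [analyze_group()].
#' @param keep_surfaces attach per-group surfaces.
#' @param ... passed to [segment_nuclei()].
#' @return list with `records` (PoolRecord data.frame), `brightness`
#'   data.frame, and per-group details in `groups`.
#' @export
analyze_movie <- function(green, red = NULL, geometry, psf = psf_pair(),
                          group_size = 10, cycle = NA,
                          gamma = psf$green$gamma, max_lag = 32,
                          axial_factor = 1, fit_window = c(24, 16),
                          B_max_2d = 5e-3, keep_surfaces = FALSE, ...) {
  groups <- make_frame_groups(green, red, geometry, group_size,
                              cycle = cycle, ...)
  res <- lapply(groups, analyze_group, psf = psf, gamma = gamma,
                max_lag = max_lag, axial_factor = axial_factor,
                fit_window = fit_window, B_max_2d = B_max_2d,
                keep_surfaces = keep_surfaces)
  keep <- !vapply(res, is.null, logical(1))
  res <- res[keep]
  list(records = do.call(rbind, lapply(res, `[[`, "record")),
       brightness = do.call(rbind, lapply(res, `[[`, "brightness")),
       groups = res)
}

#' Default pipeline configuration
#'
#' Assembles a complete, schema-valid configuration for a synthetic run:
#' scan geometry, PSF pair, simulation truth, grouping, segmentation, fit
#' and output settings. Every field can be overridden by the matching
#' argument.
#'
#' @param seed master seed of the run.
#' @param n_frames movie length.
#' @param n_px image size (square).
#' @param C_nM,phi,psi,D target truth of the simulated movie.
#' @param n_nuclei,radius_px nuclear layout; the default radius keeps
#'   roughly half the field as background so the background mode of the
#'   histogram stays well resolved.
#' @param group_size frames per analysis group.
#' @param cycle cycle metadata label.
#' @return a `run_config` list.
#' @export
default_run_config <- function(seed = 1L, n_frames = 30, n_px = 256,
                               C_nM = 30, phi = 0.5, psi = 0.3, D = 2,
                               n_nuclei = 6, radius_px = 40,
                               group_size = 10, cycle = 13L) {
  geometry <- scan_geometry(line_time_s = 4.94e-3, n_rows = n_px,
                            n_cols = n_px,
                            frame_time_s = n_px * 4.94e-3)
  structure(list(
    seed = as.integer(seed), simulate = TRUE, n_frames = n_frames,
    geometry = geometry, psf = psf_pair(),
    truth = list(C_nM = C_nM, phi = phi, psi = psi, D = D),
    nuclei = list(n = n_nuclei, radius_px = radius_px),
    group_size = group_size, cycle = cycle, gamma = psf_model()$gamma,
    max_lag = 32, axial_factor = 1,
    segmentation = list(smooth_sigma = 2, h_frac = 0.1, min_area = 500,
                        erode_px = 2),
    binding_fit = FALSE), class = "run_config")
}

#' Validate a pipeline configuration
#'
#' @param config a `run_config`.
#' @return the config, invisibly; errors on schema violations.
#' @export
validate_run_config <- function(config) {
  need <- c("seed", "simulate", "n_frames", "geometry", "psf", "group_size",
            "gamma", "max_lag", "segmentation")
  miss <- setdiff(need, names(config))
  if (length(miss)) stop("config missing fields: ",
                         paste(miss, collapse = ", "))
  validate_scan_geometry(config$geometry)
  stopifnot(config$group_size >= 7, config$group_size <= 12,
            config$max_lag >= 1, config$gamma > 0, config$gamma <= 1)
  if (config$simulate)
    stopifnot(config$truth$phi >= config$truth$psi,
              config$truth$C_nM > 0, config$truth$D >= 0)
  invisible(config)
}

#' Run the full pipeline
#'
#' Simulates (or loads) a two-channel movie, analyzes it, and writes the
#' result bundle: `pool_records.csv`, `brightness.csv`, `config.yaml`,
#' `run_info.json` (config hash, seed, package version), optionally
#' `binding_params.json` (when `config$binding_fit` is set and at least 8
#' pool records exist) and optionally the movie TIFFs. A fixed seed yields
#' byte-identical CSV outputs.
#'
#' @param config a `run_config` (see [default_run_config()]).
#' @param out_dir output directory, created if needed; `NULL` skips
#'   writing.
#' @param movie optional preloaded movie (list with `green`, `red`)
#'   used when `config$simulate` is FALSE.
#' @param write_tiff also write the simulated movie as TIFF stacks.
#' @return list with `records`, `brightness`, `truth`, `binding`,
#'   `paths`.
#' @export
run_full_pipeline <- function(config, out_dir = NULL, movie = NULL,
                              write_tiff = FALSE) {
  validate_run_config(config)
  set.seed(config$seed)
  truth <- NULL
  if (config$simulate) {
    nuc <- default_nuclei(config$geometry, config$nuclei$n,
                          config$nuclei$radius_px)
    tr <- recovery_truth(C_nM = config$truth$C_nM, phi = config$truth$phi,
                         psi = config$truth$psi, nuclei = nuc,
                         geometry = config$geometry,
                         D_free_um2_s = config$truth$D, seed = config$seed)
    sim <- simulate_timeseries(tr, config$geometry, config$psf,
                               config$n_frames, nuc, seed = config$seed,
                               cycle = config$cycle)
    truth <- sim$truth
  } else {
    if (is.null(movie)) stop("simulate = FALSE requires a movie")
    sim <- movie
  }
  seg <- config$segmentation
  res <- analyze_movie(sim$green, sim$red, config$geometry, config$psf,
                       config$group_size, cycle = config$cycle,
                       gamma = config$gamma, max_lag = config$max_lag,
                       axial_factor = config$axial_factor,
                       smooth_sigma = seg$smooth_sigma, h_frac = seg$h_frac,
                       min_area = seg$min_area, erode_px = seg$erode_px)
  binding <- NULL
  if (isTRUE(config$binding_fit) && nrow(res$records) >= 8) {
    binding <- fit_equilibrium_model(res$records, seed = config$seed)
  } else if (isTRUE(config$binding_fit)) {
    warning("binding fit skipped: fewer than 8 pool records")
  }
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(records = file.path(out_dir, "pool_records.csv"),
                  brightness = file.path(out_dir, "brightness.csv"),
                  config = file.path(out_dir, "config.yaml"),
                  info = file.path(out_dir, "run_info.json"))
    utils::write.csv(res$records, paths$records, row.names = FALSE)
    utils::write.csv(res$brightness, paths$brightness, row.names = FALSE)
    cfg <- rapply(unclass(config), unclass, how = "replace")
    yaml::write_yaml(cfg, paths$config)
    info <- list(seed = config$seed,
                 config_md5 = unname(tools::md5sum(paths$config)),
                 package_version =
                   as.character(utils::packageVersion("ricsbind")))
    jsonlite::write_json(info, paths$info, auto_unbox = TRUE)
    if (!is.null(binding)) {
      paths$binding <- file.path(out_dir, "binding_params.json")
      jsonlite::write_json(c(unclass(binding),
                             list(ssr = attr(binding, "ssr"),
                                  n_used = attr(binding, "n_used"))),
                           paths$binding, auto_unbox = TRUE)
    }
    if (write_tiff && config$simulate)
      write_movie_tiff(sim, file.path(out_dir, "movie"))
  }
  list(records = res$records, brightness = res$brightness, truth = truth,
       binding = binding, groups = res$groups, paths = paths)
}
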