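# Thermodynamic equilibrium binding model: Hill occupancy, power-law site
# capacity, free-concentration solver, dose/response fitting, accessible-site
# estimation and residence-time calculators.

#' Binding-model parameters
#'
#' Dissociation constants and site capacities of the active
#' (chromatin-correlated) and inactive immobile pools, with per-pool Hill
#' coefficients. When `power_law = TRUE` the active-pool capacity is not a
#' constant but a power law of the free concentration,
#' `C_B,a = a * C_free^k` (accessible sites opening with free TF level).
#'
#' @param KD_active,KD_inactive dissociation constants (nM, > 0).
#' @param CB_active,CB_inactive site capacities (nM, >= 0); `CB_active` is
#'   ignored when `power_law = TRUE`.
#' @param n_active,n_inactive Hill coefficients (>= 1; 1 everywhere by
#'   default, 2 for a sigmoidal inactive pool).
#' @param power_law use the power-law active capacity.
#' @param pl_a,pl_k power-law scale (nM^(1-k)) and exponent.
#' @return a `binding_params` list.
#' @export
binding_params <- function(KD_active = 17, CB_active = 50,
                           KD_inactive = 24, CB_inactive = 34,
                           n_active = 1, n_inactive = 1,
                           power_law = FALSE, pl_a = 420, pl_k = 0.7) {
  stopifnot(KD_active > 0, KD_inactive > 0, CB_active >= 0,
            CB_inactive >= 0, n_active >= 1, n_inactive >= 1,
            pl_a > 0, pl_k > 0)
  structure(list(KD_active = KD_active, CB_active = CB_active,
                 KD_inactive = KD_inactive, CB_inactive = CB_inactive,
                 n_active = n_active, n_inactive = n_inactive,
                 power_law = power_law, pl_a = pl_a, pl_k = pl_k),
            class = "binding_params")
}

#' Hill-model bound concentration
#'
#' `C_bound = C_B * C_free^n / (K_D^n + C_free^n)`: equilibrium occupancy
#' of `C_B` worth of sites with dissociation constant `K_D` and Hill
#' coefficient `n`; saturates at `C_B`.
#'
#' @param C_free free TF concentration (nM, >= 0; vectorized).
#' @param KD dissociation constant (nM, > 0).
#' @param CB site capacity (nM, >= 0).
#' @param n Hill coefficient (>= 1).
#' @return bound concentration (nM).
#' @export
hill_bound <- function(C_free, KD, CB, n = 1) {
  stopifnot(all(C_free >= 0), KD > 0, CB >= 0, n >= 1)
  CB * C_free^n / (KD^n + C_free^n)
}

#' Power-law accessible-site capacity
#'
#' `C_B = a * C_free^k`: empirical model of the active-pool site capacity
#' growing sublinearly with the free concentration.
#'
#' @param C_free free TF concentration (nM, >= 0).
#' @param a scale (nM^(1-k)), default 420.
#' @param k exponent, default 0.7.
#' @return capacity (nM).
#' @export
power_law_sites <- function(C_free, a = 420, k = 0.7) {
  stopifnot(all(C_free >= 0))
  a * C_free^k
}

bound_pools <- function(C_free, params) {
  CB_a <- if (params$power_law)
    power_law_sites(C_free, params$pl_a, params$pl_k) else params$CB_active
  list(active = hill_bound(C_free, params$KD_active, CB_a, params$n_active),
       inactive = hill_bound(C_free, params$KD_inactive,
                             params$CB_inactive, params$n_inactive))
}

#' Solve the pool conservation equation for the free concentration
#'
#' Finds the unique root of
#' `C_tot = C_free + C_active(C_free) + C_inactive(C_free)` by bracketed
#' bisection on `[0, C_tot]` (the left side is strictly increasing in
#' `C_free`, so the root exists and is unique). Vectorized over records;
#' 60 bisection steps leave the root far below the 1e-10 nM tolerance the
#' conservation identity is verified to.
#'
#' @param C_tot total concentration(s) (nM, >= 0; vectorized).
#' @param params a [binding_params()].
#' @return data.frame with `C_tot`, `C_free`, `C_active`, `C_inactive`.
#' @export
solve_free_concentration <- function(C_tot, params) {
  stopifnot(all(C_tot >= 0))
  lo <- rep(0, length(C_tot))
  hi <- C_tot
  for (i in seq_len(60)) {
    mid <- (lo + hi) / 2
    b <- bound_pools(mid, params)
    over <- mid + b$active + b$inactive > C_tot
    hi[over] <- mid[over]
    lo[!over] <- mid[!over]
  }
  cf <- (lo + hi) / 2
  b <- bound_pools(cf, params)
  data.frame(C_tot = C_tot, C_free = cf, C_active = b$active,
             C_inactive = b$inactive)
}

#' Fit the equilibrium model to a pool-record time series
#'
#' Least-squares fit of the active and inactive bound concentrations
#' (as functions of the total concentration, through
#' [solve_free_concentration()]) to measured pool records. Records from
#' excluded cycles are dropped, as are the first `drop_first` records of
#' each cycle (equilibrium not yet established early in interphase).
#' Multistart bounded optimization from log-uniform draws; the best
#' residual wins.
#'
#' @param records data.frame with columns `C_tot_nM`, `C_active_nM`,
#'   `C_inactive_nM` and optionally `cycle` and `time_s`.
#' @param n_active,n_inactive Hill coefficients held fixed during the fit.
#' @param power_law fit the power-law active capacity (parameters `pl_a`,
#'   `pl_k`) instead of a constant `CB_active`.
#' @param exclude_cycles cycle labels dropped entirely (default 10, too
#'   short for equilibrium).
#' @param drop_first number of leading records dropped per cycle.
#' @param n_starts number of multistarts (default 20).
#' @param seed seed for the multistart draws.
#' @param fix_pl_k hold the power-law exponent at this value instead of
#'   fitting it (the exponent is best calibrated separately, from the
#'   accessible-site vs free-concentration relation; fitting it jointly
#'   with `KD_active` and `pl_a` is poorly identified).
#' @param weights `"absolute"` (plain least squares, the default) or
#'   `"relative"` (residuals divided by the observation) — the right
#'   choice when the records span decades with multiplicative errors.
#' @param lower,upper named bounds on (KD_active, CB_active-or-pl_a,
#'   KD_inactive, CB_inactive, pl_k).
#' @return a [binding_params()] with attributes `ssr`, `n_used`,
#'   `boundary` (names of parameters pinned at a bound).
#' @export
fit_equilibrium_model <- function(records, n_active = 1, n_inactive = 1,
                                  power_law = FALSE,
                                  exclude_cycles = c(10), drop_first = 2,
                                  n_starts = 20, seed = 1, fix_pl_k = NULL,
                                  weights = c("absolute", "relative"),
                                  lower = NULL, upper = NULL) {
  weights <- match.arg(weights)
  df <- as.data.frame(records)
  if (!is.null(df$cycle) && length(exclude_cycles)) {
    df <- df[!(df$cycle %in% exclude_cycles), , drop = FALSE]
    if (drop_first > 0) {
      keep <- unlist(lapply(split(seq_len(nrow(df)), df$cycle), function(i)
        i[-seq_len(min(drop_first, length(i)))]))
      df <- df[sort(keep), , drop = FALSE]
    }
  }
  df <- df[stats::complete.cases(df[, c("C_tot_nM", "C_active_nM",
                                        "C_inactive_nM")]), , drop = FALSE]
  if (nrow(df) < 8) stop("need >= 8 usable records after exclusions")
  scale_ref <- max(df$C_tot_nM)
  if (is.null(lower)) lower <- c(0.01, 0.1, 0.01, 0.1, 0.2)
  if (is.null(upper)) upper <- c(1e3, 1e4, 1e3, 1e4, 1.5)
  fit_k <- power_law && is.null(fix_pl_k)
  npar <- if (fit_k) 5 else 4
  obj <- function(lp) {
    p <- exp(lp[1:4])
    params <- binding_params(KD_active = p[1],
                             CB_active = if (power_law) 1 else p[2],
                             KD_inactive = p[3], CB_inactive = p[4],
                             n_active = n_active, n_inactive = n_inactive,
                             power_law = power_law,
                             pl_a = if (power_law) p[2] else 420,
                             pl_k = if (fit_k) lp[5] else
                               if (power_law) fix_pl_k else 0.7)
    pred <- solve_free_concentration(df$C_tot_nM, params)
    ra <- pred$C_active - df$C_active_nM
    ri <- pred$C_inactive - df$C_inactive_nM
    if (weights == "relative") {
      ra <- ra / pmax(df$C_active_nM, 1e-6)
      ri <- ri / pmax(df$C_inactive_nM, 1e-6)
    }
    sum(ra^2 + ri^2)
  }
  lo <- c(log(lower[1:4]), lower[5])[1:npar]
  up <- c(log(upper[1:4]), upper[5])[1:npar]
  set.seed(seed)
  starts <- matrix(stats::runif(n_starts * npar, rep(lo, each = n_starts),
                                rep(up, each = n_starts)), n_starts, npar)
  # anchor one start at data-driven guesses
  starts[1, 1:4] <- log(pmin(pmax(c(
    stats::median(df$C_tot_nM) / 2, max(df$C_active_nM) * 1.5,
    stats::median(df$C_tot_nM) / 2, max(df$C_inactive_nM) * 1.5),
    lower[1:4]), upper[1:4]))
  if (fit_k) starts[1, 5] <- 0.7
  best <- NULL
  for (i in seq_len(n_starts)) {
    fit <- try(stats::optim(starts[i, ], obj, method = "L-BFGS-B",
                            lower = lo, upper = up,
                            control = list(maxit = 500)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all multistarts failed")
  p <- exp(best$par[1:4])
  params <- binding_params(KD_active = p[1],
                           CB_active = if (power_law) 0 else p[2],
                           KD_inactive = p[3], CB_inactive = p[4],
                           n_active = n_active, n_inactive = n_inactive,
                           power_law = power_law,
                           pl_a = if (power_law) p[2] else 420,
                           pl_k = if (fit_k) best$par[5] else
                             if (power_law) fix_pl_k else 0.7)
  if (power_law) params$CB_active <- NA_real_
  at_bound <- abs(best$par - lo) < 1e-6 | abs(best$par - up) < 1e-6
  nm <- c("KD_active", if (power_law) "pl_a" else "CB_active",
          "KD_inactive", "CB_inactive", if (fit_k) "pl_k")
  attr(params, "ssr") <- best$value
  attr(params, "n_used") <- nrow(df)
  attr(params, "boundary") <- nm[at_bound]
  attr(params, "scale_ref") <- scale_ref
  if (any(at_bound))
    warning("boundary-pinned parameter(s): ", paste(nm[at_bound],
                                                    collapse = ", "))
  params
}

#' Nuclear-averaged concentration of binding sites
#'
#' `L = ploidy * n_sites / (N_A * V)` in nM for `n_sites` genomic sites in
#' a nucleus of volume `V` (um^3).
#'
#' @param n_sites number of sites per haploid genome.
#' @param volume_um3 nuclear volume (um^3).
#' @param ploidy genome copies (default 2, diploid).
#' @return concentration (nM).
#' @export
sites_concentration <- function(n_sites, volume_um3, ploidy = 2) {
  stopifnot(n_sites > 0, volume_um3 > 0, ploidy > 0)
  ploidy * n_sites / (MOLEC_PER_UM3_PER_NM * volume_um3)
}

#' Back out the dissociation constant from one occupancy measurement
#'
#' Inverts the n = 1 Hill model at a single point:
#' `K_D = C_free * (L - C_bound) / C_bound` given the site concentration
#' `L`.
#'
#' @param C_free free concentration (nM).
#' @param C_bound bound concentration (nM, 0 < C_bound < L).
#' @param L site concentration (nM).
#' @return dissociation constant (nM).
#' @export
kd_from_occupancy <- function(C_free, C_bound, L) {
  stopifnot(C_free > 0, C_bound > 0, C_bound < L)
  C_free * (L - C_bound) / C_bound
}

#' Accessible-site capacity over time
#'
#' Inverts the n = 1 Hill model at each time point:
#' `C_B(t) = C_active(t) * (K_D + C_free(t)) / C_free(t)`, optionally
#' converted to site counts with a nuclear-volume table.
#'
#' @param C_active,C_free concentration traces (nM).
#' @param KD_active dissociation constant of the active pool (nM).
#' @param volume_um3 optional nuclear volume(s) for site counts (recycled).
#' @param ploidy genome copies for the count conversion.
#' @return data.frame with `C_B_nM` and (when volumes are given)
#'   `n_sites`; points with `C_free <= 0` are missing.
#' @export
accessible_sites_timecourse <- function(C_active, C_free, KD_active,
                                        volume_um3 = NULL, ploidy = 2) {
  stopifnot(length(C_active) == length(C_free))
  CB <- ifelse(C_free > 0, C_active * (KD_active + C_free) / C_free,
               NA_real_)
  out <- data.frame(C_B_nM = CB)
  if (!is.null(volume_um3))
    out$n_sites <- CB * MOLEC_PER_UM3_PER_NM *
      rep_len(volume_um3, length(CB)) / ploidy
  out
}

#' Diffusion-limited (Smoluchowski) on-rate
#'
#' `k_on = 4 pi D b a` with reaction cross-section `b` and reactive
#' surface fraction `a`, converted to nM^-1 s^-1.
#'
#' @param D_um2_s diffusivity (um^2/s, > 0).
#' @param b_nm reaction cross-section (nm, > 0; 0.34 nm for base-pair
#'   scale contacts).
#' @param a reactive fraction of the molecular surface, in (0, 1].
#' @return on-rate (nM^-1 s^-1).
#' @export
smoluchowski_kon <- function(D_um2_s, b_nm = 0.34, a = 0.2) {
  stopifnot(D_um2_s > 0, b_nm > 0, a > 0, a <= 1)
  # 4 pi D b a in nm^3/s, times molecules-per-nm^3 per nM
  4 * pi * (D_um2_s * 1e6) * b_nm * a * (MOLEC_PER_UM3_PER_NM * 1e-9)
}

#' Mean residence time of a binding event
#'
#' `tau = 1 / (k_on * K_D) = 1 / k_off`.
#'
#' @param KD_nM dissociation constant (nM, > 0).
#' @param kon on-rate (nM^-1 s^-1, > 0).
#' @return residence time (s).
#' @export
residence_time <- function(KD_nM, kon) {
  stopifnot(KD_nM > 0, kon > 0)
  1 / (kon * KD_nM)
}
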