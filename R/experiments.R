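#' Run repeated trials at one parameter point
#'
#' Simulates the full network `trials` times with distinct derived seeds and
#' returns the per-trial rhythm summary. This is the unit of work of every
#' sweep experiment.
#'
#' @param g_h HCN conductance (mS/cm^2).
#' @param eta_ach cholinergic tone (%).
#' @param g_tht_scale multiplier on the high-threshold calcium conductance.
#' @param trials number of repeats (distinct seeds).
#' @param duration run length (ms).
#' @param seed master seed; trial seeds derive deterministically from it.
#' @param threshold periodicity threshold (nats).
#' @param point_id integer offset so different sweep points get independent
#'   seed streams.
#' @param ... further [sim_config()] arguments.
#' @return tibble, one row per trial, columns of [rhythm_summary()] plus
#'   `trial`.
#' @export
run_trials <- function(g_h = 0.36, eta_ach = 0, g_tht_scale = 1, trials = 3,
                       duration = 7000, seed = 1, threshold = NULL,
                       point_id = 0, ...) {
  purrr::map_dfr(seq_len(trials), function(k) {
    cfg <- sim_config(duration = duration, g_h = g_h, eta_ach = eta_ach,
                      g_tht_scale = g_tht_scale,
                      seed = derive_seed(seed, point_id * 1000 + k), ...)
    mutate(rhythm_summary(simulate_network(cfg), threshold = threshold),
           trial = k, .before = 1)
  })
}

majority_periodic <- function(df) {
  sum(df$periodic) > nrow(df) / 2
}

#' Sweep HCN expression and locate the stable oscillation region
#'
#' Varies the HCN conductance `g_h` of the HTC pacemaker cells across a grid
#' (noise on), measuring the LFP peak frequency and spectral entropy at each
#' point. Within the stable region the rhythm frequency falls monotonically
#' as `g_h` falls; outside it (too little HCN: the membrane lingers near
#' threshold and noise triggers bursts; too much: over-excitability)
#' periodicity is lost. The stable-region boundaries are the outermost grid
#' points classified periodic in a majority of trials.
#'
#' @param g_h_values grid of HCN conductances (mS/cm^2).
#' @param trials,duration,seed see [run_trials()].
#' @param threshold periodicity threshold (nats); required. See
#'   [calibrate_periodicity_threshold()].
#' @param g_kleak_norm potassium-leak conductance defining `eta_ach = 0`; the
#'   published control value 0.01 mS/cm^2.
#' @param ... further [sim_config()] arguments.
#' @return object of class `gh_sweep`: `results` (per point per trial),
#'   `by_point` (trial means + periodic majority), `lower_boundary`,
#'   `upper_boundary` (mS/cm^2), `threshold`.
#' @export
sweep_gh <- function(g_h_values = seq(0.20, 0.48, by = 0.01), trials = 5,
                     duration = 7000, seed = 1, threshold,
                     g_kleak_norm = 0.01, ...) {
  res <- purrr::imap_dfr(g_h_values, function(g, i) {
    mutate(run_trials(g_h = g, trials = trials, duration = duration,
                      seed = seed, threshold = threshold, point_id = i,
                      g_kleak_norm = g_kleak_norm, ...),
           g_h = g, .before = 1)
  })
  by_point <- res |>
    group_by(.data$g_h) |>
    summarise(peak_freq = mean(.data$peak_freq), entropy = mean(.data$entropy),
              periodic = sum(.data$periodic) > dplyr::n() / 2)
  per <- by_point$g_h[by_point$periodic]
  structure(list(results = res, by_point = by_point,
                 lower_boundary = if (length(per)) min(per) else NA_real_,
                 upper_boundary = if (length(per)) max(per) else NA_real_,
                 threshold = threshold),
            class = "gh_sweep")
}

#' @export
print.gh_sweep <- function(x, ...) {
  cat("<gh_sweep> ", nrow(x$by_point), " g_h points; stable region [",
      x$lower_boundary, ", ", x$upper_boundary, "] mS/cm^2\n", sep = "")
  invisible(x)
}

#' Cholinergic rescue of a slowed alpha rhythm
#'
#' With HCN expression reduced to `g_h_fraction` of control, sweeps the
#' cholinergic-tone index `eta_ach` (fractional reduction of the HTC
#' potassium leak) and asks whether increased ACh can restore a periodic
#' 10-Hz rhythm. "Rescued" means the majority of trials are periodic and the
#' mean peak frequency lies in `target_band`. Past a breakdown point the
#' increased excitability lets noise trigger bursts and periodicity is lost.
#'
#' @param g_h_fraction HCN expression relative to the 0.36 mS/cm^2 control.
#' @param eta_grid cholinergic-tone grid (%).
#' @param target_band the restored-rhythm frequency band (Hz).
#' @param trials,duration,seed,threshold,g_kleak_norm,... see [sweep_gh()].
#' @param stop_after_breakdown stop scanning after this many consecutive
#'   aperiodic grid points (`Inf` to scan the whole grid).
#' @return object of class `ach_rescue`: `results`, `by_point`,
#'   `rescue_eta` (smallest rescuing eta, `NA` if none), `breakdown_eta`
#'   (smallest eta with an aperiodic majority), `max_periodic_freq`.
#' @export
ach_rescue <- function(g_h_fraction = 0.8, eta_grid = seq(0, 50, by = 2.5),
                       target_band = c(9.75, 10.25), trials = 3,
                       duration = 7000, seed = 1, threshold,
                       g_kleak_norm = 0.01, stop_after_breakdown = 2, ...) {
  # frequency rises with eta only until periodicity breaks down; once the
  # breakdown is bracketed there is nothing left to measure further out
  pieces <- list(); n_broken <- 0
  for (i in seq_along(eta_grid)) {
    eta <- eta_grid[i]
    df <- mutate(run_trials(g_h = 0.36 * g_h_fraction, eta_ach = eta,
                            trials = trials, duration = duration, seed = seed,
                            threshold = threshold, point_id = i,
                            g_kleak_norm = g_kleak_norm, ...),
                 eta_ach = eta, .before = 1)
    pieces[[i]] <- df
    n_broken <- if (majority_periodic(df)) 0 else n_broken + 1
    if (is.finite(stop_after_breakdown) && n_broken >= stop_after_breakdown) break
  }
  res <- bind_rows(pieces)
  by_point <- res |>
    group_by(.data$eta_ach) |>
    summarise(peak_freq = mean(.data$peak_freq), entropy = mean(.data$entropy),
              periodic = sum(.data$periodic) > dplyr::n() / 2)
  rescued <- by_point$periodic & by_point$peak_freq >= target_band[1] &
    by_point$peak_freq <= target_band[2]
  broken <- !by_point$periodic
  structure(list(
    results = res, by_point = by_point, g_h_fraction = g_h_fraction,
    rescue_eta = if (any(rescued)) min(by_point$eta_ach[rescued]) else NA_real_,
    breakdown_eta = if (any(broken)) min(by_point$eta_ach[broken]) else NA_real_,
    max_periodic_freq = if (any(by_point$periodic))
      max(by_point$peak_freq[by_point$periodic]) else NA_real_,
    threshold = threshold), class = "ach_rescue")
}

#' @export
print.ach_rescue <- function(x, ...) {
  cat("<ach_rescue> g_h at ", 100 * x$g_h_fraction, "% of control: ",
      if (is.na(x$rescue_eta)) "not rescuable" else
        paste0("rescue at eta = ", x$rescue_eta, "%"),
      "; breakdown at eta = ", x$breakdown_eta, "%\n", sep = "")
  invisible(x)
}

#' Two-dimensional stability map over HCN expression and cholinergic tone
#'
#' Entropy surface over a `g_h` x `eta_ach` grid with the periodic-region
#' mask; stable oscillations occupy a bounded region of the plane.
#'
#' @param g_h_values,eta_grid grid axes.
#' @param trials,duration,seed,threshold,g_kleak_norm,... see [sweep_gh()].
#' @return object of class `thal_map`: `results` per (point, trial) and
#'   `by_point` with `periodic` mask.
#' @export
sweep_2d <- function(g_h_values = seq(0.24, 0.44, by = 0.04),
                     eta_grid = seq(-10, 30, by = 8), trials = 3,
                     duration = 7000, seed = 1, threshold,
                     g_kleak_norm = 0.01, ...) {
  grid <- tidyr::expand_grid(g_h = g_h_values, eta_ach = eta_grid)
  res <- purrr::pmap_dfr(list(grid$g_h, grid$eta_ach, seq_len(nrow(grid))),
    function(g, eta, i) {
      mutate(run_trials(g_h = g, eta_ach = eta, trials = trials,
                        duration = duration, seed = seed,
                        threshold = threshold, point_id = i,
                        g_kleak_norm = g_kleak_norm, ...),
             g_h = g, eta_ach = eta, .before = 1)
    })
  by_point <- res |>
    group_by(.data$g_h, .data$eta_ach) |>
    summarise(peak_freq = mean(.data$peak_freq), entropy = mean(.data$entropy),
              periodic = sum(.data$periodic) > dplyr::n() / 2, .groups = "drop")
  structure(list(results = res, by_point = by_point, threshold = threshold),
            class = "thal_map")
}

#' Firing-rate cascade across HCN expression
#'
#' Mean population firing rates (0-mV crossings per second, averaged over
#' cells and trials) for each HCN conductance. Reduced HCN slows the HTC
#' pacemaker, releasing TC cells from delayed GABAergic inhibition; the
#' raised TC drive in turn raises RE firing — an excitation-inhibition shift
#' toward more GABA release. HTC activity is also summarized as the burst
#' rate.
#'
#' @param g_h_values HCN grid (mS/cm^2).
#' @param trials,duration,seed,g_kleak_norm,... see [sweep_gh()].
#' @return object of class `rate_cascade`: `results` per (point, trial),
#'   `by_point` mean rates, and Spearman correlations `cor_htc_tc`,
#'   `cor_tc_re` across the grid.
#' @export
rate_cascade <- function(g_h_values = seq(0.28, 0.44, by = 0.02), trials = 5,
                         duration = 7000, seed = 1, g_kleak_norm = 0.01, ...) {
  res <- purrr::imap_dfr(g_h_values, function(g, i) {
    mutate(run_trials(g_h = g, trials = trials, duration = duration,
                      seed = seed, point_id = i,
                      g_kleak_norm = g_kleak_norm, ...),
           g_h = g, .before = 1)
  })
  by_point <- res |>
    group_by(.data$g_h) |>
    summarise(burst_rate = mean(.data$burst_rate),
              rate_htc = mean(.data$rate_htc), rate_tc = mean(.data$rate_tc),
              rate_re = mean(.data$rate_re))
  safe_spearman <- function(x, y) {
    if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
    cor(x, y, method = "spearman")
  }
  structure(list(
    results = res, by_point = by_point,
    cor_htc_tc = safe_spearman(by_point$rate_htc, by_point$rate_tc),
    cor_tc_re = safe_spearman(by_point$rate_tc, by_point$rate_re)),
    class = "rate_cascade")
}

the_cache <- new.env(parent = emptyenv())

#' Calibrate the normal-cholinergic-tone potassium leak
#'
#' Normal cholinergic tone is defined functionally: `g_kleak_norm` is the HTC
#' potassium-leak conductance at which the (noise-free, deterministic)
#' network generates a 10-Hz rhythm at control HCN expression. This
#' calibration anchors the `eta_ach` scale of all sweep experiments; the
#' published 0.01 mS/cm^2 anchors the search interval.
#' The result is cached per (g_h, duration, target) within the session.
#'
#' @param g_h HCN conductance at which to calibrate (control 0.36).
#' @param target target mean HTC burst rate (Hz).
#' @param tol frequency tolerance (Hz).
#' @param duration tuning-run length (ms).
#' @param interval bisection interval for the leak (mS/cm^2); must lie on
#'   the branch where rate falls monotonically with the leak.
#' @return the calibrated leak conductance (mS/cm^2), with the achieved
#'   burst rate as attribute `rate`.
#' @export
calibrate_gkleak_norm <- function(g_h = 0.36, target = 10, tol = 0.02,
                                  duration = 5000,
                                  interval = c(0.006, 0.012)) {
  key <- paste0("norm_", g_h, "_", duration, "_", target)
  if (!is.null(the_cache[[key]])) return(the_cache[[key]])
  rate_at <- function(gkl) {
    cfg <- sim_config(duration = duration, g_h = g_h, noise = FALSE,
                      seed = 1L, htc = list(g_kl = gkl))
    mean(burst_stats(simulate_network(cfg))$burst_rate)
  }
  # The deterministic rate is piecewise smooth in the leak (burst-pattern
  # mode locking); a two-stage grid search is robust where bisection is not.
  coarse <- seq(interval[1], interval[2], length.out = 13)
  r1 <- vapply(coarse, rate_at, numeric(1))
  i1 <- which.min(abs(r1 - target))
  if (!is.finite(r1[i1])) abort("no rhythmic operating point in `interval`")
  if (abs(r1[i1] - target) > tol) {
    lo <- coarse[max(i1 - 1, 1)]; hi <- coarse[min(i1 + 1, length(coarse))]
    fine <- seq(lo, hi, length.out = 9)
    r2 <- vapply(fine, rate_at, numeric(1))
    i2 <- which.min(abs(r2 - target))
    out <- structure(fine[i2], rate = r2[i2])
  } else {
    out <- structure(coarse[i1], rate = r1[i1])
  }
  the_cache[[key]] <- out
  out
}

#' Tune cholinergic tone to a target rhythm frequency
#'
#' Scans the cholinergic-tone index `eta_ach` (noise off, deterministic) and
#' picks the value whose network rhythm is both regular (coefficient of
#' variation of the interburst interval below `max_cv`) and closest to
#' `target` Hz, refining once around the best coarse point. The restriction
#' to regular points matters: the deterministic burst rate plateaus near 10
#' Hz over a range of tones that includes chaotic burst-count-transition
#' windows, and a baseline inside such a window is not the regular 10-Hz
#' rhythm the re-baselining protocol calls for. Results are cached per
#' (g_h, target, duration) within the session.
#'
#' @param g_h HCN conductance.
#' @param target target burst rate (Hz).
#' @param tol acceptable deviation (Hz).
#' @param max_cv maximum interburst-interval coefficient of variation for a
#'   tone to count as regular.
#' @param duration run length (ms) for the deterministic tuning runs.
#' @param interval `eta_ach` search range (%).
#' @param step coarse grid step (%).
#' @param g_kleak_norm leak conductance defining `eta_ach = 0`.
#' @param ... further [sim_config()] arguments.
#' @return list: `eta_ach`, achieved `burst_rate`, `cv`, `converged`
#'   (TRUE when a regular point within `tol` of the target was found).
#' @export
tune_eta_to_target <- function(g_h, target = 10, tol = 0.1, max_cv = 0.02,
                               duration = 5000, interval = c(-10, 45),
                               step = 2.5, g_kleak_norm = 0.01, ...) {
  key <- paste0("tune_", g_h, "_", target, "_", duration, "_", g_kleak_norm)
  if (!is.null(the_cache[[key]])) return(the_cache[[key]])
  probe <- function(eta) {
    sim <- simulate_network(sim_config(duration = duration, g_h = g_h,
                                       eta_ach = eta, noise = FALSE,
                                       g_kleak_norm = g_kleak_norm,
                                       seed = 1L, ...))
    keep <- sim$time >= sim$config$transient
    ibi <- unlist(lapply(which(sim$type == "HTC"), function(i) {
      st <- detect_spikes(sim$v[keep, i], sim$time[keep])
      diff(detect_bursts(st)$onset)
    }))
    if (length(ibi) < 10) return(c(rate = NA_real_, cv = NA_real_))
    c(rate = 1000 / mean(ibi), cv = stats::sd(ibi) / mean(ibi))
  }
  best_of <- function(etas) {
    m <- vapply(etas, probe, numeric(2))
    ok <- is.finite(m["rate", ]) & m["cv", ] <= max_cv
    if (!any(ok)) return(NULL)
    i <- which(ok)[which.min(abs(m["rate", ok] - target))]
    list(eta_ach = etas[i], burst_rate = unname(m["rate", i]),
         cv = unname(m["cv", i]))
  }
  coarse <- best_of(seq(interval[1], interval[2], by = step))
  if (is.null(coarse)) {
    out <- list(eta_ach = NA_real_, burst_rate = NA_real_, cv = NA_real_,
                converged = FALSE)
    the_cache[[key]] <- out
    return(out)
  }
  best <- coarse
  if (abs(best$burst_rate - target) > tol) {
    fine <- best_of(best$eta_ach + seq(-step, step, by = step / 5))
    if (!is.null(fine) &&
        abs(fine$burst_rate - target) < abs(best$burst_rate - target)) {
      best <- fine
    }
  }
  best$converged <- abs(best$burst_rate - target) <= tol
  the_cache[[key]] <- best
  best
}

#' Tolerance of the rhythm to increased calcium conductance
#'
#' For each HCN level, the baseline is first re-tuned to a 10-Hz rhythm via
#' the potassium leak ([tune_eta_to_target()]); the high-threshold calcium
#' conductance is then increased in percentage steps (noise on) until the
#' network loses periodicity. The tolerance is the largest contiguous
#' increase from 0% that stays periodic in a majority of trials; it shrinks
#' as HCN expression falls. The sweep stops early once an aperiodic point is
#' hit (the contiguous-from-zero definition makes later points irrelevant).
#'
#' @param g_h_values HCN conductances to profile (mS/cm^2).
#' @param g_tht_increase grid of % increases of the calcium conductance.
#' @param trials,duration,seed,threshold,g_kleak_norm,... see [sweep_gh()].
#' @param baseline_tol largest acceptable distance (Hz) between the re-tuned
#'   baseline rhythm and 10 Hz before a g_h point is marked invalid.
#' @param tune_interval `eta_ach` search range handed to
#'   [tune_eta_to_target()].
#' @return object of class `ca_tolerance`: `results` per (g_h, increase,
#'   trial) and `profile` with one row per g_h: `eta_baseline`, `tolerance`
#'   (%; `NA` when the baseline cannot reach 10 Hz).
#' @export
calcium_tolerance <- function(g_h_values = c(0.28, 0.32, 0.36),
                              g_tht_increase = seq(0, 40, by = 2.5),
                              trials = 3, duration = 7000, seed = 1,
                              threshold, g_kleak_norm = 0.01,
                              baseline_tol = 1, tune_interval = c(-10, 45),
                              ...) {
  g_tht_increase <- sort(g_tht_increase)
  all_res <- list()
  profile <- purrr::imap_dfr(g_h_values, function(g, gi) {
    tuned <- tune_eta_to_target(g, g_kleak_norm = g_kleak_norm,
                                interval = tune_interval)
    # low HCN expression may not support a regular 10-Hz rhythm at any tone;
    # the nearest regular baseline within `baseline_tol` Hz is used, beyond
    # that the point is marked invalid
    if (is.na(tuned$eta_ach) || abs(tuned$burst_rate - 10) > baseline_tol) {
      return(tibble(g_h = g, eta_baseline = NA_real_,
                    baseline_rate = tuned$burst_rate, tolerance = NA_real_))
    }
    tol <- 0   # an aperiodic baseline tolerates no increase at all
    for (i in seq_along(g_tht_increase)) {
      inc <- g_tht_increase[i]
      df <- run_trials(g_h = g, eta_ach = tuned$eta_ach,
                       g_tht_scale = 1 + inc / 100, trials = trials,
                       duration = duration, seed = seed, threshold = threshold,
                       point_id = gi * 100 + i, g_kleak_norm = g_kleak_norm, ...)
      all_res[[length(all_res) + 1]] <<- mutate(df, g_h = g,
                                                g_tht_increase = inc, .before = 1)
      if (!majority_periodic(df)) break
      tol <- inc
    }
    tibble(g_h = g, eta_baseline = tuned$eta_ach,
           baseline_rate = tuned$burst_rate, tolerance = tol)
  })
  structure(list(results = bind_rows(all_res), profile = profile,
                 threshold = threshold), class = "ca_tolerance")
}

#' @export
print.ca_tolerance <- function(x, ...) {
  print(x$profile)
  invisible(x)
}
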