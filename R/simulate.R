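#' Simulation configuration
#'
#' Collects integration settings, noise settings and the headline parameter
#' manipulations of the model: HCN conductance `g_h` (control 0.36 mS/cm^2),
#' cholinergic tone `eta_ach` (% reduction of the HTC potassium leak, control
#' 0) and a fractional scaling of the high-threshold calcium conductance
#' `g_tht_scale` (control 1).
#'
#' @param duration total simulated time (ms). The first `transient` ms are
#'   discarded by all analysis functions.
#' @param dt integration step (ms); forward Euler.
#' @param record_interval recording (decimation) interval, ms; must be an
#'   integer multiple of `dt`. The default 0.4 ms is a 2.5-kHz observation
#'   rate.
#' @param transient discarded initial transient (ms).
#' @param seed integer master seed; every random element of the run (white
#'   noise, Poisson trains) derives from it.
#' @param noise master switch; `white_noise`/`poisson` override it per source.
#' @param white_noise Gaussian white-noise drive on HTC cells.
#' @param poisson Poisson EPSP/IPSP shot noise on TC and RE cells.
#' @param variance white-noise variance (0.1).
#' @param scaling_mode white-noise step scaling, see [white_noise_increment()].
#' @param g_h HTC HCN conductance (mS/cm^2).
#' @param eta_ach cholinergic-tone index (%), see [apply_ach()].
#' @param g_kleak_norm the normal-cholinergic-tone HTC potassium-leak
#'   conductance that `eta_ach` is measured against (mS/cm^2). The default is
#'   the published 0.01; experiments may substitute the calibrated value
#'   from [calibrate_gkleak_norm()], since normal tone is defined functionally
#'   as the leak producing a 10-Hz rhythm.
#' @param g_tht_scale multiplier on the high-threshold calcium conductance.
#' @param n_htc number of HTC cells (network size scales with it, see
#'   [build_network()]).
#' @param g_gj gap-junction conductance (mS/cm^2).
#' @param htc,tc,re named lists of extra [cell_params()] overrides.
#' @param conductances named synaptic-conductance overrides, see
#'   [build_network()].
#' @param i_app constant applied current to HTC cells (uA/cm^2).
#' @param record_currents record the ionic currents of the first HTC cell
#'   (for burst-mechanism inspection).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(duration = 14000, dt = 0.01, record_interval = 0.4,
                       transient = 1000, seed = 1L,
                       noise = TRUE, white_noise = noise, poisson = noise,
                       variance = 0.1,
                       scaling_mode = c("as_printed", "standard_em"),
                       g_h = 0.36, eta_ach = 0, g_kleak_norm = 0.01,
                       g_tht_scale = 1, n_htc = 2, g_gj = 0.004,
                       htc = list(), tc = list(), re = list(),
                       conductances = NULL, i_app = 0,
                       record_currents = FALSE) {
  scaling_mode <- match.arg(scaling_mode)
  rec_every <- record_interval / dt
  if (abs(rec_every - round(rec_every)) > 1e-8)
    abort("`record_interval` must be an integer multiple of `dt`")
  if (duration <= transient)
    abort("`duration` must exceed `transient`")
  structure(list(
    duration = duration, dt = dt, record_interval = record_interval,
    rec_every = as.integer(round(rec_every)), transient = transient,
    seed = as.integer(seed), white_noise = white_noise, poisson = poisson,
    variance = variance, scaling_mode = scaling_mode,
    g_h = g_h, eta_ach = eta_ach, g_kleak_norm = g_kleak_norm,
    g_tht_scale = g_tht_scale,
    n_htc = n_htc, g_gj = g_gj, htc = htc, tc = tc, re = re,
    conductances = conductances, i_app = i_app,
    record_currents = record_currents
  ), class = "sim_config")
}

engine_config <- function(config, topology, single_cell = FALSE) {
  htc_over <- c(config$htc,
                list(g_h = config$g_h,
                     g_kl = apply_ach(config$eta_ach, config$g_kleak_norm),
                     g_tht = 12 * config$g_tht_scale,
                     i_app = config$i_app))
  htc_over <- htc_over[!duplicated(names(htc_over))]
  hp <- do.call(cell_params, c(list("HTC"), htc_over))
  tp <- do.call(cell_params, c(list("TC"), config$tc))
  rp <- do.call(cell_params, c(list("RE"), config$re))
  ca <- calcium_constants()

  if (single_cell) {
    n_htc <- config$n_htc; n_tc <- 0L; n_re <- 0L
    syn <- tibble(pre = integer(), post = integer(), kind = character(),
                  g_max = numeric(), e_rev = numeric(), bind = numeric(),
                  unbind = numeric(), pulse = numeric(), delay = numeric())
    gap <- if (n_htc >= 2) {
      gj <- expand.grid(a = seq_len(n_htc), b = seq_len(n_htc))
      gj <- gj[gj$a < gj$b, ]
      tibble(a = gj$a, b = gj$b, g_gj = config$g_gj)
    } else tibble(a = integer(), b = integer(), g_gj = numeric())
  } else {
    n_htc <- topology$n_htc; n_tc <- topology$n_tc; n_re <- topology$n_re
    syn <- topology$synapses
    gap <- topology$gap_junctions
  }
  kind_code <- c(AMPA = 0L, GABA_A = 1L, GABA_B = 2L)
  list(
    n_htc = n_htc, n_tc = n_tc, n_re = n_re,
    dt = config$dt, n_steps = round(config$duration / config$dt),
    rec_every = config$rec_every,
    htc = unclass(hp), tc = unclass(tp), re = unclass(rp),
    ca = ca,
    noise = list(white_on = isTRUE(config$white_noise),
                 poisson_on = isTRUE(config$poisson) && n_tc + n_re > 0,
                 variance = config$variance,
                 em_standard = config$scaling_mode == "standard_em",
                 mean_isi = 10, gs_tc_epsp = 1.0, gs_re_epsp = 0.02,
                 gs_re_ipsp = 0.015, e_epsp = 0, e_ipsp = -85),
    syn_pre = as.integer(syn$pre - 1L), syn_post = as.integer(syn$post - 1L),
    syn_kind = unname(kind_code[syn$kind]),
    syn_g = syn$g_max, syn_e = syn$e_rev, syn_bind = syn$bind,
    syn_unbind = syn$unbind, syn_pulse = syn$pulse, syn_delay = syn$delay,
    gj_a = as.integer(gap$a - 1L), gj_b = as.integer(gap$b - 1L),
    gj_g = gap$g_gj,
    record_currents = isTRUE(config$record_currents), v0 = -70
  )
}

run_engine_seeded <- function(ecfg, seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  .run_engine(ecfg)
}

finish_sim <- function(raw, config, topology, cell_type) {
  n_rec <- nrow(raw$v)
  time <- (seq_len(n_rec) - 1) * config$record_interval
  cells <- paste0(cell_type, ave(seq_along(cell_type), cell_type, FUN = seq_along))
  colnames(raw$v) <- cells
  spikes <- setNames(raw$spikes, cells)
  structure(list(time = time, v = raw$v, cell = cells, type = cell_type,
                 spikes = spikes, currents = raw$currents,
                 config = config, topology = topology),
            class = "thal_sim")
}

#' Simulate the thalamic network
#'
#' Builds the network of [build_network()] for the configured number of HTC
#' cells, integrates all cells, synapses and noise sources with forward Euler
#' at `config$dt`, and records decimated voltage traces plus full-rate spike
#' times (upward 0-mV crossings with a 2-ms refractory period, which also
#' trigger synaptic transmitter pulses). The run is bitwise reproducible from
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return object of class `thal_sim`: recording time grid (ms), a voltage
#'   matrix (rows = time points, columns = cells, 2.5-kHz default), per-cell
#'   spike times, the configuration and topology. Use [tidy()] for a long
#'   trace tibble, [glance()] for a one-row rhythm summary, [compute_lfp()]
#'   and [rhythm_summary()] for analysis.
#' @examples
#' \donttest{
#' sim <- simulate_network(sim_config(duration = 3000, seed = 42))
#' glance(sim)
#' }
#' @export
simulate_network <- function(config = sim_config()) {
  topology <- build_network(config$n_htc, g_gj = config$g_gj,
                            conductances = config$conductances)
  ecfg <- engine_config(config, topology)
  raw <- run_engine_seeded(ecfg, config$seed)
  cell_type <- c(rep("HTC", topology$n_htc), rep("TC", topology$n_tc),
                 rep("RE", topology$n_re))
  finish_sim(raw, config, topology, cell_type)
}

#' Simulate isolated HTC cells (no chemical synapses)
#'
#' One or more HTC pacemaker cells with no network; with `n_htc >= 2` the
#' cells remain gap-junction coupled. With noise off this isolates the
#' deterministic burst pacemaker.
#'
#' @param config a [sim_config()]; `n_htc` may be 1 here.
#' @return `thal_sim`, as [simulate_network()].
#' @export
simulate_htc <- function(config = sim_config(n_htc = 1, noise = FALSE)) {
  ecfg <- engine_config(config, topology = NULL, single_cell = TRUE)
  raw <- run_engine_seeded(ecfg, config$seed)
  finish_sim(raw, config, NULL, rep("HTC", config$n_htc))
}

#' @export
print.thal_sim <- function(x, ...) {
  cat("<thal_sim> ", length(x$cell), " cell(s), ",
      x$config$duration / 1000, " s at ",
      1 / x$config$record_interval * 1000, " Hz recording; seed ",
      x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Local field potential of a simulation
#'
#' The LFP is the pointwise mean of the HTC membrane voltages.
#'
#' @param sim a `thal_sim`.
#' @param discard_transient drop samples before `config$transient`.
#' @return tibble with `time` (ms) and `lfp` (mV).
#' @export
compute_lfp <- function(sim, discard_transient = TRUE) {
  htc_cols <- which(sim$type == "HTC")
  if (!length(htc_cols)) abort("no HTC cells in this simulation")
  lfp <- rowMeans(sim$v[, htc_cols, drop = FALSE])
  out <- tibble(time = sim$time, lfp = lfp)
  if (discard_transient) out <- out[out$time >= sim$config$transient, ]
  out
}

#' Detect spikes in a voltage trace
#'
#' Upward crossings of the threshold: sample `i` is a spike when
#' `v[i-1] < threshold` and `v[i] >= threshold`.
#'
#' @param v voltage trace (mV) at uniform sampling.
#' @param time sample times (ms); defaults to the sample index.
#' @param threshold crossing threshold (mV).
#' @return spike times (ms).
#' @export
detect_spikes <- function(v, time = seq_along(v), threshold = 0) {
  idx <- which(v[-1] >= threshold & v[-length(v)] < threshold) + 1
  time[idx]
}

#' Firing rate from spike times
#'
#' Count of threshold crossings divided by the duration.
#'
#' @param spikes spike times (ms).
#' @param duration duration over which they were collected (ms).
#' @return rate in Hz.
#' @export
firing_rate <- function(spikes, duration) length(spikes) / (duration / 1000)

#' Per-cell firing rates of a simulation
#'
#' Rates are computed from the recorded (decimated) traces after the
#' transient, as 0-mV upward crossings per second.
#'
#' @param sim a `thal_sim`.
#' @return tibble with `cell`, `type`, `n_spikes`, `rate` (Hz).
#' @export
firing_rates <- function(sim) {
  keep <- sim$time >= sim$config$transient
  dur <- max(sim$time) - sim$config$transient
  counts <- vapply(seq_along(sim$cell), function(i) {
    length(detect_spikes(sim$v[keep, i], sim$time[keep]))
  }, integer(1))
  tibble(cell = sim$cell, type = sim$type, n_spikes = counts,
         rate = counts / (dur / 1000))
}

#' Group spikes into bursts
#'
#' Successive spikes with inter-spike interval at most `max_intraburst_isi`
#' belong to one burst. The default 25-ms cutoff sits between the ~2-ms
#' intraburst interval and the ~90-ms interburst gap of the alpha pacemaker.
#'
#' @param spike_times sorted spike times (ms).
#' @param max_intraburst_isi grouping cutoff (ms).
#' @return tibble with `onset`, `offset` (ms) and `n_spikes` per burst.
#' @export
detect_bursts <- function(spike_times, max_intraburst_isi = 25) {
  if (!length(spike_times)) {
    return(tibble(onset = numeric(), offset = numeric(), n_spikes = integer()))
  }
  grp <- cumsum(c(1, diff(spike_times) > max_intraburst_isi))
  tibble(
    onset = as.numeric(tapply(spike_times, grp, min)),
    offset = as.numeric(tapply(spike_times, grp, max)),
    n_spikes = as.integer(tapply(spike_times, grp, length))
  )
}

#' Burst-rate statistics of the HTC population
#'
#' Interburst intervals are onset-to-onset differences; the burst rate is the
#' reciprocal of their mean.
#'
#' @param sim a `thal_sim`.
#' @param max_intraburst_isi see [detect_bursts()].
#' @return tibble per HTC cell: `cell`, `n_bursts`, `mean_ibi` (ms),
#'   `burst_rate` (Hz), `mean_spikes_per_burst`, `mean_burst_dur` (ms).
#' @export
burst_stats <- function(sim, max_intraburst_isi = 25) {
  htc <- which(sim$type == "HTC")
  purrr::map_dfr(htc, function(i) {
    keep <- sim$time >= sim$config$transient
    st <- detect_spikes(sim$v[keep, i], sim$time[keep])
    b <- detect_bursts(st, max_intraburst_isi)
    ibi <- diff(b$onset)
    tibble(cell = sim$cell[i], n_bursts = nrow(b),
           mean_ibi = if (length(ibi)) mean(ibi) else NA_real_,
           burst_rate = if (length(ibi)) 1000 / mean(ibi) else NA_real_,
           mean_spikes_per_burst = if (nrow(b)) mean(b$n_spikes) else NA_real_,
           mean_burst_dur = if (nrow(b)) mean(b$offset - b$onset) else NA_real_)
  })
}
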