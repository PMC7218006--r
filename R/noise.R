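#' Gaussian white-noise voltage increments for HTC cells
#'
#' Background synaptic and channel noise on the pacemaker cells is an
#' additive Gaussian white-noise term on the membrane-voltage update. In the
#' default `"standard_em"` (Euler-Maruyama) scaling each step adds
#' `sqrt(dt) * sigma * z`, `z ~ N(0, 1)`, `sigma^2 = variance`, so the summed
#' increment over a window of length `w` ms has variance `variance * w`. The
#' `"as_printed"` mode adds `dt * xi` with `xi ~ N(0, variance)` instead
#' (a literal reading of the source model's update rule; much weaker noise).
#' The active mode is recorded in simulation metadata.
#'
#' @param n number of increments.
#' @param dt time step (ms).
#' @param variance noise variance (mV^2/ms under `"standard_em"`).
#' @param scaling_mode `"standard_em"` or `"as_printed"`.
#' @return numeric vector of `n` voltage increments (mV). Uses the current R
#'   RNG stream: seed with `set.seed()` for reproducibility.
#' @export
white_noise_increment <- function(n, dt = 0.01, variance = 0.1,
                                  scaling_mode = c("as_printed", "standard_em")) {
  scaling_mode <- match.arg(scaling_mode)
  if (dt <= 0) abort("`dt` must be > 0")
  if (variance == 0) return(rep(0, n))
  z <- rnorm(n, 0, sqrt(variance))
  if (scaling_mode == "standard_em") sqrt(dt) * z else dt * z
}

#' Sample a Poisson impulse train
#'
#' Impulse times with exponentially distributed inter-impulse intervals
#' (mean `mean_isi`), truncated to `duration`. This is the shot-noise drive
#' delivered as EPSP/IPSP kernels to TC and RE cells.
#'
#' @param duration train length (ms).
#' @param mean_isi mean inter-impulse interval (ms).
#' @return strictly increasing impulse times in `(0, duration)`.
#' @export
sample_impulse_train <- function(duration, mean_isi = 10) {
  if (duration <= 0) abort("`duration` must be > 0")
  n_guess <- ceiling(duration / mean_isi + 4 * sqrt(duration / mean_isi) + 10)
  times <- cumsum(rexp(n_guess, rate = 1 / mean_isi))
  while (length(times) && times[length(times)] < duration) {
    times <- c(times, times[length(times)] +
                 cumsum(rexp(n_guess, rate = 1 / mean_isi)))
  }
  times[times < duration]
}

#' Shot-noise PSP current from an impulse train
#'
#' `I = -g_s * exp(T(t) - t) * (V - e_rev)` where `T(t)` is the most recent
#' impulse time at or before `t` (only the latest impulse contributes; the
#' kernel has a 1-ms time constant). Before the first impulse the current is
#' zero. `e_rev = 0` mV for EPSPs, `-85` mV for IPSPs.
#'
#' @param impulse_times sorted impulse times (ms).
#' @param t evaluation times (ms); vectorised.
#' @param v_post postsynaptic voltage (mV), scalar or same length as `t`.
#' @param g_s kernel amplitude (mS/cm^2).
#' @param e_rev reversal potential (mV).
#' @return current density (uA/cm^2), positive = depolarizing drive as it
#'   enters the membrane equation with a plus sign.
#' @export
psp_current <- function(impulse_times, t, v_post, g_s, e_rev = 0) {
  if (is.unsorted(impulse_times)) abort("`impulse_times` must be sorted")
  idx <- findInterval(t, impulse_times)
  last_T <- ifelse(idx > 0, impulse_times[pmax(idx, 1)], NA_real_)
  out <- ifelse(is.na(last_T), 0, -g_s * exp(last_T - t) * (v_post - e_rev))
  out
}
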