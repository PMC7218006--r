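#' Default biophysical parameters for a thalamic cell type
#'
#' Conductance densities (mS/cm^2), reversal potentials (mV) and kinetic
#' offsets for the three cell types of the thalamic alpha network:
#'
#' * `"HTC"` — high-threshold bursting thalamocortical pacemaker cell, carrying
#'   fast Na+/K+ spike currents, low- and high-threshold T-type calcium
#'   currents (one shared calcium pool), an HCN h-current, a calcium-activated
#'   potassium (AHP) current and ohmic + potassium leak.
#' * `"TC"` — thalamocortical relay cell: Na+/K+, low-threshold T current, a
#'   calcium-regulated h-current and leak.
#' * `"RE"` — reticular cell: Na+/K+, reticular T current and leak.
#'
#' The voltage used by the Na+/K+ rate functions is shifted by `v_shift_nak`
#' (+25 mV for HTC/TC, +55 mV for RE) and the low-threshold T current kinetics
#' by `v_shift_tlt` (+2 mV); the high-threshold T current uses the raw
#' membrane voltage. Membrane capacitance is 1 uF/cm^2.
#'
#' @param type one of `"HTC"`, `"TC"`, `"RE"`.
#' @param ... named overrides of any default (e.g. `g_h = 0.28`).
#' @return a named list of class `cell_params`.
#' @examples
#' cell_params("HTC")$g_h                # 0.36 mS/cm^2, the control HCN level
#' cell_params("HTC", g_h = 0.8 * 0.36)  # reduced HCN expression
#' @export
cell_params <- function(type = c("HTC", "TC", "RE"), ...) {
  type <- match.arg(type)
  p <- switch(type,
    HTC = list(
      c_m = 1, g_na = 90, e_na = 50, g_k = 10, e_k = -100,
      g_tlt = 2, g_tht = 12, g_l = 0.01, e_l = -70, g_kl = 0.01, e_kl = -100,
      g_h = 0.36, e_h = -40, g_ahp = 15, i_app = 0,
      v_shift_nak = 25, v_shift_tlt = 2
    ),
    TC = list(
      c_m = 1, g_na = 90, e_na = 50, g_k = 10, e_k = -100,
      g_tlt = 2, g_l = 0.01, e_l = -70, g_kl = 0.0028, e_kl = -100,
      g_h = 0.1, e_h = -43, a = 2,
      # rate constants of the calcium-regulated h-current as published,
      # exposed because they are dimensionally suspect (fractions are
      # clamped to [0,1] during integration)
      k_o1 = 1e-4, k_o2 = 1e-3, k_o3 = 0.01, k_p1 = 4e-4, k_p2 = 4e-3,
      ca_ref = 2e-4,
      v_shift_nak = 25, v_shift_tlt = 2
    ),
    RE = list(
      c_m = 1, g_na = 100, e_na = 50, g_k = 10, e_k = -100,
      g_tre = 2.3, g_l = 0.01, e_l = -73, g_kl = 0.08, e_kl = -100,
      v_shift_nak = 55
    )
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) abort(paste0("unknown ", type, " parameter(s): ",
                                  paste(bad, collapse = ", ")))
    p[names(dots)] <- dots
  }
  gpos <- grep("^g_", names(p), value = TRUE)
  if (any(unlist(p[gpos]) < 0)) abort("conductances must be >= 0")
  structure(c(p, list(type = type)), class = "cell_params")
}

#' Calcium-pool handling constants
#'
#' Intracellular calcium in every cell relaxes toward a 0.00024 mM resting
#' level; T-type calcium influx is rectified at zero (an outward calcium
#' current never depletes the pool). The calcium reversal potential is
#' recomputed each step from the Nernst equation at 36 C against a fixed
#' extracellular concentration.
#'
#' @param ca_o extracellular calcium (mM).
#' @param temperature kelvin.
#' @return named list with resting level, per-type decay constants (ms),
#'   `ca_o` and `temperature`.
#' @export
calcium_constants <- function(ca_o = 2, temperature = 309.15) {
  list(ca_rest = 0.00024, tau_htc = 3.0, tau_tc = 5.0, tau_re = 3.0,
       ca_o = ca_o, temperature = temperature)
}
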