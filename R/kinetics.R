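#' Na+/K+ rate constants (Traub-style kinetics)
#'
#' Opening/closing rates (1/ms) of the delayed-rectifier activation gate `n`
#' and the fast sodium gates `m`, `h`, evaluated at the shifted membrane
#' voltage `v_t` (the per-cell-type kinetic offset is already applied by the
#' caller: `v_t = v + 25` for HTC/TC, `v + 55` for RE). Removable 0/0
#' singularities in the linear-over-exponential forms are evaluated by their
#' limits.
#'
#' @param v_t shifted membrane voltage (mV); vectorised.
#' @return a tibble with columns `alpha_n, beta_n, alpha_m, beta_m, alpha_h,
#'   beta_h`.
#' @examples
#' rate_na_k(15)$alpha_n  # 0.16, the limit of the 0/0 form
#' @export
rate_na_k <- function(v_t) {
  if (!all(is.finite(v_t))) abort("`v_t` must be finite")
  tibble(
    alpha_n = 0.032 * vtrap(15 - v_t, 5),
    beta_n  = 0.5 * exp((10 - v_t) / 40),
    alpha_m = 0.32 * vtrap(13 - v_t, 4),
    beta_m  = 0.28 * vtrap(v_t - 40, 5),
    alpha_h = 0.128 * exp((17 - v_t) / 18),
    beta_h  = 4 / (exp((40 - v_t) / 5) + 1)
  )
}

# x/(exp(x/y) - 1) with the removable singularity at 0 evaluated by limit
vtrap <- function(x, y) {
  out <- ifelse(abs(x / y) < 1e-6, y * (1 - x / (2 * y)), x / (expm1(x / y)))
  out
}

#' Steady state and time constant from a rate pair
#'
#' `x_inf = alpha/(alpha+beta)`, `tau = 1/(alpha+beta)`.
#'
#' @param alpha,beta non-negative rates (1/ms); vectorised.
#' @return tibble with columns `x_inf`, `tau`.
#' @export
steady_state_tau <- function(alpha, beta) {
  s <- alpha + beta
  if (any(s <= 0)) abort("degenerate kinetics: alpha + beta must be > 0")
  tibble(x_inf = alpha / s, tau = 1 / s)
}

#' Calcium reversal potential (Nernst)
#'
#' @param ca_i,ca_o intra/extracellular calcium (mM), positive.
#' @param temperature kelvin (default 36 C).
#' @return reversal potential in mV.
#' @examples
#' nernst_ca(0.00024, 2)  # ~ +120 mV at rest
#' @export
nernst_ca <- function(ca_i, ca_o, temperature = 309.15) {
  if (any(ca_i <= 0) || any(ca_o <= 0)) abort("concentrations must be > 0")
  1000 * 8.314462618 * temperature / (2 * 96485.33212) * log(ca_o / ca_i)
}

#' One Euler step of the intracellular calcium pool
#'
#' `d[Ca]/dt = max(0, -10 * I_Ca / (2 * 96489)) + (0.00024 - [Ca]) / tau`:
#' influx from the (inward, negative) T-type calcium current, rectified so an
#' outward current never removes calcium, plus first-order decay to rest.
#'
#' @param ca_i calcium (mM).
#' @param i_ca_total summed T-type calcium current density (uA/cm^2).
#' @param dt time step (ms).
#' @param tau decay constant (ms): 3 for HTC/RE pools, 5 for TC.
#' @param ca_rest resting level (mM).
#' @return updated calcium (mM), floored at a small positive value.
#' @export
update_calcium <- function(ca_i, i_ca_total, dt, tau = 3, ca_rest = 0.00024) {
  if (dt <= 0) abort("`dt` must be > 0")
  influx <- pmax(0, -10 * i_ca_total / (2 * 96489))
  pmax(ca_i + dt * (influx + (ca_rest - ca_i) / tau), 1e-10)
}

# ---- channel kinetics shared between the R reference model and tests ----

#' Gating kinetics of the T-type and h currents
#'
#' Steady states and time constants for the low-threshold T current (shifted
#' voltage `v + 2`), the HTC high-threshold T current (unshifted voltage), the
#' HTC h-current gate `r`, and the reticular T current. The activation gate of
#' both HTC T currents is instantaneous (`m = m_inf(v)`); inactivation gates
#' relax with the returned time constants.
#'
#' @param v membrane voltage (mV); for `tlt_kinetics` the +2 mV shift is
#'   applied internally.
#' @return tibble of steady states and time constants (ms).
#' @name gate-kinetics
NULL

#' @rdname gate-kinetics
#' @export
tlt_kinetics <- function(v) {
  vt <- v + 2
  tibble(
    m_inf = 1 / (1 + exp(-(vt + 57) / 6.2)),
    h_inf = 1 / (1 + exp((vt + 81) / 4)),
    tau_h = (30.8 + (211.4 + exp((vt + 113.2) / 5)) /
               (1 + exp((vt + 84) / 3.2))) / 3.74
  )
}

#' @rdname gate-kinetics
#' @export
tht_kinetics <- function(v) {
  tibble(
    m_inf = 1 / (1 + exp(-(v + 40.1) / 3.5)),
    h_inf = 1 / (1 + exp((v + 62.2) / 5.5)),
    tau_h = 0.1483 * exp(-0.09398 * v) + 5.284 * exp(0.008855 * v)
  )
}

#' @rdname gate-kinetics
#' @export
h_gate_kinetics <- function(v) {
  tibble(
    r_inf = 1 / (1 + exp((v + 60) / 5.5)),
    tau_r = 20 + 1000 / (exp((v + 56.5) / 14.2) + exp(-(v + 74) / 11.6))
  )
}

#' @rdname gate-kinetics
#' @export
tre_kinetics <- function(v) {
  tibble(
    m_inf = 1 / (1 + exp(-(v + 52) / 7.4)),
    tau_m = 0.99 + 0.333 / (exp((v + 27) / 10) + exp(-(v + 102) / 15)),
    h_inf = 1 / (1 + exp((v + 80) / 5)),
    tau_h = 28.307 + 0.33 / (exp((v + 48) / 4) + exp(-(v + 407) / 50))
  )
}

#' @rdname gate-kinetics
#' @export
ahp_kinetics <- function(ca_i) {
  s <- 48 * ca_i^2
  tibble(m_inf = s / (s + 0.09), tau_m = 1 / (s + 0.09))
}

# ---- current densities ----

#' Ionic current densities of the HTC pacemaker cell
#'
#' `i_tht()` is the high-threshold T-type calcium current
#' `g * m_inf(v)^2 * h * (v - e_ca)` whose slow inactivation sets the burst
#' duration; `i_h_htc()` is the HCN h-current `g * r * (v - e_h)`,
#' depolarizing below its -40 mV reversal and hyperpolarizing above it;
#' `i_ahp()` is the calcium-activated potassium current `g * m^2 * (v - e_k)`.
#'
#' @param v membrane voltage (mV).
#' @param h,r,m gating variables in `[0, 1]`.
#' @param e_ca calcium reversal potential (mV), from [nernst_ca()].
#' @param g conductance density (mS/cm^2).
#' @param e_h,e_k reversal potentials (mV).
#' @return current density (uA/cm^2); positive = outward.
#' @name htc-currents
NULL

#' @rdname htc-currents
#' @export
i_tht <- function(v, h, e_ca, g = 12) {
  m <- tht_kinetics(v)$m_inf
  g * m^2 * h * (v - e_ca)
}

#' @rdname htc-currents
#' @export
i_h_htc <- function(v, r, g = 0.36, e_h = -40) g * r * (v - e_h)

#' @rdname htc-currents
#' @export
i_ahp <- function(v, m, g = 15, e_k = -100) g * m^2 * (v - e_k)

#' TC-cell calcium-regulated h-current
#'
#' `i = g * (o + a * (1 - c - o)) * (v - e_h)` with the conductance factor
#' clamped to `[0, 1 + a]`. The fractions `o` (open), `p` (calcium-bound
#' regulator) and `c` (closed/locked) evolve under the published first-order
#' rates (see [tc_h_derivs()]), each clamped to `[0, 1]`.
#'
#' @param v membrane voltage (mV).
#' @param o,c state fractions in `[0, 1]`.
#' @param g conductance (mS/cm^2).
#' @param a relative conductance of the locked-open pathway.
#' @param e_h reversal (mV).
#' @return current density (uA/cm^2).
#' @export
i_h_tc <- function(v, o, c, g = 0.1, a = 2, e_h = -43) {
  fac <- pmin(pmax(o + a * (1 - c - o), 0), 1 + a)
  g * fac * (v - e_h)
}

#' Time derivatives of the TC h-current state fractions
#'
#' Literal implementation of the published kinetics: `do/dt = k_o1*(1-c-o) -
#' k_o2*((1-p)/k_o3)`, `dp/dt = k_p1*(1-p) - k_p2*([Ca]/ca_ref)^2`,
#' `dc/dt = beta_c*o - alpha_c*c` with `alpha_c = h_inf/tau_s`,
#' `beta_c = (1-h_inf)/tau_s`.
#'
#' @param v voltage (mV); `o,p,c` fractions; `ca_i` calcium (mM).
#' @param pars a `"TC"` [cell_params()] list (supplies the rate constants).
#' @return named list `do`, `dp`, `dc` (1/ms).
#' @export
tc_h_derivs <- function(v, o, p, c, ca_i, pars = cell_params("TC")) {
  h_inf <- 1 / (1 + exp((v + 75) / 5.5))
  tau_s <- 20 + 1000 / (exp((v + 71.5) / 14.2) + exp(-(v + 89) / 11.6))
  list(
    do = pars$k_o1 * (1 - c - o) - pars$k_o2 * ((1 - p) / pars$k_o3),
    dp = pars$k_p1 * (1 - p) - pars$k_p2 * (ca_i / pars$ca_ref)^2,
    dc = (1 - h_inf) / tau_s * o - h_inf / tau_s * c
  )
}

# ---- pure-R reference stepper for a single HTC cell -------------------------
# Kept deliberately independent of the C++ engine: used in tests as the
# cross-check that both integrate the same model.

#' Initial state of an isolated HTC cell
#'
#' Voltage at `v0`, gates at their steady state for `v0`, calcium at rest.
#'
#' @param v0 initial voltage (mV).
#' @param ca calcium-handling constants, see [calcium_constants()].
#' @return named list of state variables.
#' @export
htc_init <- function(v0 = -70, ca = calcium_constants()) {
  r <- rate_na_k(v0 + 25)
  list(
    v = v0,
    n = r$alpha_n / (r$alpha_n + r$beta_n),
    m = r$alpha_m / (r$alpha_m + r$beta_m),
    h = r$alpha_h / (r$alpha_h + r$beta_h),
    h_tlt = tlt_kinetics(v0)$h_inf,
    h_tht = tht_kinetics(v0)$h_inf,
    r_h = h_gate_kinetics(v0)$r_inf,
    m_ahp = ahp_kinetics(ca$ca_rest)$m_inf,
    ca_i = ca$ca_rest
  )
}

#' One forward-Euler step of an isolated HTC cell
#'
#' Advances voltage, all gates (clamped to `[0, 1]`) and the shared calcium
#' pool by one explicit Euler step of the HTC membrane equation
#' `C dV/dt = -I_Na - I_K - I_TLT - I_THT - I_L - I_H - I_AHP + I_app`.
#' This is the slow reference implementation; network simulations use the
#' compiled engine in [simulate_network()].
#'
#' @param state list from [htc_init()].
#' @param pars HTC [cell_params()].
#' @param dt time step (ms).
#' @param i_ext additional external current density (uA/cm^2, + = inward
#'   drive added to the right-hand side like `I_app`).
#' @param ca calcium constants.
#' @return updated state list, with the step's total current in `$i_total`.
#' @export
htc_step <- function(state, pars = cell_params("HTC"), dt = 0.01, i_ext = 0,
                     ca = calcium_constants()) {
  if (dt <= 0) abort("`dt` must be > 0")
  s <- state
  bad <- !vapply(s, is.finite, logical(1))
  if (any(bad)) abort(paste("non-finite state variable:",
                            paste(names(s)[bad], collapse = ", ")))
  v <- s$v
  rr <- rate_na_k(v + pars$v_shift_nak)
  e_ca <- nernst_ca(s$ca_i, ca$ca_o, ca$temperature)
  kin_tlt <- tlt_kinetics(v)
  kin_tht <- tht_kinetics(v)
  kin_r <- h_gate_kinetics(v)
  kin_ahp <- ahp_kinetics(s$ca_i)

  i_na <- pars$g_na * s$m^3 * s$h * (v - pars$e_na)
  i_k <- pars$g_k * s$n^4 * (v - pars$e_k)
  i_tlt_ <- pars$g_tlt * kin_tlt$m_inf^2 * s$h_tlt * (v - e_ca)
  i_tht_ <- pars$g_tht * kin_tht$m_inf^2 * s$h_tht * (v - e_ca)
  i_l <- pars$g_l * (v - pars$e_l) + pars$g_kl * (v - pars$e_kl)
  i_h_ <- pars$g_h * s$r_h * (v - pars$e_h)
  i_ahp_ <- pars$g_ahp * s$m_ahp^2 * (v - pars$e_k)
  i_total <- i_na + i_k + i_tlt_ + i_tht_ + i_l + i_h_ + i_ahp_

  cl <- function(x) min(max(x, 0), 1)
  s$n <- cl(s$n + dt * (rr$alpha_n * (1 - s$n) - rr$beta_n * s$n))
  s$m <- cl(s$m + dt * (rr$alpha_m * (1 - s$m) - rr$beta_m * s$m))
  s$h <- cl(s$h + dt * (rr$alpha_h * (1 - s$h) - rr$beta_h * s$h))
  s$h_tlt <- cl(s$h_tlt + dt * (kin_tlt$h_inf - s$h_tlt) / kin_tlt$tau_h)
  s$h_tht <- cl(s$h_tht + dt * (kin_tht$h_inf - s$h_tht) / kin_tht$tau_h)
  s$r_h <- cl(s$r_h + dt * (kin_r$r_inf - s$r_h) / kin_r$tau_r)
  s$m_ahp <- cl(s$m_ahp + dt * (kin_ahp$m_inf - s$m_ahp) / kin_ahp$tau_m)
  s$ca_i <- update_calcium(s$ca_i, i_tlt_ + i_tht_, dt,
                           tau = ca$tau_htc, ca_rest = ca$ca_rest)
  s$v <- v + dt * (-i_total + pars$i_app + i_ext) / pars$c_m
  s$i_total <- i_total
  s
}
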