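test_that("Na/K rate constants handle removable singularities and scale correctly", {
  # limits of the 0/0 forms
  expect_equal(rate_na_k(15)$alpha_n, 0.032 * 5, tolerance = 1e-9)
  expect_equal(rate_na_k(13)$alpha_m, 0.32 * 4, tolerance = 1e-9)
  expect_equal(rate_na_k(40)$beta_m, 0.28 * 5, tolerance = 1e-9)
  # zero exponent
  expect_equal(rate_na_k(10)$beta_n, 0.5)
  # continuity across the singular point
  r <- rate_na_k(c(14.999999, 15, 15.000001))
  expect_lt(diff(range(r$alpha_n)), 1e-6)
  # all rates non-negative over a wide voltage range
  rr <- rate_na_k(seq(-120, 80, by = 0.5))
  expect_true(all(as.matrix(rr) >= 0))
  expect_error(rate_na_k(NaN), "finite")
})

test_that("steady state and time constant follow from rate pairs", {
  expect_equal(steady_state_tau(1, 1), tibble::tibble(x_inf = 0.5, tau = 0.5))
  expect_equal(steady_state_tau(0, 2), tibble::tibble(x_inf = 0, tau = 0.5))
  s <- steady_state_tau(0.16, 0.5)
  expect_equal(s$x_inf, 0.16 / 0.66, tolerance = 1e-12)  # 0.2424...
  expect_equal(s$tau, 1 / 0.66, tolerance = 1e-12)       # 1.5151...
  expect_error(steady_state_tau(0, 0), "degenerate")
})

test_that("T-type and h-current gating kinetics have the printed midpoints", {
  # high-threshold T current: m midpoint -40.1 mV, h midpoint -62.2 mV
  expect_equal(tht_kinetics(-40.1)$m_inf, 0.5)
  expect_equal(tht_kinetics(-62.2)$h_inf, 0.5)
  # HTC h-current gate: midpoint -60 mV; tau_r at -74 mV by direct evaluation
  expect_equal(h_gate_kinetics(-60)$r_inf, 0.5)
  expect_equal(h_gate_kinetics(-74)$tau_r,
               20 + 1000 / (exp(-17.5 / 14.2) + exp(0)), tolerance = 1e-12)
  # low-threshold T current midpoints at the +2 mV shifted voltage
  expect_equal(tlt_kinetics(-59)$m_inf, 0.5)
  expect_equal(tlt_kinetics(-83)$h_inf, 0.5)
  # AHP midpoint at [Ca] = sqrt(0.09/48), with tau = 1/0.18 there
  ca_mid <- sqrt(0.09 / 48)
  k <- ahp_kinetics(ca_mid)
  expect_equal(k$m_inf, 0.5)
  expect_equal(k$tau_m, 1 / 0.18)
  expect_equal(ahp_kinetics(0)$tau_m, 1 / 0.09)
  expect_equal(ahp_kinetics(0)$m_inf, 0)
})

test_that("HTC currents reverse and scale as specified", {
  # h-current reverses exactly at E_h = -40 mV and flips sign around it
  expect_equal(i_h_htc(-40, r = 0.7), 0)
  expect_lt(i_h_htc(-60, r = 0.5), 0)   # depolarizing (inward) below E_h
  expect_gt(i_h_htc(-20, r = 0.5), 0)   # hyperpolarizing above E_h
  # zero conductance kills the high-threshold calcium current everywhere
  expect_equal(i_tht(seq(-80, 0, by = 10), h = 0.5, e_ca = 120, g = 0), rep(0, 9))
  expect_equal(i_ahp(-50, m = 0.3, g = 0), 0)
  # TC h-current: o = c = 0 gives conductance factor a = 2; reversal at -43
  expect_equal(i_h_tc(-50, o = 0, c = 0), 0.1 * 2 * (-50 + 43))
  expect_equal(i_h_tc(-43, o = 0.4, c = 0.1), 0)
  # factor clamping
  expect_equal(i_h_tc(-50, o = 0, c = 1), 0)          # factor would be 0
  expect_equal(i_h_tc(-53, o = 1, c = 0), 0.1 * 1 * (-53 + 43))
})

test_that("TC h-current c-gate fixed point satisfies c = (1 - h_inf)/h_inf * o", {
  v <- -70; o <- 0.3
  h_inf <- 1 / (1 + exp((v + 75) / 5.5))
  c_star <- (1 - h_inf) / h_inf * o
  d <- tc_h_derivs(v, o = o, p = 0.5, c = c_star, ca_i = 0.00024)
  expect_equal(d$dc, 0, tolerance = 1e-12)
  # numerically: iterating the c equation converges to the fixed point
  cc <- 0  # rates are ~1e-4/ms, so a 1-ms Euler step is stable
  for (i in 1:20000) cc <- cc + 1 * tc_h_derivs(v, o, 0.5, cc, 0.00024)$dc
  expect_equal(cc, c_star, tolerance = 1e-2)
})

test_that("calcium reversal potential follows the Nernst equation", {
  expect_equal(nernst_ca(2, 2), 0)
  expect_equal(nernst_ca(0.00024, 2), 120.1, tolerance = 0.1)
  # doubling extracellular calcium adds (RT/2F) ln 2 ~ 9.23 mV
  inc <- nernst_ca(0.00024, 4) - nernst_ca(0.00024, 2)
  expect_equal(inc, 1000 * 8.314462618 * 309.15 / (2 * 96485.33212) * log(2),
               tolerance = 1e-9)
  expect_equal(inc, 9.23, tolerance = 0.01)
  expect_error(nernst_ca(0, 2), "> 0")
  expect_error(nernst_ca(0.001, -1), "> 0")
})

test_that("calcium pool: fixed point, rectified influx, exponential decay", {
  # resting level is a fixed point with no calcium current
  expect_equal(update_calcium(0.00024, 0, dt = 0.01), 0.00024)
  # outward (positive) current is rectified: pure decay
  expect_equal(update_calcium(0.001, +50, dt = 0.01, tau = 3),
               update_calcium(0.001, 0, dt = 0.01, tau = 3))
  # inward current raises calcium
  expect_gt(update_calcium(0.00024, -100, dt = 0.01), 0.00024)
  # with zero current the pool follows the analytic exponential; the Euler
  # error halves with dt (first-order convergence)
  decay_err <- function(dt) {
    ca <- 0.001
    for (i in seq_len(round(3 / dt))) ca <- update_calcium(ca, 0, dt, tau = 3)
    abs(ca - (0.00024 + (0.001 - 0.00024) * exp(-1)))
  }
  e1 <- decay_err(0.01); e2 <- decay_err(0.005)
  expect_lt(e1 / (0.001 - 0.00024), 1e-3)
  expect_equal(e1 / e2, 2, tolerance = 0.05)
  expect_true(update_calcium(1e-10, +10, 0.01) > 0)
})

test_that("gates stay in [0,1] and calcium positive under random strong drive", {
  set.seed(7)
  for (rep in 1:5) {
    s <- htc_init(v0 = runif(1, -90, -50))
    g_lo <- 0; g_hi <- 1; ca_min <- Inf
    for (i in 1:400) {
      s <- htc_step(s, dt = 0.01, i_ext = rnorm(1, 0, 40))
      gates <- unlist(s[c("n", "m", "h", "h_tlt", "h_tht", "r_h", "m_ahp")])
      g_lo <- min(g_lo, gates); g_hi <- max(g_hi, gates)
      ca_min <- min(ca_min, s$ca_i)
    }
    expect_gte(g_lo, 0); expect_lte(g_hi, 1); expect_gt(ca_min, 0)
  }
})

test_that("passive membrane settles at the leak-weighted reversal (-85 mV)", {
  cfg <- quick_htc(duration = 2000,
                   htc = list(g_na = 0, g_k = 0, g_tlt = 0, g_tht = 0,
                              g_h = 0, g_ahp = 0))
  sim <- simulate_htc(cfg)
  v_end <- tail(sim$v[, 1], 1)
  expect_equal(v_end, (0.01 * -70 + 0.01 * -100) / 0.02, tolerance = 1e-6)
})

test_that("compiled engine reproduces the pure-R reference HTC stepper", {
  cfg <- quick_htc(duration = 1200, transient = 0)
  sim <- simulate_htc(cfg)
  s <- htc_init()
  n_steps <- 10000  # 100 ms
  v_ref <- numeric(n_steps %/% 40)
  for (i in seq_len(n_steps)) {
    s <- htc_step(s, dt = 0.01)
    if (i %% 40 == 0) v_ref[i / 40] <- s$v
  }
  v_eng <- sim$v[2:(length(v_ref) + 1), 1]
  expect_lt(max(abs(v_eng - v_ref)), 1e-6)
})

test_that("cell_params validates inputs and carries printed defaults", {
  h <- cell_params("HTC")
  expect_equal(h$g_h, 0.36)
  expect_equal(h$g_tht, 12)
  expect_equal(h$g_ahp, 15)
  expect_equal(h$g_na, 90)
  r <- cell_params("RE")
  expect_equal(r$g_na, 100)
  expect_equal(r$g_tre, 2.3)
  expect_equal(r$g_kl, 0.08)
  expect_equal(cell_params("TC")$g_kl, 0.0028)
  expect_error(cell_params("HTC", g_na = -1), "conductances")
  expect_error(cell_params("HTC", nonsense = 2), "unknown")
  expect_error(htc_step(list(v = NaN), dt = 0.01), "non-finite")
})
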