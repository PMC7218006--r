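test_that("receptor binding kinetics: fixed points, decay and Hill activation", {
  # sustained 0.5 mM transmitter drives AMPA receptors to 0.98*0.5/(0.98*0.5+0.18)
  expect_equal(synapse_fixed_point("AMPA"), 0.49 / 0.67, tolerance = 1e-12)
  expect_equal(synapse_fixed_point("AMPA"), 0.7313, tolerance = 1e-4)
  expect_equal(synapse_fixed_point("GABA_A"), 10 / 10.18, tolerance = 1e-12)
  # GABA-B G-protein Hill factor half-saturates at [G] = 100^(1/4)
  expect_equal(gabab_hill(100^0.25), 0.5)
  expect_equal(gabab_hill(0), 0)
  expect_lt(abs(gabab_hill(1e4) - 1), 1e-10)
  # with no transmitter, GABA_A receptors decay exponentially at 0.18/ms
  r <- 0.5; dt <- 0.001
  for (i in 1:2000) r <- r + dt * (20 * 0 * (1 - r) - 0.18 * r)
  expect_equal(r, 0.5 * exp(-0.18 * 2), tolerance = 1e-4)
})

test_that("receptor fraction stays in [0,1] for random pulse trains", {
  set.seed(11)
  for (kind in c("AMPA", "GABA_A", "GABA_B")) {
    k <- synapse_rates(kind)
    for (rep in 1:3) {
      pulses <- sort(runif(30, 0, 200))
      r <- 0; dt <- 0.01; r_min <- 0; r_max <- 0
      for (t in seq(0, 250, by = dt)) {
        on <- any(t >= pulses & t <= pulses + 1.0)
        T_ <- if (on) 0.5 else 0
        r <- r + dt * (k$bind * T_ * (1 - r) - k$unbind * r)
        r_min <- min(r_min, r); r_max <- max(r_max, r)
      }
      expect_gte(r_min, -1e-12)
      expect_lte(r_max, 1)
    }
  }
})

test_that("gap junctions are ohmic, antisymmetric and charge conserving", {
  expect_equal(gap_current(-60, -60, 0.004), 0)
  expect_equal(gap_current(-50, -70, 0.004), 0.08)
  expect_equal(gap_current(-50, -70, 0.004) + gap_current(-70, -50, 0.004), 0)
  expect_error(gap_current(NaN, -70), "finite")
})

test_that("cholinergic modulation maps eta to the potassium leak and back", {
  expect_equal(apply_ach(0, 0.01), 0.01)
  expect_equal(apply_ach(20, 0.01), 0.008)
  expect_equal(eta_from_gkleak(0.008, 0.01), 20)
  eta <- seq(0, 99, by = 7)
  expect_equal(eta_from_gkleak(apply_ach(eta, 0.01), 0.01), eta)
  expect_error(apply_ach(150, 0.01), "negative conductance")
  expect_error(apply_ach(10, 0), "> 0")
})

test_that("default network topology matches the 2/8/10 motif", {
  net <- build_network()
  expect_equal(c(net$n_htc, net$n_tc, net$n_re), c(2, 8, 10))
  syn <- net$synapses
  counts <- table(syn$class)
  expect_equal(unname(counts[["tc_re_ampa"]]), 80)     # all-to-all 8 x 10
  expect_equal(unname(counts[["htc_re_ampa"]]), 20)
  expect_equal(unname(counts[["htc_tc_gabaa"]]), 16)
  expect_equal(unname(counts[["re_re_gabaa"]]), 90)    # no self-connections
  expect_equal(nrow(net$gap_junctions), 1)
  # TC cells (ids 3..10) contact only RE cells
  tc_ids <- 3:10
  tc_out <- syn[syn$pre %in% tc_ids, ]
  expect_true(all(tc_out$post >= 11))
  # every connection class has its printed conductance
  expect_equal(unique(syn$g_max[syn$class == "htc_tc_gabaa"]), 0.4)
  expect_equal(unique(syn$g_max[syn$class == "re_htc_gabaa"]), 0.0002)
  expect_equal(unique(syn$g_max[syn$class == "re_htc_gabab"]), 0.004)
  # pulse durations depend on the presynaptic type; HTC->TC carries the delay
  expect_equal(unique(syn$pulse[syn$class == "htc_tc_gabaa"]), 1.0)
  expect_equal(unique(syn$pulse[syn$class == "re_tc_gabaa"]), 0.3)
  expect_equal(unique(syn$pulse[syn$class == "tc_re_ampa"]), 0.5)
  expect_equal(unique(syn$pulse[syn$class == "htc_re_ampa"]), 0.3)
  expect_equal(unique(syn$delay[syn$class == "htc_tc_gabaa"]), 10)
  expect_equal(unique(syn$delay[syn$class != "htc_tc_gabaa"]), 0)
  expect_error(build_network(1), ">= 2")
  # scaled topology preserves the ratios
  net2 <- build_network(4)
  expect_equal(c(net2$n_htc, net2$n_tc, net2$n_re), c(4, 16, 20))
  expect_equal(nrow(net2$gap_junctions), 6)
})

test_that("zeroing all chemical conductances reduces the network to gap-coupled cells", {
  zero <- c(htc_re_ampa = 0, tc_re_ampa = 0, htc_tc_gabaa = 0,
            re_htc_gabaa = 0, re_htc_gabab = 0, re_tc_gabaa = 0,
            re_tc_gabab = 0, re_re_gabaa = 0)
  cfg_net <- sim_config(duration = 3000, noise = FALSE, conductances = zero)
  cfg_iso <- sim_config(duration = 3000, noise = FALSE, n_htc = 2)
  v_net <- simulate_network(cfg_net)$v[, 1:2]
  v_iso <- simulate_htc(cfg_iso)$v
  expect_identical(unname(v_net), unname(v_iso))
})

test_that("removing the delayed HTC->TC inhibition raises TC firing", {
  base <- simulate_network(sim_config(duration = 4000, seed = 3))
  cut <- simulate_network(sim_config(duration = 4000, seed = 3,
                                     conductances = c(htc_tc_gabaa = 0)))
  rate_tc <- function(sim) {
    fr <- firing_rates(sim)
    mean(fr$rate[fr$type == "TC"])
  }
  expect_gt(rate_tc(cut), rate_tc(base))
})
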