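test_that("spike detection counts upward threshold crossings only", {
  t <- seq(0, 1000, by = 0.4)
  # constructed 25-Hz spike train: narrow peaks above 0 every 40 ms
  v <- -70 + 90 * (t %% 40 < 1.2)
  spk <- detect_spikes(v, t)
  expect_equal(firing_rate(spk, 1000), 25, tolerance = 0.2)
  expect_length(detect_spikes(rep(-70, 100)), 0)
  expect_equal(firing_rate(numeric(0), 14000), 0)
  expect_equal(firing_rate(rep(1, 140), 14000), 10)
  # a crossing is counted once, at the first sample at/above threshold
  expect_equal(detect_spikes(c(-1, 1, 2, 1, -1, 2), threshold = 0), c(2, 6))
})

test_that("burst grouping splits spike trains at the intraburst cutoff", {
  expect_equal(detect_bursts(5)$n_spikes, 1L)
  b <- detect_bursts(cumsum(c(0, 2, 2, 95, 2, 2)), max_intraburst_isi = 25)
  expect_equal(nrow(b), 2)
  expect_equal(b$n_spikes, c(3L, 3L))
  expect_equal(b$onset, c(0, 99))
  expect_equal(b$offset - b$onset, c(4, 4))
  expect_equal(nrow(detect_bursts(numeric(0))), 0)
})

test_that("the LFP is the mean HTC voltage", {
  sim <- simulate_htc(quick_htc(duration = 2000, n_htc = 2))
  lfp <- compute_lfp(sim, discard_transient = FALSE)
  expect_equal(lfp$lfp, rowMeans(sim$v[, 1:2]))
  # constructed cases via a minimal object
  fake <- structure(list(
    time = c(0, 1, 2), v = cbind(HTC1 = c(-60, -60, 0), HTC2 = c(-40, 60, 0)),
    cell = c("HTC1", "HTC2"), type = c("HTC", "HTC"),
    config = list(transient = 0)), class = "thal_sim")
  expect_equal(compute_lfp(fake)$lfp, c(-50, 0, 0))
  fake$type <- c("TC", "TC")
  expect_error(compute_lfp(fake), "no HTC")
})

test_that("the interburst-interval rate matches the spectral peak on a periodic run", {
  sim <- simulate_network(sim_config(duration = 7000, noise = FALSE))
  f_ibi <- mean_burst_rate(sim)
  f_spec <- peak_frequency(power_spectrum(smooth_lfp(compute_lfp(sim))))
  expect_lt(abs(f_ibi - f_spec), 0.5)
})

test_that("an isolated cell neither diverges nor drifts over long runs", {
  sim <- cached_htc_run()
  expect_true(all(is.finite(sim$v)))
  expect_true(all(sim$v > -110 & sim$v < 70))
  # burst pattern is a stable limit cycle: late IBIs match earlier ones
  keep <- sim$time >= 2000  # settle onto the limit cycle first
  st <- detect_spikes(sim$v[keep, 1], sim$time[keep])
  b <- detect_bursts(st)
  ibi <- diff(b$onset)
  n <- length(ibi)
  expect_equal(mean(ibi[1:10]), mean(ibi[(n - 9):n]), tolerance = 0.01)
})

test_that("simulation accessors return tidy structures", {
  sim <- simulate_htc(quick_htc(duration = 2000))
  td <- tidy(sim)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("time", "cell", "type", "v"))
  expect_equal(nrow(td), length(sim$time))
  g <- glance(sim, threshold = 5)
  expect_equal(nrow(g), 1)
  expect_true(all(c("peak_freq", "entropy", "periodic", "burst_rate",
                    "rate_htc", "g_h", "seed") %in% names(g)))
  fr <- firing_rates(sim)
  expect_named(fr, c("cell", "type", "n_spikes", "rate"))
  expect_output(print(sim), "thal_sim")
  expect_error(sim_config(record_interval = 0.025), "integer multiple")
  expect_error(sim_config(duration = 500, transient = 1000), "exceed")
})
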