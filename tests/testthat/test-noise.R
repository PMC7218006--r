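test_that("white-noise increments have the configured scaling and moments", {
  expect_equal(white_noise_increment(100, variance = 0), rep(0, 100))
  set.seed(1)
  # standard Euler-Maruyama: variance of the sum over 1 ms equals 0.1 * 1 ms
  n_per_ms <- 100  # dt = 0.01
  x <- matrix(white_noise_increment(n_per_ms * 20000, dt = 0.01,
                                    scaling_mode = "standard_em"),
              nrow = n_per_ms)
  v <- var(colSums(x))
  expect_equal(v, 0.1, tolerance = 0.05)
  # mean of many increments is 0 within 4 standard errors
  m <- mean(x)
  expect_lt(abs(m), 4 * sqrt(0.1 * 0.01) / sqrt(length(x)))
  # as-printed scaling is sqrt(dt) weaker per step
  set.seed(2)
  a <- white_noise_increment(5e4, dt = 0.01, scaling_mode = "as_printed")
  set.seed(2)
  b <- white_noise_increment(5e4, dt = 0.01, scaling_mode = "standard_em")
  expect_equal(sd(a) / sd(b), sqrt(0.01), tolerance = 0.01)
  # identical seeds give identical draws
  set.seed(3); x1 <- white_noise_increment(100)
  set.seed(3); x2 <- white_noise_increment(100)
  expect_identical(x1, x2)
})

test_that("Poisson impulse trains have exponential intervals at the stated mean", {
  set.seed(5)
  tr <- sample_impulse_train(14000 * 10, mean_isi = 10)
  n_exp <- 14000 * 10 / 10
  expect_lt(abs(length(tr) - n_exp), 4 * sqrt(n_exp))
  expect_true(all(diff(tr) > 0))
  expect_true(all(tr < 14000 * 10))
  ks <- suppressWarnings(stats::ks.test(diff(tr), "pexp", rate = 1 / 10))
  expect_gt(ks$p.value, 0.01)
  # a duration shorter than the first interval gives an empty train
  set.seed(42)
  first <- rexp(1, 1 / 10)
  set.seed(42)
  expect_length(sample_impulse_train(first * 0.5, mean_isi = 10), 0)
})

test_that("PSP kernel uses the most recent impulse with a 1-ms time constant", {
  imp <- c(10, 30)
  # at an impulse the kernel is at its peak: |I| = g_s * |V - e_rev|
  expect_equal(psp_current(imp, 10, v_post = -60, g_s = 1, e_rev = 0), 60)
  # 1 ms later the kernel has decayed by e^-1
  expect_equal(psp_current(imp, 11, -60, 1, 0), 60 * exp(-1))
  # a later impulse resets the clock (no summation over history)
  expect_equal(psp_current(imp, 30.5, -60, 1, 0), 60 * exp(-0.5))
  # zero at the reversal potential and before the first impulse
  expect_equal(psp_current(imp, 15, 0, 1, 0), 0)
  expect_equal(psp_current(imp, 5, -60, 1, 0), 0)
  expect_error(psp_current(c(3, 1), 2, -60, 1), "sorted")
  # injected charge scales linearly with g_s
  tt <- seq(0, 50, by = 0.01)
  q1 <- sum(psp_current(imp, tt, -60, 0.015, e_rev = -85))
  q2 <- sum(psp_current(imp, tt, -60, 0.030, e_rev = -85))
  expect_equal(q2, 2 * q1, tolerance = 1e-12)
})

test_that("simulations are bitwise reproducible and deterministic without noise", {
  cfg <- sim_config(duration = 2500, seed = 99)
  s1 <- simulate_network(cfg)
  s2 <- simulate_network(cfg)
  expect_identical(s1$v, s2$v)
  expect_identical(s1$spikes, s2$spikes)
  # different seeds give different noisy trajectories
  s3 <- simulate_network(sim_config(duration = 2500, seed = 100))
  expect_false(identical(s1$v, s3$v))
  # with all noise off, seed is irrelevant
  d1 <- simulate_network(sim_config(duration = 2500, noise = FALSE, seed = 1))
  d2 <- simulate_network(sim_config(duration = 2500, noise = FALSE, seed = 2))
  expect_identical(d1$v, d2$v)
})
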