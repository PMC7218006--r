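make_wave <- function(f, dur_s = 4, fs = 2500, amp = 1) {
  t <- seq(0, dur_s, by = 1 / fs)
  amp * sin(2 * pi * f * t)
}

test_that("LFP smoothing: constant, linear and attenuation behaviour", {
  expect_equal(smooth_lfp(rep(-60, 100)), rep(0, 76))
  # moving average of a ramp is the ramp delayed by (window-1)/2 = 12 samples
  x <- seq_len(200)
  sm <- smooth_lfp(x)
  expect_equal(diff(sm), rep(1, 175))
  expect_equal(sm, (x[25:200] - 12) - mean(x))
  # 60-Hz power is strongly attenuated relative to 10 Hz
  gain <- function(f) {
    x <- make_wave(f)
    sd(smooth_lfp(x)) / sd(x)
  }
  expect_gt(gain(10), 0.9)
  expect_lt(gain(60) / gain(10), 0.6)   # ~0.5: the damping setting in above 60 Hz
  expect_lt(gain(100) / gain(10), 0.05) # window null at 100 Hz
  expect_error(smooth_lfp(1:10), "smoothing window")
  # tibble in, tibble out, time axis preserved
  df <- tibble::tibble(time = seq(0, 39.6, by = 0.4), lfp = rep(1, 100))
  out <- smooth_lfp(df)
  expect_equal(out$time[1], df$time[25])
})

test_that("power spectrum: normalization, Parseval, sinusoid peak", {
  x <- smooth_lfp(make_wave(10, dur_s = 13))
  sp <- power_spectrum(x)
  expect_equal(sum(sp$p), 1, tolerance = 1e-12)
  expect_true(all(sp$p >= 0))
  # peak frequency within one grid bin of 10 Hz
  expect_equal(peak_frequency(sp), 10, tolerance = 1 / 13 + 1e-9)
  # Parseval: sum |F|^2 over all bins equals N * sum |x|^2
  full <- Mod(fft(x))^2
  expect_equal(sum(full), length(x) * sum(x^2), tolerance = 1e-6)
  expect_error(power_spectrum(rep(0, 100)), "all-zero")
})

test_that("spectral entropy: bounds, invariances and degenerate cases", {
  one_bin <- tibble::tibble(freq = 0:3, p = c(0, 1, 0, 0))
  expect_equal(spectral_entropy(one_bin), 0)
  n <- 64
  unif <- tibble::tibble(freq = seq_len(n), p = rep(1 / n, n))
  expect_equal(spectral_entropy(unif), log(n))
  expect_error(spectral_entropy(tibble::tibble(p = c(0.5, 0.4))), "normalized")
  # invariant under LFP amplitude scaling
  e1 <- spectral_entropy(power_spectrum(smooth_lfp(make_wave(9))))
  e2 <- spectral_entropy(power_spectrum(smooth_lfp(make_wave(9, amp = 50))))
  expect_equal(e1, e2, tolerance = 1e-9)
  # permutation invariant; zero-power bins contribute nothing
  set.seed(8)
  p <- runif(50); p <- p / sum(p)
  ent <- function(p) spectral_entropy(tibble::tibble(p = p))
  expect_equal(ent(sample(p)), ent(p))
  expect_equal(ent(c(p, rep(0, 30))), ent(p))
  # broadband noise carries much higher entropy than a pure tone
  set.seed(9)
  e_noise <- spectral_entropy(power_spectrum(smooth_lfp(rnorm(10000))))
  e_tone <- spectral_entropy(power_spectrum(smooth_lfp(make_wave(10))))
  expect_gt(e_noise, e_tone + 2)
})

test_that("peak frequency recovers synthetic rhythms and prefers the fundamental", {
  for (f in c(5, 8, 10, 12)) {
    sp <- power_spectrum(smooth_lfp(make_wave(f)))
    expect_equal(peak_frequency(sp), f, tolerance = 1 / 4 + 1e-9)
  }
  # a waveform whose 2nd harmonic slightly dominates is still reported at f0
  t <- seq(0, 4, by = 1 / 2500)
  x <- sin(2 * pi * 9 * t) + 1.1 * sin(2 * pi * 18 * t)
  sp <- power_spectrum(smooth_lfp(x))
  expect_equal(peak_frequency(sp), 9, tolerance = 0.3)
  expect_equal(peak_frequency(sp, fundamental_ratio = Inf), 18, tolerance = 0.3)
  expect_error(peak_frequency(sp, band = c(2000, 3000)), "search band")
})

test_that("periodicity classification is strict at the threshold", {
  expect_true(classify_periodicity(0, 5))
  expect_false(classify_periodicity(5, 5))
  expect_false(classify_periodicity(5.1, 5))
})
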