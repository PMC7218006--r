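# Short-run configurations used across test files. Durations are deliberately
# small; anything asserting paper-scale behaviour lives in test-acceptance.R.

quick_htc <- function(duration = 4000, n_htc = 1, noise = FALSE, ...) {
  sim_config(duration = duration, n_htc = n_htc, noise = noise, ...)
}

# mean HTC burst rate of a simulation (Hz)
mean_burst_rate <- function(sim) mean(burst_stats(sim)$burst_rate)

# one long noise-free single-cell run shared by several tests
cached_htc_run <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- simulate_htc(quick_htc(duration = 14000))
    val
  }
})
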