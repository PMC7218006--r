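#' Tidy a simulation into a long trace tibble
#'
#' @param x a `thal_sim`.
#' @param discard_transient drop samples before the configured transient.
#' @param ... unused.
#' @return tibble with `time` (ms), `cell`, `type`, `v` (mV).
#' @export
tidy.thal_sim <- function(x, discard_transient = FALSE, ...) {
  keep <- if (discard_transient) x$time >= x$config$transient else TRUE
  out <- as_tibble(x$v[keep, , drop = FALSE])
  out$time <- x$time[keep]
  out <- tidyr::pivot_longer(out, -"time", names_to = "cell", values_to = "v")
  out$type <- x$type[match(out$cell, x$cell)]
  select(out, "time", "cell", "type", "v")
}

#' One-row rhythm summary of a simulation
#'
#' @param x a `thal_sim`.
#' @param threshold optional periodicity threshold (nats).
#' @param ... passed to [rhythm_summary()].
#' @return one-row tibble: run settings plus the [rhythm_summary()] columns.
#' @export
glance.thal_sim <- function(x, threshold = NULL, ...) {
  mutate(rhythm_summary(x, threshold = threshold, ...),
         g_h = x$config$g_h, eta_ach = x$config$eta_ach,
         g_tht_scale = x$config$g_tht_scale,
         duration = x$config$duration, seed = x$config$seed)
}

#' @export
tidy.gh_sweep <- function(x, ...) x$results

#' @export
glance.gh_sweep <- function(x, ...) {
  tibble(lower_boundary = x$lower_boundary, upper_boundary = x$upper_boundary,
         threshold = x$threshold, n_points = nrow(x$by_point))
}

#' @export
tidy.ach_rescue <- function(x, ...) x$results

#' @export
glance.ach_rescue <- function(x, ...) {
  tibble(g_h_fraction = x$g_h_fraction, rescue_eta = x$rescue_eta,
         breakdown_eta = x$breakdown_eta,
         max_periodic_freq = x$max_periodic_freq, threshold = x$threshold)
}

#' @export
tidy.thal_map <- function(x, ...) x$results

#' @export
glance.thal_map <- function(x, ...) {
  tibble(n_points = nrow(x$by_point),
         n_periodic = sum(x$by_point$periodic), threshold = x$threshold)
}

#' @export
tidy.rate_cascade <- function(x, ...) x$results

#' @export
glance.rate_cascade <- function(x, ...) {
  tibble(cor_htc_tc = x$cor_htc_tc, cor_tc_re = x$cor_tc_re,
         n_points = nrow(x$by_point))
}

#' @export
tidy.ca_tolerance <- function(x, ...) x$results

#' @export
glance.ca_tolerance <- function(x, ...) x$profile
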