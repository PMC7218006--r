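#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_hline geom_vline
#'   geom_tile facet_wrap facet_grid labs scale_fill_viridis_c vars
NULL

#' Plot voltage traces of a simulation
#'
#' @param object a `thal_sim`.
#' @param cells cell names to show (default: first cell of each type).
#' @param window optional `c(from, to)` time window (ms).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.thal_sim <- function(object, cells = NULL,
                              window = NULL, ...) {
  if (is.null(cells)) cells <- object$cell[!duplicated(object$type)]
  df <- filter(tidy.thal_sim(object), .data$cell %in% cells)
  if (!is.null(window)) {
    df <- filter(df, .data$time >= window[1], .data$time <= window[2])
  }
  ggplot(df, aes(x = .data$time / 1000, y = .data$v)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(vars(.data$cell), ncol = 1) +
    labs(x = "time (s)", y = "membrane voltage (mV)")
}

#' Plot a power spectrum
#'
#' @param object a `thal_spectrum`.
#' @param band frequency band to display (Hz).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.thal_spectrum <- function(object, band = c(0, 40), ...) {
  df <- filter(as_tibble(object), .data$freq >= band[1], .data$freq <= band[2])
  ggplot(df, aes(x = .data$freq, y = .data$p)) +
    geom_line() +
    labs(x = "frequency (Hz)", y = "normalized power")
}

#' Plot an HCN-expression sweep
#'
#' Peak frequency and spectral entropy against the HCN conductance, with the
#' stable-region boundaries marked.
#'
#' @param object a `gh_sweep`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.gh_sweep <- function(object, ...) {
  df <- tidyr::pivot_longer(object$by_point, c("peak_freq", "entropy"),
                            names_to = "measure")
  ggplot(df, aes(x = .data$g_h, y = .data$value)) +
    geom_point() + geom_line() +
    geom_vline(xintercept = c(object$lower_boundary, object$upper_boundary),
               linetype = 2) +
    facet_wrap(vars(.data$measure), scales = "free_y", ncol = 1) +
    labs(x = "g_H (mS/cm^2)", y = NULL)
}

#' Plot a cholinergic-rescue sweep
#'
#' @param object an `ach_rescue`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ach_rescue <- function(object, ...) {
  df <- tidyr::pivot_longer(object$by_point, c("peak_freq", "entropy"),
                            names_to = "measure")
  p <- ggplot(df, aes(x = .data$eta_ach, y = .data$value)) +
    geom_point() + geom_line() +
    facet_wrap(vars(.data$measure), scales = "free_y", ncol = 1) +
    labs(x = "eta_ach (%)", y = NULL)
  if (!is.na(object$rescue_eta)) {
    p <- p + geom_vline(xintercept = object$rescue_eta, linetype = 2)
  }
  p
}

#' Plot the 2-D stability map
#'
#' @param object a `thal_map`.
#' @param ... unused.
#' @return a ggplot (entropy tiles; periodic points outlined).
#' @export
autoplot.thal_map <- function(object, ...) {
  ggplot(object$by_point, aes(x = .data$g_h, y = .data$eta_ach)) +
    geom_tile(aes(fill = .data$entropy)) +
    geom_point(data = filter(object$by_point, .data$periodic), size = 0.8) +
    scale_fill_viridis_c() +
    labs(x = "g_H (mS/cm^2)", y = "eta_ach (%)", fill = "entropy (nats)")
}

#' Plot the firing-rate cascade
#'
#' @param object a `rate_cascade`.
#' @param ... unused.
#' @return a ggplot of population rates vs the HTC burst rate.
#' @export
autoplot.rate_cascade <- function(object, ...) {
  df <- tidyr::pivot_longer(object$by_point, c("rate_tc", "rate_re"),
                            names_to = "population", values_to = "rate")
  ggplot(df, aes(x = .data$burst_rate, y = .data$rate,
                 colour = .data$population)) +
    geom_point() + geom_line() +
    labs(x = "HTC burst rate (Hz)", y = "mean firing rate (Hz)")
}

#' Plot calcium-conductance tolerance profiles
#'
#' @param object a `ca_tolerance`.
#' @param ... unused.
#' @return a ggplot of tolerated calcium-conductance increase vs HCN level.
#' @export
autoplot.ca_tolerance <- function(object, ...) {
  ggplot(object$profile, aes(x = .data$g_h, y = .data$tolerance)) +
    geom_point() + geom_line() +
    labs(x = "g_H (mS/cm^2)", y = "tolerated g_THT increase (%)")
}
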