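#' Detect spikes in a voltage trace
#'
#' One spike per upward threshold crossing, with a refractory lockout so
#' noisy re-crossings within a spike are not double-counted. Spike time
#' is the (linearly interpolated) crossing time.
#'
#' @param trace A data frame with columns `time` (ms) and `v` (mV), or a
#'   `neuron_sim` object.
#' @param threshold Crossing threshold (mV). 0 mV is unambiguous for
#'   full-height action potentials.
#' @param lockout Minimum spacing between detected spikes (ms).
#' @return Numeric vector of spike times (ms).
#' @export
detect_spikes <- function(trace, threshold = 0, lockout = 1) {
  if (inherits(trace, "neuron_sim")) trace <- trace$trace
  if (!all(c("time", "v") %in% names(trace)))
    stop_bad_input("trace needs columns time and v")
  if (any(!is.finite(trace$v))) stop_bad_input("voltage trace must be finite")
  crossing_times(trace$time, trace$v, threshold, lockout)
}

#' Vector strength of phase locking
#'
#' The mean resultant length of spike phases relative to a periodic
#' stimulus at frequency `f`: \eqn{VS = |N^{-1} \sum_k e^{i 2\pi f
#' t_k}|}. 1 means perfect locking, 0 uniform firing across the cycle.
#' Following the convention that vector strength is only meaningful when
#' a train elicits more than 4 spikes, `NA` is returned (an explicit
#' "undefined" flag, not 0) when `length(spikes) < min_spikes`.
#'
#' @param spikes Spike times (ms).
#' @param frequency Stimulus/input frequency (Hz).
#' @param min_spikes Minimum spike count for a defined value (default 5,
#'   i.e. strictly more than 4 spikes).
#' @return Vector strength in \[0, 1\], or `NA` when undefined.
#' @export
#' @examples
#' vector_strength(seq(0, 999, by = 62.5), 16) # perfectly locked
vector_strength <- function(spikes, frequency, min_spikes = 5) {
  if (!is.finite(frequency) || frequency <= 0)
    stop_bad_input("frequency must be > 0")
  if (length(spikes) < min_spikes) return(NA_real_)
  ph <- 2 * pi * frequency * spikes / 1000
  sqrt(mean(cos(ph))^2 + mean(sin(ph))^2)
}

#' Circular mean phase of firing
#'
#' The circular mean of spike phases relative to the stimulus cycle
#' (phase 0 at each input-pulse onset / modulation-cycle start), reported
#' in \[0, 2\eqn{\pi}). Undefined (`NA`) under the same spike-count gate
#' as [vector_strength()].
#'
#' @inheritParams vector_strength
#' @return Mean phase in radians, or `NA` when undefined.
#' @export
mean_phase <- function(spikes, frequency, min_spikes = 5) {
  if (!is.finite(frequency) || frequency <= 0)
    stop_bad_input("frequency must be > 0")
  if (length(spikes) < min_spikes) return(NA_real_)
  ph <- 2 * pi * frequency * spikes / 1000
  m <- atan2(mean(sin(ph)), mean(cos(ph))) %% (2 * pi)
  if (2 * pi - m < 1e-9) m <- 0 # wrap numerical 2*pi back to phase zero
  m
}

#' Evoked and spontaneous firing rates
#'
#' Firing rate during stimulus windows and between them, each as the
#' mean of per-window rates across repetitions (spikes/s).
#'
#' @param spikes Spike times (ms).
#' @param stim_windows Data frame with columns `start`, `end` (ms), one
#'   row per stimulus presentation.
#' @param quiet_windows Optional data frame of inter-stimulus windows in
#'   the same format; `NULL` leaves the spontaneous rate undefined (`NA`).
#' @return A one-row tibble: `evoked_rate`, `spont_rate` (spikes/s),
#'   `n_stim`, `n_quiet`.
#' @export
response_rates <- function(spikes, stim_windows, quiet_windows = NULL) {
  window_rates <- function(w) {
    if (is.null(w) || nrow(w) == 0) return(NA_real_)
    if (!all(c("start", "end") %in% names(w)))
      stop_bad_input("windows need columns start and end")
    if (any(w$end <= w$start)) stop_bad_input("zero or negative-length window")
    r <- purrr::map2_dbl(w$start, w$end, function(a, b) {
      sum(spikes >= a & spikes < b) / (b - a) * 1000
    })
    mean(r)
  }
  tibble::tibble(
    evoked_rate = window_rates(stim_windows),
    spont_rate = window_rates(quiet_windows),
    n_stim = nrow(stim_windows),
    n_quiet = if (is.null(quiet_windows)) 0L else nrow(quiet_windows)
  )
}

#' Dynamic range of a rate modulation transfer function
#'
#' The spread of firing rate across modulation frequencies:
#' max rate minus min rate (spikes/s).
#'
#' @param rates Firing rates across the frequency grid (spikes/s).
#' @return `max(rates) - min(rates)`.
#' @export
#' @examples
#' dynamic_range(c(2, 7, 4))
dynamic_range <- function(rates) {
  rates <- rates[is.finite(rates)]
  if (length(rates) < 2)
    stop_bad_input("dynamic range needs rates at >= 2 frequencies")
  max(rates) - min(rates)
}
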