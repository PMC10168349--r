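#' Double-exponential synaptic event model
#'
#' The product-of-exponentials event shape used for EPSC/EPSP fitting:
#' \deqn{f(x) = y_0 + amp (1 - e^{-(x - x_0)/\tau_{rise}})
#'   e^{-(x - x_0)/\tau_{decay}}}
#' for \eqn{x \ge x_0} and \eqn{y_0} before onset. `amp` is a scale, not
#' the peak: the peak deviation from baseline is `amp` times the
#' (unnormalised) pulse maximum.
#'
#' @param x Time (ms); vectorised.
#' @param y0 Baseline (pA or mV).
#' @param amp Amplitude scale (negative for inward currents).
#' @param x0 Event onset (ms).
#' @param tau_rise,tau_decay Kinetics (ms).
#' @return Numeric vector of the model evaluated at `x`.
#' @export
epsc_model <- function(x, y0, amp, x0, tau_rise, tau_decay) {
  s <- pmax(x - x0, 0)
  y0 + amp * (1 - exp(-s / tau_rise)) * exp(-s / tau_decay)
}

#' Fit the double-exponential model to a synaptic event
#'
#' Bounded Levenberg-Marquardt least squares ([minpack.lm::nlsLM()]) of
#' [epsc_model()] to a monophasic EPSC/EPSP trace. Initial values: `y0`
#' from the pre-event samples, `amp` from the extremum, `x0` from the 10%
#' deviation crossing, `tau_rise` = 1 ms, `tau_decay` from the time to
#' half decay. Refuses (errors) rather than returning a fit when the
#' solver does not converge or the trace is flat.
#'
#' @param trace Data frame with columns `time` (ms) and `value`.
#' @param onset_guess Optional initial `x0` (ms).
#' @return An object of class `epsc_fit` with the estimates, fitted
#'   values, residuals and convergence info. Use [tidy()] / [glance()]
#'   to extract them as tibbles.
#' @export
#' @examples
#' tr <- gen_epsc_trace(y0 = 0, amp = -50, x0 = 20, tau_rise = 2,
#'                      tau_decay = 40, noise_sd = 0, dt = 0.1,
#'                      duration = 300)
#' tidy(fit_epsc(tr))
fit_epsc <- function(trace, onset_guess = NULL) {
  if (!all(c("time", "value") %in% names(trace)))
    stop_bad_input("trace needs columns time and value")
  x <- trace$time
  y <- trace$value
  if (anyNA(y) || any(!is.finite(y))) stop_bad_input("trace must be finite")

  rng <- diff(range(y))
  if (rng < .Machine$double.eps^0.5 * (1 + max(abs(y))))
    stop_bad_input("flat trace: no event to fit (degenerate amplitude)")

  i_peak <- which.max(abs(y - stats::median(y[seq_len(max(3, length(y) %/% 20))])))
  y0_0 <- mean(y[seq_len(max(3, length(y) %/% 20))])
  amp_0 <- y[i_peak] - y0_0
  x0_0 <- if (!is.null(onset_guess)) onset_guess else {
    dev <- abs(y - y0_0) >= 0.1 * abs(amp_0)
    first <- which(dev & x <= x[i_peak])
    if (length(first)) x[first[1]] else x[max(i_peak - 1, 1)]
  }
  post <- y[x >= x[i_peak]] - y0_0
  half_i <- which(abs(post) <= abs(amp_0) / 2)
  td_0 <- if (length(half_i)) {
    max((x[x >= x[i_peak]][half_i[1]] - x[i_peak]) / log(2), 1)
  } else max(diff(range(x)) / 4, 1)

  start <- list(y0 = y0_0, amp = amp_0 * 1.3, x0 = x0_0,
                tau_rise = 1, tau_decay = td_0)
  span <- diff(range(x))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      value ~ epsc_model(time, y0, amp, x0, tau_rise, tau_decay),
      data = trace, start = start,
      lower = c(y0 = -Inf, amp = -Inf, x0 = min(x), tau_rise = 1e-3,
                tau_decay = 1e-2),
      upper = c(y0 = Inf, amp = Inf, x0 = max(x), tau_rise = span,
                tau_decay = 10 * span),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)
    ),
    error = function(e) abort(paste0("EPSC fit failed to converge: ",
                                     conditionMessage(e)),
                              class = "nmdagain_fit_failure")
  )
  est <- coef(fit)
  structure(list(estimate = est, fitted = fitted(fit),
                 residuals = residuals(fit),
                 rss = sum(residuals(fit)^2), n = length(y),
                 converged = fit$convInfo$isConv, data = trace),
            class = "epsc_fit")
}

#' @export
print.epsc_fit <- function(x, ...) {
  cat("<epsc_fit>\n")
  print(round(x$estimate, 4))
  cat(sprintf("  rss = %.4g over %d points\n", x$rss, x$n))
  invisible(x)
}

#' @rdname fit_epsc
#' @param x,object An `epsc_fit` object.
#' @param ... Unused.
#' @export
tidy.epsc_fit <- function(x, ...) {
  tibble::tibble(term = names(x$estimate), estimate = unname(x$estimate))
}

#' @rdname fit_epsc
#' @export
glance.epsc_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, sigma = sqrt(x$rss / (x$n - 5)), n = x$n,
                 converged = x$converged)
}

#' Waveform measurements of a synaptic event
#'
#' The standard event metrics, measured directly from the trace:
#' amplitude (extremum minus baseline mean), halfwidth (time between the
#' two half-amplitude crossings, linearly interpolated), rise time
#' (10-90% of amplitude by default) and decay time constant
#' (single-exponential fit from the peak back toward baseline).
#'
#' @param trace Data frame with columns `time` (ms) and `value`.
#' @param baseline_window `c(start, end)` (ms) preceding the event, used
#'   for the baseline mean.
#' @param polarity `"auto"` (largest deviation), `"positive"` or
#'   `"negative"`.
#' @param rise_frac Fractions defining rise time (default 10-90%).
#' @return One-row tibble: `baseline`, `amplitude`, `peak_time`,
#'   `halfwidth`, `halfwidth_defined`, `rise_time`, `decay_tau`.
#' @export
measure_waveform <- function(trace, baseline_window, polarity = "auto",
                             rise_frac = c(0.1, 0.9)) {
  if (!all(c("time", "value") %in% names(trace)))
    stop_bad_input("trace needs columns time and value")
  x <- trace$time
  y <- trace$value
  in_base <- x >= baseline_window[1] & x <= baseline_window[2]
  if (!any(in_base)) stop_bad_input("baseline window contains no samples")
  base <- mean(y[in_base])
  after <- x > baseline_window[2]
  dev <- y - base
  i_peak <- switch(polarity,
                   auto = which(abs(dev) == max(abs(dev[after])))[1],
                   positive = which(dev == max(dev[after]))[1],
                   negative = which(dev == min(dev[after]))[1],
                   stop_bad_input("polarity must be auto/positive/negative"))
  amp <- dev[i_peak]
  sgn <- sign(amp)

  # crossing of level `frac * amp` searched outward from the peak
  cross_before <- function(level) {
    pre <- which(sgn * dev[seq_len(i_peak)] < sgn * level)
    if (!length(pre)) return(NA_real_)
    i <- max(pre)
    approx(dev[c(i, i + 1)], x[c(i, i + 1)], xout = level)$y
  }
  cross_after <- function(level) {
    post <- which(sgn * dev < sgn * level & seq_along(dev) > i_peak)
    if (!length(post)) return(NA_real_)
    i <- min(post)
    approx(dev[c(i - 1, i)], x[c(i - 1, i)], xout = level)$y
  }

  t_half1 <- cross_before(amp / 2)
  t_half2 <- cross_after(amp / 2)
  halfwidth <- t_half2 - t_half1
  rise <- cross_before(rise_frac[2] * amp) - cross_before(rise_frac[1] * amp)

  # single-exponential decay fit, peak -> return to 5% of amplitude
  post_i <- which(seq_along(dev) >= i_peak & sgn * dev >= 0.05 * sgn * amp)
  decay_tau <- NA_real_
  if (length(post_i) >= 5) {
    xs <- x[post_i] - x[i_peak]
    ys <- dev[post_i]
    d <- tryCatch({
      f <- minpack.lm::nlsLM(ys ~ A * exp(-xs / tau),
                             start = list(A = amp, tau = max(xs[length(xs)] / 2,
                                                             1e-2)),
                             lower = c(A = -Inf, tau = 1e-3),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
      unname(coef(f)[["tau"]])
    }, error = function(e) NA_real_)
    decay_tau <- d
  }

  tibble::tibble(baseline = base, amplitude = amp, peak_time = x[i_peak],
                 halfwidth = halfwidth,
                 halfwidth_defined = is.finite(halfwidth),
                 rise_time = rise, decay_tau = decay_tau)
}

#' Pointwise average of repeated sweeps
#'
#' Averages sweeps sampled on an identical time base; measurements are
#' then made on the average waveform.
#'
#' @param sweeps A list of data frames with columns `time`, `value`, all
#'   with the same `time` vector.
#' @return A tibble with columns `time`, `value` (the mean trace).
#' @export
average_sweeps <- function(sweeps) {
  if (!length(sweeps)) stop_bad_input("no sweeps supplied")
  t0 <- sweeps[[1]]$time
  vals <- purrr::map(sweeps, function(s) {
    if (!all(c("time", "value") %in% names(s)))
      stop_bad_input("each sweep needs columns time and value")
    if (length(s$time) != length(t0) || any(s$time != t0))
      stop_bad_input("sweeps must share an identical time base")
    s$value
  })
  tibble::tibble(time = t0, value = Reduce(`+`, vals) / length(vals))
}

#' Temporal-summation metrics for a train of events
#'
#' For an averaged response to a pulse train: the peak amplitude of each
#' event measured from the common pre-train baseline (summation shows as
#' successively larger peaks), and the area under the curve (trapezoidal
#' integral of the baseline-subtracted trace) over the train window.
#'
#' @param trace Data frame with columns `time` (ms), `value`.
#' @param onsets Pulse onset times (ms), at least 2.
#' @param baseline_window `c(start, end)` (ms) before the first onset.
#' @param window_end End of the integration window (ms); default extends
#'   one inter-pulse interval past the last onset.
#' @return A list of class `train_summation`: `peaks` (tibble `pulse`,
#'   `time`, `amplitude`), `auc`, `baseline`.
#' @export
summation_metrics <- function(trace, onsets, baseline_window,
                              window_end = NULL) {
  if (length(onsets) < 2) stop_bad_input("need >= 2 pulse onsets")
  onsets <- sort(onsets)
  x <- trace$time
  y <- trace$value
  in_base <- x >= baseline_window[1] & x <= baseline_window[2]
  if (!any(in_base)) stop_bad_input("baseline window contains no samples")
  base <- mean(y[in_base])
  ipi <- mean(diff(onsets))
  if (is.null(window_end)) window_end <- tail(onsets, 1) + ipi
  bounds <- c(onsets, window_end)

  peaks <- purrr::map_dfr(seq_along(onsets), function(k) {
    sel <- x >= bounds[k] & x < bounds[k + 1]
    dev <- y[sel] - base
    i <- which.max(abs(dev))
    tibble::tibble(pulse = k, time = x[sel][i], amplitude = dev[i])
  })

  sel <- x >= onsets[1] & x <= window_end
  xs <- x[sel]
  ys <- y[sel] - base
  auc <- sum(diff(xs) * (head(ys, -1) + tail(ys, -1)) / 2)

  structure(list(peaks = peaks, auc = auc, baseline = base),
            class = "train_summation")
}

#' @export
print.train_summation <- function(x, ...) {
  cat("<train_summation>\n")
  print(x$peaks)
  cat(sprintf("  AUC = %.4g (baseline %.4g)\n", x$auc, x$baseline))
  invisible(x)
}

#' @rdname summation_metrics
#' @param x A `train_summation` object.
#' @param ... Unused.
#' @export
tidy.train_summation <- function(x, ...) x$peaks

#' Optional zero-phase low-pass filtering of a trace
#'
#' Forward-backward (zero-phase) 4-pole Butterworth low-pass, matching
#' the usual pre-analysis conditioning of voltage-clamp data. Synthetic
#' traces in the test-suite are analysed unfiltered.
#'
#' @param trace Data frame with `time` (ms), `value`.
#' @param cutoff Cutoff frequency (kHz, i.e. 1/ms).
#' @return The trace with `value` filtered.
#' @export
lowpass_trace <- function(trace, cutoff = 3) {
  dt <- trace$time[2] - trace$time[1]
  w <- 2 * cutoff * dt # cutoff / Nyquist, with fs = 1/dt kHz
  if (w >= 1) return(trace)
  bf <- signal::butter(2, w, type = "low")
  trace$value <- as.numeric(signal::filtfilt(bf, trace$value))
  trace
}
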