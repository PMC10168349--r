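#' Synaptic parameters
#'
#' Kinetics and strengths of the two synaptic conductances: a fast AMPA
#' receptor conductance and a slow, Mg2+-insensitive NMDA conductance
#' mimicking GluN2C/D-containing receptors (no voltage dependence). The
#' NMDA peak is expressed as a fraction of the AMPA peak; the default
#' ratio is 0.25.
#'
#' @param g_ampa Peak AMPA conductance density for a single input pulse
#'   (mS/cm\eqn{^2}). `NULL` means "to be calibrated" (see
#'   [calibrate_synapse()]).
#' @param nmda_ratio NMDA peak conductance as a fraction of the AMPA peak.
#' @param tau_rise_ampa,tau_decay_ampa AMPA kinetics (ms).
#' @param tau_rise_nmda,tau_decay_nmda NMDA kinetics (ms); the slow decay
#'   is what widens the temporal-summation window.
#' @param e_syn Synaptic reversal potential (mV).
#' @param nmda_on Logical; include the NMDA conductance at all.
#' @param nmda_saturation Logical; cap the summed NMDA conductance at its
#'   nominal maximum (`nmda_ratio * g_ampa`), mimicking receptor-pool
#'   saturation of a gating-variable synapse. Without the cap, linear
#'   accumulation of the slow NMDA kinetics at high input rates grows
#'   without bound and drives the neuron into depolarisation block at
#'   every membrane resistance, which is not how saturating NMDA
#'   receptor conductances behave. Default `TRUE`.
#'
#' @return An object of class `synapse_params`.
#' @export
#' @examples
#' synapse_params(g_ampa = 0.2)
synapse_params <- function(g_ampa = NULL, nmda_ratio = 0.25,
                           tau_rise_ampa = 0.2, tau_decay_ampa = 2,
                           tau_rise_nmda = 5, tau_decay_nmda = 100,
                           e_syn = 0, nmda_on = TRUE,
                           nmda_saturation = TRUE) {
  if (tau_rise_ampa <= 0 || tau_rise_ampa >= tau_decay_ampa)
    stop_bad_input("need 0 < tau_rise_ampa < tau_decay_ampa")
  if (tau_rise_nmda <= 0 || tau_rise_nmda >= tau_decay_nmda)
    stop_bad_input("need 0 < tau_rise_nmda < tau_decay_nmda")
  if (nmda_ratio < 0) stop_bad_input("nmda_ratio must be >= 0")
  if (!is.null(g_ampa) && (!is.finite(g_ampa) || g_ampa < 0))
    stop_bad_input("g_ampa must be >= 0")
  structure(list(g_ampa = g_ampa, nmda_ratio = nmda_ratio,
                 tau_rise_ampa = tau_rise_ampa, tau_decay_ampa = tau_decay_ampa,
                 tau_rise_nmda = tau_rise_nmda, tau_decay_nmda = tau_decay_nmda,
                 e_syn = e_syn, nmda_on = isTRUE(nmda_on),
                 nmda_saturation = isTRUE(nmda_saturation)),
            class = "synapse_params")
}

#' @export
print.synapse_params <- function(x, ...) {
  cat("<synapse_params>\n")
  cat(sprintf("  AMPA: g_max = %s mS/cm^2, tau_rise = %g ms, tau_decay = %g ms\n",
              if (is.null(x$g_ampa)) "<uncalibrated>" else format(x$g_ampa),
              x$tau_rise_ampa, x$tau_decay_ampa))
  cat(sprintf("  NMDA: %s, ratio = %g, tau_rise = %g ms, tau_decay = %g ms\n",
              if (x$nmda_on) "on" else "off", x$nmda_ratio,
              x$tau_rise_nmda, x$tau_decay_nmda))
  cat(sprintf("  Esyn = %g mV\n", x$e_syn))
  invisible(x)
}

#' Periodic input train
#'
#' Evenly spaced synaptic input onsets at the given frequency: for
#' frequency `f` (Hz) and duration `D` (ms) there are `floor(D * f / 1000)`
#' onsets at period `1000 / f` ms starting at `offset`.
#'
#' @param frequency Input rate (Hz).
#' @param duration Train duration (ms).
#' @param offset Time of the first onset (ms).
#' @return An object of class `input_train` with fields `onsets` (ms),
#'   `frequency`, `duration`, `offset`.
#' @export
#' @examples
#' make_train(16, 1000)$onsets
make_train <- function(frequency, duration, offset = 0) {
  if (!is.finite(frequency) || frequency <= 0)
    stop_bad_input("frequency must be > 0")
  if (!is.finite(duration) || duration <= 0)
    stop_bad_input("duration must be > 0")
  if (offset < 0 || offset >= duration)
    stop_bad_input("offset must lie in [0, duration)")
  n <- floor(duration * frequency / 1000)
  onsets <- offset + (seq_len(n) - 1) * 1000 / frequency
  onsets <- onsets[onsets < duration]
  structure(list(onsets = onsets, frequency = frequency,
                 duration = duration, offset = offset),
            class = "input_train")
}

#' @export
print.input_train <- function(x, ...) {
  cat(sprintf("<input_train> %g Hz, %g ms, %d onsets\n",
              x$frequency, x$duration, length(x$onsets)))
  invisible(x)
}

#' Geometric frequency grid
#'
#' Frequencies spaced at equal ratios, `steps_per_octave` per doubling,
#' inclusive of both endpoints. The default 16-512 Hz grid at 4
#' steps/octave has 21 frequencies.
#'
#' @param fmin,fmax Grid endpoints (Hz).
#' @param steps_per_octave Number of frequencies per doubling.
#' @return Numeric vector of frequencies (Hz).
#' @export
#' @examples
#' frequency_grid()
frequency_grid <- function(fmin = 16, fmax = 512, steps_per_octave = 4) {
  if (!(fmax > fmin && fmin > 0)) stop_bad_input("need fmax > fmin > 0")
  if (steps_per_octave < 1) stop_bad_input("steps_per_octave must be >= 1")
  n <- floor(steps_per_octave * log2(fmax / fmin) + 1e-9)
  f <- fmin * 2^((0:n) / steps_per_octave)
  if (tail(f, 1) < fmax * (1 - 1e-9)) f <- c(f, fmax)
  f
}

#' Single-pulse synaptic conductance
#'
#' The normalised dual-exponential conductance time course
#' \eqn{g(t) = g_{max} N (1 - e^{-(t-t_0)/\tau_r}) e^{-(t-t_0)/\tau_d}}
#' for \eqn{t \ge t_0} (0 before), with \eqn{N} chosen analytically so the
#' pulse peaks exactly at `g_max`. `synaptic_peak_time()` gives the time
#' from onset to peak, \eqn{t^* = \tau_r \log(1 + \tau_d/\tau_r)}.
#'
#' @param t Time points (ms).
#' @param tau_rise,tau_decay Kinetics (ms), `tau_rise < tau_decay`.
#' @param t0 Pulse onset (ms).
#' @param g_max Peak conductance.
#' @return Conductance at `t` (same units as `g_max`).
#' @export
#' @examples
#' tt <- seq(0, 20, 0.01)
#' max(synaptic_pulse(tt, 0.2, 2)) # ~1
synaptic_pulse <- function(t, tau_rise, tau_decay, t0 = 0, g_max = 1) {
  if (tau_rise <= 0 || tau_rise >= tau_decay)
    stop_bad_input("need 0 < tau_rise < tau_decay")
  s <- pmax(t - t0, 0)
  g <- (1 - exp(-s / tau_rise)) * exp(-s / tau_decay)
  g_max * g / pulse_peak_value(tau_rise, tau_decay)
}

#' @rdname synaptic_pulse
#' @export
synaptic_peak_time <- function(tau_rise, tau_decay) {
  tau_rise * log(1 + tau_decay / tau_rise)
}

pulse_peak_value <- function(tau_rise, tau_decay) {
  ts <- synaptic_peak_time(tau_rise, tau_decay)
  (1 - exp(-ts / tau_rise)) * exp(-ts / tau_decay)
}

# Exact superposition of normalised dual-exponential pulses sampled on a
# uniform grid, via two first-order recursive filters.  The pulse is
# decomposed as e^{-s/tau_d} - e^{-s/kappa}, kappa = tau_r tau_d/(tau_r +
# tau_d); each onset deposits an impulse at the first grid point at or
# after it, pre-decayed by the (sub-grid) offset, so grid samples are
# exact regardless of where onsets fall.
superpose_pulses <- function(tgrid, onsets, tau_rise, tau_decay, g_max) {
  n <- length(tgrid)
  if (length(onsets) == 0 || g_max == 0) return(numeric(n))
  h <- tgrid[2] - tgrid[1]
  kappa <- tau_rise * tau_decay / (tau_rise + tau_decay)
  t0 <- tgrid[1]
  idx <- pmin(pmax(ceiling((onsets - t0) / h - 1e-9) + 1, 1), n)
  lag <- tgrid[idx] - onsets
  zd <- numeric(n)
  zk <- numeric(n)
  wd <- exp(-lag / tau_decay)
  wk <- exp(-lag / kappa)
  for (j in seq_along(idx)) {
    zd[idx[j]] <- zd[idx[j]] + wd[j]
    zk[idx[j]] <- zk[idx[j]] + wk[j]
  }
  yd <- as.numeric(stats::filter(zd, exp(-h / tau_decay), method = "recursive"))
  yk <- as.numeric(stats::filter(zk, exp(-h / kappa), method = "recursive"))
  g_max * (yd - yk) / pulse_peak_value(tau_rise, tau_decay)
}

#' AMPA/NMDA conductance waveforms for an input train
#'
#' Sums the single-pulse conductance over all pulse onsets (linear
#' superposition, no short-term plasticity). Values are exact at the
#' supplied grid points. When the synapse has `nmda_saturation = TRUE`
#' (the default) the summed NMDA conductance is additionally capped at
#' its nominal maximum `nmda_ratio * g_ampa`, the behaviour of a
#' saturating gating-variable synapse; the AMPA component always sums
#' linearly (its fast decay never accumulates appreciably).
#'
#' @param train An [make_train()] object.
#' @param synapse A [synapse_params()] object with `g_ampa` set.
#' @param t Uniform time grid (ms).
#' @return A tibble with columns `time`, `g_ampa`, `g_nmda` (mS/cm\eqn{^2}).
#' @export
#' @examples
#' tr <- make_train(30, 200)
#' conductance_waveform(tr, synapse_params(g_ampa = 0.1), seq(0, 200, 0.05))
conductance_waveform <- function(train, synapse, t) {
  stopifnot(inherits(train, "input_train"), inherits(synapse, "synapse_params"))
  if (is.null(synapse$g_ampa))
    stop_bad_input("synapse g_ampa is not set; run calibrate_synapse() first")
  if (length(t) < 2 || any(diff(t) <= 0))
    stop_bad_input("t must be an increasing grid")
  g_nmda_max <- if (synapse$nmda_on) synapse$nmda_ratio * synapse$g_ampa else 0
  g_nmda <- superpose_pulses(t, train$onsets, synapse$tau_rise_nmda,
                             synapse$tau_decay_nmda, g_nmda_max)
  if (synapse$nmda_saturation) g_nmda <- pmin(g_nmda, g_nmda_max)
  tibble::tibble(
    time = t,
    g_ampa = superpose_pulses(t, train$onsets, synapse$tau_rise_ampa,
                              synapse$tau_decay_ampa, synapse$g_ampa),
    g_nmda = g_nmda
  )
}

#' Calibrate the AMPA conductance to the spiking threshold
#'
#' Finds, by bisection, the minimal single-pulse AMPA peak conductance
#' that makes one AMPA-only pulse fire the neuron from rest, then sets
#' `g_ampa` to `scale` times that threshold. With the default
#' `scale = 0.9` a single pulse is subthreshold, so any spiking during a
#' train must come from temporal summation -- the regime of interest.
#'
#' @param membrane A [membrane_params()] object.
#' @param synapse A [synapse_params()] object (its kinetics are used).
#' @param scale Fraction of the single-pulse threshold to use.
#' @param dt Integration step (ms).
#' @param t_sim Length of the single-pulse probe simulation (ms).
#' @param tol Relative bisection tolerance on the threshold.
#' @return `calibrate_synapse()`: the `synapse` object with `g_ampa` set
#'   (threshold stored as attribute `g_threshold`). `ampa_threshold()`:
#'   the threshold conductance itself (mS/cm\eqn{^2}).
#' @export
calibrate_synapse <- function(membrane, synapse, scale = 0.9, dt = 0.01,
                              t_sim = 60, tol = 1e-3) {
  thr <- ampa_threshold(membrane, synapse, dt = dt, t_sim = t_sim, tol = tol)
  synapse$g_ampa <- scale * thr
  attr(synapse, "g_threshold") <- thr
  synapse
}

#' @rdname calibrate_synapse
#' @export
ampa_threshold <- function(membrane, synapse, dt = 0.01, t_sim = 60,
                           tol = 1e-3) {
  stopifnot(inherits(membrane, "membrane_params"),
            inherits(synapse, "synapse_params"))
  probe <- synapse
  probe$nmda_on <- FALSE
  rest <- resting_state(membrane)
  spikes_at <- function(g) {
    probe$g_ampa <- g
    sim <- simulate_neuron(membrane, train = make_train(1000 / t_sim, t_sim,
                                                        offset = 5),
                           synapse = probe, duration = t_sim, dt = dt,
                           init = rest)
    length(sim$spikes) > 0
  }
  lo <- 1e-4
  hi <- 0.5
  while (spikes_at(lo)) lo <- lo / 4 # pathological, but keep the bracket valid
  it <- 0
  while (!spikes_at(hi)) {
    hi <- hi * 2
    it <- it + 1
    if (it > 12) stop_bad_input("no spiking found up to g_ampa = %g", hi)
  }
  while ((hi - lo) / hi > tol) {
    mid <- sqrt(lo * hi)
    if (spikes_at(mid)) hi <- mid else lo <- mid
  }
  hi
}
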