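#' Simulate the model neuron
#'
#' Integrates the conductance-based neuron with a fixed-step 4th-order
#' Runge-Kutta scheme (default dt = 0.01 ms). The synaptic drive is a
#' periodic input train converted to AMPA/NMDA conductance waveforms; an
#' applied current can be given instead of, or on top of, the train.
#' Synaptic current uses the instantaneous driving force
#' \eqn{I_{syn} = (g_{AMPA} + g_{NMDA})(V - E_{syn})}; the NMDA term
#' carries no Mg2+ block.
#'
#' @param membrane A [membrane_params()] object.
#' @param train Optional [make_train()] input train.
#' @param synapse Optional [synapse_params()] with `g_ampa` set (required
#'   when `train` is given).
#' @param i_app Applied current (\eqn{\mu}A/cm\eqn{^2}): a scalar or a
#'   function of time (ms).
#' @param duration Simulated time (ms).
#' @param dt Integration step (ms).
#' @param init Initial state: `"steady"` (the root-found resting state,
#'   the default, which removes onset transients) or a named numeric
#'   vector `c(v =, h =, n =)`.
#' @param threshold,lockout Spike detection: upward crossing threshold
#'   (mV) and refractory lockout (ms).
#'
#' @return An object of class `neuron_sim`: a list with `trace` (tibble:
#'   `time`, `v`, `h`, `n`, `g_syn`), `spikes` (spike times, ms),
#'   `membrane`, `synapse`, `dt`, `duration`.
#' @export
#' @examples
#' mem <- membrane_params()
#' syn <- synapse_params(g_ampa = 0.3, nmda_on = FALSE)
#' sim <- simulate_neuron(mem, make_train(64, 250), syn, duration = 250)
#' length(sim$spikes)
simulate_neuron <- function(membrane, train = NULL, synapse = NULL,
                            i_app = 0, duration, dt = 0.01,
                            init = "steady", threshold = 0, lockout = 1) {
  stopifnot(inherits(membrane, "membrane_params"))
  if (!is.finite(duration) || duration <= 0) stop_bad_input("duration must be > 0")
  if (!is.finite(dt) || dt <= 0) stop_bad_input("dt must be > 0")
  if (!is.null(train) && 1000 / train$frequency < dt)
    stop_bad_input("input period shorter than dt")

  nsteps <- ceiling(duration / dt)
  t_half <- seq(0, by = dt / 2, length.out = 2 * nsteps + 1)

  if (!is.null(train)) {
    if (is.null(synapse)) stop_bad_input("train given without synapse")
    wf <- conductance_waveform(train, synapse, t_half)
    gsyn_half <- wf$g_ampa + wf$g_nmda
  } else {
    gsyn_half <- numeric(2 * nsteps + 1)
  }

  iapp_half <- if (is.function(i_app)) {
    vapply(t_half, i_app, numeric(1))
  } else {
    rep_len(as.numeric(i_app), 2 * nsteps + 1)
  }

  state0 <- if (identical(init, "steady")) {
    resting_state(membrane)
  } else {
    if (!is.numeric(init) || !all(c("v", "h", "n") %in% names(init)))
      stop_bad_input("init must be \"steady\" or c(v=, h=, n=)")
    init[c("v", "h", "n")]
  }

  esyn <- if (is.null(synapse)) 0 else synapse$e_syn
  res <- .rk4_integrate(gsyn_half, iapp_half, dt, nsteps,
                        state0[["v"]], state0[["h"]], state0[["n"]],
                        membrane$cm, membrane$gna, membrane$ena,
                        membrane$gk, membrane$ek, membrane$gl, membrane$el,
                        membrane$phi, esyn)
  if (!res$ok)
    abort(sprintf("integration failed (non-finite state) at t = %.3f ms",
                  res$t_fail),
          class = "nmdagain_integration_failure")

  tgrid <- seq(0, by = dt, length.out = nsteps + 1)
  trace <- tibble::tibble(time = tgrid, v = res$v, h = res$h, n = res$n,
                          g_syn = gsyn_half[seq(1, 2 * nsteps + 1, by = 2)])
  spikes <- crossing_times(tgrid, res$v, threshold, lockout)
  structure(list(trace = trace, spikes = spikes, membrane = membrane,
                 synapse = synapse, dt = dt, duration = duration),
            class = "neuron_sim")
}

# upward threshold crossings with linear interpolation and refractory lockout
crossing_times <- function(time, v, threshold = 0, lockout = 1) {
  up <- which(v[-length(v)] < threshold & v[-1] >= threshold)
  if (length(up) == 0) return(numeric(0))
  tc <- time[up] + (threshold - v[up]) / (v[up + 1] - v[up]) * diff(time)[1]
  keep <- rep(TRUE, length(tc))
  last <- tc[1]
  for (i in seq_along(tc)[-1]) {
    if (tc[i] - last < lockout) keep[i] <- FALSE else last <- tc[i]
  }
  tc[keep]
}

#' @export
print.neuron_sim <- function(x, ...) {
  cat(sprintf("<neuron_sim> %g ms at dt = %g ms, %d spikes\n",
              x$duration, x$dt, length(x$spikes)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname simulate_neuron
#' @param x,object A `neuron_sim` object.
#' @param ... Unused.
#' @export
tidy.neuron_sim <- function(x, ...) x$trace

#' @rdname simulate_neuron
#' @export
glance.neuron_sim <- function(x, ...) {
  tibble::tibble(
    n_spikes = length(x$spikes),
    rate = length(x$spikes) / x$duration * 1000,
    v_min = min(x$trace$v), v_max = max(x$trace$v),
    v_final = tail(x$trace$v, 1),
    duration = x$duration, dt = x$dt
  )
}

#' Plot a simulated voltage trace
#'
#' @param object A `neuron_sim` object.
#' @param ... Unused.
#' @return A ggplot object: membrane potential over time with the
#'   synaptic conductance below.
#' @export
autoplot.neuron_sim <- function(object, ...) {
  df <- tidyr::pivot_longer(object$trace[, c("time", "v", "g_syn")],
                            -"time", names_to = "series")
  df$series <- factor(df$series, c("v", "g_syn"),
                      c("V (mV)", "g_syn (mS/cm^2)"))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$series), scales = "free_y",
                        switch = "y") +
    ggplot2::labs(x = "time (ms)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Write and read simulation output as delimited text
#'
#' `write_sim_trace()` writes the trace (time, v, h, n, g_syn) as TSV;
#' `write_spike_times()` writes spike times as a single column.
#'
#' @param sim A `neuron_sim` object.
#' @param path Output file.
#' @return The input, invisibly.
#' @export
write_sim_trace <- function(sim, path) {
  readr::write_tsv(sim$trace, path)
  invisible(sim)
}

#' @rdname write_sim_trace
#' @export
write_spike_times <- function(sim, path) {
  readr::write_tsv(tibble::tibble(spike_time_ms = sim$spikes), path)
  invisible(sim)
}
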