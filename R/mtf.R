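#' Rate and temporal modulation transfer functions of the model neuron
#'
#' Runs the in silico sweep: for every leak conductance, synaptic
#' condition (AMPA-only vs AMPA+NMDA) and input frequency, drives the
#' model with a periodic input train and tabulates firing rate, spikes
#' per train, vector strength and mean phase. The AMPA-only condition is
#' the same synapse with the NMDA conductance switched off.
#'
#' Because the published experiment does not fix the synaptic strength,
#' `g_ampa` is recalibrated for every leak conductance with
#' [calibrate_synapse()] (single pulse at `scale` times the spiking
#' threshold) unless the supplied synapse already has `g_ampa` set and
#' `calibrate = FALSE`.
#'
#' @param membrane A [membrane_params()] object (its `gl` is overridden
#'   by `gl_values`).
#' @param synapse A [synapse_params()] object; `g_ampa` may be `NULL`
#'   when `calibrate = TRUE`.
#' @param gl_values Leak conductances to sweep (mS/cm\eqn{^2}).
#' @param frequencies Input frequencies (Hz); default 16-512 Hz at 4
#'   steps/octave.
#' @param duration Train duration (ms).
#' @param dt Integration step (ms).
#' @param offset Onset of the first pulse (ms).
#' @param calibrate Recalibrate `g_ampa` per leak conductance.
#' @param scale Calibration scale (`g_ampa` as a multiple of the
#'   single-pulse spiking threshold). The default (`NULL`) follows the
#'   two regimes of the published experiment: 0.85 for `gl <= 1`
#'   (high-resistance cells integrate subthreshold inputs, so spiking
#'   requires temporal summation) and 2 for `gl > 1` (low-resistance
#'   cells fire one phase-locked spike per input, which requires
#'   suprathreshold single inputs). A scalar or a vector along
#'   `gl_values`.
#' @param min_spikes Spike-count gate for vector strength (default:
#'   defined only when a train elicits more than 4 spikes).
#' @return A tibble of class `mtf_result` with one row per (gl,
#'   condition, frequency): `gl`, `condition`, `frequency`, `n_spikes`,
#'   `spikes_per_train`, `rate`, `vector_strength`, `vs_defined`,
#'   `mean_phase`, `g_ampa`.
#' @export
#' @examples
#' \donttest{
#' mtf <- run_sweep(membrane_params(), synapse_params(),
#'                  frequencies = frequency_grid(16, 64, 1))
#' }
run_sweep <- function(membrane, synapse, gl_values = membrane$gl,
                      frequencies = frequency_grid(16, 512, 4),
                      duration = 1000, dt = 0.01, offset = 0,
                      calibrate = TRUE, scale = NULL, min_spikes = 5) {
  stopifnot(inherits(membrane, "membrane_params"),
            inherits(synapse, "synapse_params"))
  if (length(gl_values) == 0 || length(frequencies) == 0)
    stop_bad_input("gl_values and frequencies must be nonempty")
  if (!calibrate && is.null(synapse$g_ampa))
    stop_bad_input("g_ampa unset and calibrate = FALSE")
  scale <- if (is.null(scale)) calibration_scale(gl_values)
           else rep_len(scale, length(gl_values))

  rows <- purrr::map2_dfr(gl_values, scale, function(gl, sc) {
    mem <- membrane
    mem$gl <- gl
    syn <- if (calibrate) {
      calibrate_synapse(mem, synapse, scale = sc, dt = dt)
    } else {
      synapse
    }
    purrr::map_dfr(c("ampa", "ampa_nmda"), function(cond) {
      s <- syn
      s$nmda_on <- cond == "ampa_nmda"
      purrr::map_dfr(frequencies, function(f) {
        train <- make_train(f, duration, offset = offset)
        sim <- tryCatch(
          simulate_neuron(mem, train, s, duration = duration, dt = dt),
          nmdagain_integration_failure = function(e) {
            abort(sprintf("sweep failed at gl = %g, condition = %s, f = %g Hz: %s",
                          gl, cond, f, conditionMessage(e)),
                  class = "nmdagain_integration_failure")
          }
        )
        ns <- length(sim$spikes)
        tibble::tibble(
          gl = gl, condition = cond, frequency = f,
          n_spikes = ns, spikes_per_train = ns,
          rate = ns / duration * 1000,
          vector_strength = vector_strength(sim$spikes - offset, f,
                                            min_spikes = min_spikes),
          vs_defined = ns >= min_spikes,
          mean_phase = mean_phase(sim$spikes - offset, f,
                                  min_spikes = min_spikes),
          g_ampa = s$g_ampa
        )
      })
    })
  })
  class(rows) <- c("mtf_result", class(rows))
  attr(rows, "scale") <- scale
  attr(rows, "duration") <- duration
  attr(rows, "dt") <- dt
  rows
}

#' Default per-regime calibration scale
#'
#' The synaptic strength regime as a function of leak conductance:
#' subthreshold single inputs (0.85 x threshold) for high-resistance
#' cells (`gl <= 1` mS/cm^2), suprathreshold single inputs (2 x
#' threshold) for leaky low-resistance cells.
#'
#' @param gl Leak conductance values (mS/cm\eqn{^2}).
#' @return Numeric vector of calibration scales.
#' @export
calibration_scale <- function(gl) {
  ifelse(gl <= 1, 0.85, 2)
}

#' Classify a modulation transfer function as sustained or onset
#'
#' A response collapses to "onset" when strong sustained depolarisation
#' (depolarisation block) leaves exactly one spike per train across the
#' top octave of input frequencies; it is "sustained" otherwise. A zero
#' count at the top frequency fits neither profile and is flagged
#' `"anomalous"`.
#'
#' @param mtf An `mtf_result` tibble (any number of gl/condition groups).
#' @return A tibble with one row per (gl, condition) and a `class`
#'   column in `{"sustained", "onset", "anomalous"}`.
#' @export
classify_response <- function(mtf) {
  if (!all(c("gl", "condition", "frequency", "spikes_per_train") %in% names(mtf)))
    stop_bad_input("mtf must be a run_sweep() result")
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(mtf), .data$gl, .data$condition),
    class = {
      top <- .data$frequency >= max(.data$frequency) / 2
      counts <- .data$spikes_per_train[top]
      top_f <- .data$spikes_per_train[which.max(.data$frequency)]
      if (top_f == 0) "anomalous"
      else if (all(counts == 1)) "onset"
      else "sustained"
    },
    .groups = "drop"
  )
}

#' Plot rate and temporal modulation transfer functions
#'
#' @param object An `mtf_result` from [run_sweep()].
#' @param ... Unused.
#' @return A ggplot: firing rate and vector strength vs input frequency
#'   (log axis), coloured by synaptic condition, facetted by leak
#'   conductance.
#' @export
autoplot.mtf_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df <- tidyr::pivot_longer(
    df[, c("gl", "condition", "frequency", "rate", "vector_strength")],
    c("rate", "vector_strength"), names_to = "metric"
  )
  df$metric <- factor(df$metric, c("rate", "vector_strength"),
                      c("firing rate (spikes/s)", "vector strength"))
  ggplot2::ggplot(df, ggplot2::aes(.data$frequency, .data$value,
                                   colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_grid(ggplot2::vars(.data$metric), ggplot2::vars(.data$gl),
                        scales = "free_y",
                        labeller = ggplot2::labeller(
                          gl = function(x) paste0("gL = ", x))) +
    ggplot2::labs(x = "input frequency (Hz)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Write a modulation-transfer-function table as delimited text
#'
#' @param mtf An `mtf_result`.
#' @param path Output TSV path.
#' @return The input, invisibly.
#' @export
write_mtf <- function(mtf, path) {
  readr::write_tsv(tibble::as_tibble(mtf), path)
  invisible(mtf)
}
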