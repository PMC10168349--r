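# shared fixtures, built in code; the calibrated reference synapse is
# computed once per test run and memoised
.cache <- new.env(parent = emptyenv())

ref_membrane <- function(gl = 0.7) membrane_params(gl = gl)

ref_synapse <- function(gl = 0.7, scale = 0.85) {
  key <- sprintf("syn_%g_%g", gl, scale)
  if (is.null(.cache[[key]])) {
    .cache[[key]] <- calibrate_synapse(ref_membrane(gl), synapse_params(),
                                       scale = scale)
  }
  .cache[[key]]
}

# voltage trace with stylised action potentials at known times
ap_trace <- function(ap_times, duration = 100, dt = 0.01, v_rest = -65,
                     height = 90, width = 0.3) {
  t <- seq(0, duration, by = dt)
  v <- rep(v_rest, length(t))
  for (tk in ap_times) v <- v + height * exp(-((t - tk) / width)^2)
  tibble::tibble(time = t, v = v)
}
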