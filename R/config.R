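#' Read and write simulation configuration files
#'
#' Human-readable YAML with four sections -- `membrane`, `synapse`,
#' `stimulus`, `integration` -- whose keys map one-to-one onto
#' [membrane_params()], [synapse_params()] and the sweep arguments.
#' Unknown keys are rejected rather than silently ignored, so typos do
#' not fall back to defaults.
#'
#' @param path Config file path.
#' @return `read_sim_config()`: a list with elements `membrane`
#'   (`membrane_params`), `synapse` (`synapse_params`), `stimulus` and
#'   `integration` (plain lists). The packaged default configuration is
#'   at `system.file("extdata", "fig_sweep_config.yml", package =
#'   "nmdagain")`.
#' @export
#' @examples
#' cfg <- read_sim_config(system.file("extdata", "fig_sweep_config.yml",
#'                                    package = "nmdagain"))
#' cfg$membrane
read_sim_config <- function(path) {
  if (!file.exists(path)) stop_bad_input("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  bad_sections <- setdiff(names(raw),
                          c("membrane", "synapse", "stimulus", "integration"))
  if (length(bad_sections))
    stop_bad_input("unknown config section(s): %s",
                   paste(bad_sections, collapse = ", "))
  check_keys <- function(given, allowed, section) {
    bad <- setdiff(names(given), allowed)
    if (length(bad))
      stop_bad_input("unknown key(s) in [%s]: %s", section,
                     paste(bad, collapse = ", "))
  }
  mem_keys <- names(formals(membrane_params))
  syn_keys <- names(formals(synapse_params))
  stim_keys <- c("fmin_hz", "fmax_hz", "steps_per_octave", "duration_ms",
                 "offset_ms", "gl_values_ms_per_cm2")
  int_keys <- c("dt_ms", "init", "calibrate", "scale")
  check_keys(raw$membrane, mem_keys, "membrane")
  check_keys(raw$synapse, syn_keys, "synapse")
  check_keys(raw$stimulus, stim_keys, "stimulus")
  check_keys(raw$integration, int_keys, "integration")
  list(
    membrane = do.call(membrane_params, raw$membrane %||% list()),
    synapse = do.call(synapse_params, raw$synapse %||% list()),
    stimulus = raw$stimulus %||% list(),
    integration = raw$integration %||% list()
  )
}

#' @rdname read_sim_config
#' @param config A list as returned by `read_sim_config()`.
#' @export
write_sim_config <- function(config, path) {
  out <- list(
    membrane = unclass(config$membrane),
    synapse = unclass(config$synapse),
    stimulus = config$stimulus,
    integration = config$integration
  )
  out$synapse <- out$synapse[!vapply(out$synapse, is.null, logical(1))]
  attr(out$synapse, "g_threshold") <- NULL
  yaml::write_yaml(out, path)
  invisible(config)
}

#' Run the frequency sweep described by a config file
#'
#' Thin orchestration wrapper: reads the config, runs [run_sweep()] over
#' the configured frequency grid and leak values, optionally writes the
#' tidy result table as TSV.
#'
#' @param path Config file path.
#' @param out Optional output TSV path for the MTF table.
#' @return The `mtf_result` tibble, invisibly when `out` is given.
#' @export
run_sweep_config <- function(path, out = NULL) {
  cfg <- read_sim_config(path)
  st <- cfg$stimulus
  it <- cfg$integration
  freqs <- frequency_grid(st$fmin_hz %||% 16, st$fmax_hz %||% 512,
                          st$steps_per_octave %||% 4)
  mtf <- run_sweep(
    cfg$membrane, cfg$synapse,
    gl_values = st$gl_values_ms_per_cm2 %||% cfg$membrane$gl,
    frequencies = freqs,
    duration = st$duration_ms %||% 1000,
    dt = it$dt_ms %||% 0.01,
    offset = st$offset_ms %||% 0,
    calibrate = it$calibrate %||% TRUE,
    scale = it$scale %||% 0.9
  )
  if (!is.null(out)) {
    write_mtf(mtf, out)
    return(invisible(mtf))
  }
  mtf
}

`%||%` <- function(a, b) if (is.null(a)) b else a
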