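#' Membrane parameters for the model neuron
#'
#' Passive and active membrane constants of the single-compartment
#' fast-spiking neuron (Wang-Buzsaki type). Defaults are the published
#' constants of that model with the leak conductance set to mimic the
#' average input resistance of an IC VIP neuron (~200 M\eqn{\Omega} for a
#' 15 \eqn{\mu}m spherical soma).
#'
#' @param cm Membrane capacitance (\eqn{\mu}F/cm\eqn{^2}).
#' @param gna,ena Maximal Na\eqn{^+} conductance density (mS/cm\eqn{^2}) and
#'   reversal potential (mV).
#' @param gk,ek Maximal delayed-rectifier K\eqn{^+} conductance density
#'   (mS/cm\eqn{^2}) and reversal potential (mV).
#' @param gl,el Leak conductance density (mS/cm\eqn{^2}) and leak reversal
#'   potential (mV). `gl` is the knob used to mimic neuron-to-neuron
#'   diversity in input resistance.
#' @param phi Dimensionless temperature-like scale applied to the gating
#'   kinetics.
#' @param diameter Soma diameter (\eqn{\mu}m), sphere assumed; used only for
#'   conductance-to-resistance conversion.
#'
#' @return An object of class `membrane_params` (a named list).
#' @seealso [membrane_resistance()], [simulate_neuron()]
#' @export
#' @examples
#' membrane_params()
#' membrane_params(gl = 0.282) # high input resistance variant
membrane_params <- function(cm = 1, gna = 35, ena = 55, gk = 9, ek = -90,
                            gl = 0.7, el = -65, phi = 5, diameter = 15) {
  p <- list(cm = cm, gna = gna, ena = ena, gk = gk, ek = ek,
            gl = gl, el = el, phi = phi, diameter = diameter)
  if (!all(vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                  logical(1))))
    stop_bad_input("all membrane parameters must be finite numeric scalars")
  if (cm <= 0) stop_bad_input("cm must be > 0")
  if (diameter <= 0) stop_bad_input("diameter must be > 0")
  if (gna < 0 || gk < 0 || gl < 0)
    stop_bad_input("conductance densities must be >= 0")
  if (ena <= ek) stop_bad_input("ena must exceed ek")
  structure(p, class = "membrane_params")
}

#' @export
print.membrane_params <- function(x, ...) {
  cat("<membrane_params>\n")
  cat(sprintf("  Cm = %g uF/cm^2, phi = %g, diameter = %g um\n",
              x$cm, x$phi, x$diameter))
  cat(sprintf("  gNa = %g (ENa = %g mV), gK = %g (EK = %g mV)\n",
              x$gna, x$ena, x$gk, x$ek))
  cat(sprintf("  gL = %g mS/cm^2 (EL = %g mV) -> Rm ~ %.0f MOhm\n",
              x$gl, x$el, membrane_resistance(x$gl, x$diameter)))
  invisible(x)
}

# x / (1 - exp(-x)), finite at the removable singularity x = 0.
# Kept identical to the C++ integrator's version.
vtrap <- function(x) {
  out <- x / (-expm1(-x))
  out[abs(x) < 1e-7] <- 1
  out
}

#' Voltage-dependent gating rate constants
#'
#' The six Hodgkin-Huxley rate constants of the fast-spiking neuron model
#' (Na\eqn{^+} activation m, inactivation h; K\eqn{^+} activation n), in
#' 1/ms. The removable singularities of \eqn{\alpha_m} (at \eqn{-35} mV)
#' and \eqn{\alpha_n} (at \eqn{-34} mV) evaluate to their finite limits.
#'
#' @param v Membrane potential (mV); vectorised.
#' @return A tibble with columns `v`, `alpha_m`, `beta_m`, `alpha_h`,
#'   `beta_h`, `alpha_n`, `beta_n`.
#' @export
#' @examples
#' rate_functions(c(-65, -35))
rate_functions <- function(v) {
  if (!is.numeric(v) || !all(is.finite(v)))
    stop_bad_input("v must be finite numeric")
  tibble::tibble(
    v = v,
    alpha_m = vtrap(0.1 * (v + 35)),
    beta_m = 4 * exp(-(v + 60) / 18),
    alpha_h = 0.07 * exp(-(v + 58) / 20),
    beta_h = 1 / (exp(-0.1 * (v + 28)) + 1),
    alpha_n = 0.1 * vtrap(0.1 * (v + 34)),
    beta_n = 0.125 * exp(-(v + 44) / 80)
  )
}

#' Steady-state gating values
#'
#' `m_inf()` is the instantaneous Na\eqn{^+} activation used in place of a
#' dynamic m gate; `h_inf()` and `n_inf()` are the fixed points of the h
#' and n kinetics, used for steady initial conditions.
#'
#' @param v Membrane potential (mV); vectorised.
#' @return Numeric vector of values in \[0, 1\].
#' @export
m_inf <- function(v) {
  r <- rate_functions(v)
  r$alpha_m / (r$alpha_m + r$beta_m)
}

#' @rdname m_inf
#' @export
h_inf <- function(v) {
  r <- rate_functions(v)
  r$alpha_h / (r$alpha_h + r$beta_h)
}

#' @rdname m_inf
#' @export
n_inf <- function(v) {
  r <- rate_functions(v)
  r$alpha_n / (r$alpha_n + r$beta_n)
}

#' Time derivatives of the membrane state
#'
#' Right-hand side of the model: \eqn{C_m dV/dt = -I_{Na} - I_K - I_L -
#' I_{syn} + I_{app}} with \eqn{I_{Na} = g_{Na} m_\infty^3 h (V - E_{Na})},
#' \eqn{I_K = g_K n^4 (V - E_K)}, \eqn{I_L = g_L (V - E_L)}, and first-order
#' h/n kinetics scaled by \eqn{\phi}.
#'
#' @param v,h,n Membrane potential (mV) and gating variables.
#' @param params A [membrane_params()] object.
#' @param i_syn Synaptic current (\eqn{\mu}A/cm\eqn{^2}; positive = outward).
#' @param i_app Applied current (\eqn{\mu}A/cm\eqn{^2}; positive = inward).
#' @return Named numeric vector `c(dv, dh, dn)` (mV/ms, 1/ms, 1/ms).
#' @export
neuron_derivatives <- function(v, h, n, params, i_syn = 0, i_app = 0) {
  stopifnot(inherits(params, "membrane_params"))
  r <- rate_functions(v)
  minf <- r$alpha_m / (r$alpha_m + r$beta_m)
  ina <- params$gna * minf^3 * h * (v - params$ena)
  ik <- params$gk * n^4 * (v - params$ek)
  il <- params$gl * (v - params$el)
  c(dv = (-ina - ik - il - i_syn + i_app) / params$cm,
    dh = params$phi * (r$alpha_h * (1 - h) - r$beta_h * h),
    dn = params$phi * (r$alpha_n * (1 - n) - r$beta_n * n))
}

#' Resting state of the model neuron
#'
#' Solves for the fixed point of the full system (V with h and n at their
#' steady-state values) by root-finding on the total membrane current.
#'
#' @param params A [membrane_params()] object.
#' @param interval Search interval for the resting potential (mV).
#' @return Named numeric vector `c(v, h, n)`.
#' @export
#' @examples
#' resting_state(membrane_params())
resting_state <- function(params, interval = c(-90, -30)) {
  stopifnot(inherits(params, "membrane_params"))
  f <- function(v) {
    r <- rate_functions(v)
    minf <- r$alpha_m / (r$alpha_m + r$beta_m)
    hss <- r$alpha_h / (r$alpha_h + r$beta_h)
    nss <- r$alpha_n / (r$alpha_n + r$beta_n)
    -params$gna * minf^3 * hss * (v - params$ena) -
      params$gk * nss^4 * (v - params$ek) - params$gl * (v - params$el)
  }
  # locate a sign change on a grid first: near threshold the current
  # balance can have multiple roots and we want the hyperpolarised one
  grid <- seq(interval[1], interval[2], by = 0.5)
  fv <- f(grid)
  idx <- which(fv[-1] * fv[-length(fv)] <= 0)
  if (length(idx) == 0)
    stop_bad_input("no resting state found in [%g, %g] mV",
                   interval[1], interval[2])
  root <- uniroot(f, c(grid[idx[1]], grid[idx[1] + 1]), tol = 1e-10)$root
  c(v = root, h = h_inf(root), n = n_inf(root))
}

#' Convert leak conductance density to input resistance
#'
#' For a spherical soma of the given diameter, the total membrane
#' resistance is \eqn{R = 1/(g_L A)} with surface area \eqn{A = \pi d^2}.
#' With `gl` in mS/cm\eqn{^2} and `diameter` in \eqn{\mu}m this is
#' \eqn{R_{M\Omega} = 10^5 / (g_L \pi d^2)}.
#'
#' @param gl Leak conductance density (mS/cm\eqn{^2}); vectorised.
#' @param diameter Soma diameter (\eqn{\mu}m).
#' @return Resistance in M\eqn{\Omega}.
#' @export
#' @examples
#' membrane_resistance(c(0.282, 0.50, 0.75, 1.99, 5.3), diameter = 15)
membrane_resistance <- function(gl, diameter = 15) {
  if (!is.numeric(gl) || any(!is.finite(gl)) || any(gl <= 0))
    stop_bad_input("gl must be positive and finite")
  if (!is.numeric(diameter) || length(diameter) != 1 || !is.finite(diameter) ||
      diameter <= 0)
    stop_bad_input("diameter must be a positive scalar")
  1e5 / (gl * pi * diameter^2)
}
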