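#' Generate a phase-locked spike train
#'
#' Inhomogeneous point process whose intensity is modulated within each
#' stimulus cycle by a von Mises profile at frequency `f` with
#' concentration `kappa`, normalised so the mean rate equals `rate`.
#' `kappa = 0` gives a homogeneous Poisson process (vector strength near
#' 0); large `kappa` concentrates all spikes at one phase (vector
#' strength near 1). The expected vector strength of the generated train
#' is the von Mises mean resultant \eqn{I_1(\kappa)/I_0(\kappa)};
#' [kappa_for_vs()] inverts that relation so trains with a target vector
#' strength can be generated directly. Spikes are drawn by thinning a
#' homogeneous process, so output is exact and fully seeded.
#'
#' @param rate Mean firing rate (spikes/s).
#' @param frequency Modulation frequency (Hz).
#' @param kappa von Mises concentration (>= 0).
#' @param duration Train length (ms).
#' @param seed Integer seed (mandatory for reproducibility).
#' @param mu Preferred phase (radians).
#' @return Sorted numeric vector of spike times in \[0, duration\) (ms).
#' @export
#' @examples
#' s <- gen_phase_locked_spikes(100, 16, kappa_for_vs(0.9), 5000, seed = 1)
#' vector_strength(s, 16)
gen_phase_locked_spikes <- function(rate, frequency, kappa, duration, seed,
                                    mu = 0) {
  if (rate < 0) stop_bad_input("rate must be >= 0")
  if (kappa < 0) stop_bad_input("kappa must be >= 0")
  if (rate == 0) return(numeric(0))
  withr::with_seed(seed, {
    # intensity(t) = rate * exp(kappa (cos(theta - mu) - 1)) / I0e(kappa)
    # where I0e = exp(-kappa) I0(kappa); peak value rate / I0e(kappa)
    i0e <- besselI(kappa, 0, expon.scaled = TRUE)
    lam_max <- rate / i0e
    n_cand <- rpois(1, lam_max * duration / 1000)
    cand <- sort(runif(n_cand, 0, duration))
    theta <- 2 * pi * frequency * cand / 1000
    p_keep <- exp(kappa * (cos(theta - mu) - 1))
    cand[runif(n_cand) < p_keep]
  })
}

#' @rdname gen_phase_locked_spikes
#' @param vs Target vector strength in \[0, 1).
#' @export
kappa_for_vs <- function(vs) {
  if (vs < 0 || vs >= 1) stop_bad_input("target vector strength must be in [0, 1)")
  if (vs == 0) return(0)
  a <- function(k) besselI(k, 1, expon.scaled = TRUE) /
    besselI(k, 0, expon.scaled = TRUE)
  uniroot(function(k) a(k) - vs, c(1e-8, 1e4), tol = 1e-10)$root
}

#' Generate a synthetic EPSC/EPSP trace
#'
#' Forward model of the double-exponential fit equation
#' ([epsc_model()]) plus iid Gaussian noise, sampled on a uniform grid.
#' With `noise_sd = 0` the trace is the noiseless model, so fitting it
#' recovers the parameters exactly.
#'
#' @param y0,amp,x0,tau_rise,tau_decay Model parameters (see
#'   [epsc_model()]).
#' @param noise_sd Gaussian noise SD (same units as `amp`).
#' @param dt Sampling interval (ms).
#' @param duration Trace length (ms).
#' @param seed Integer seed (required when `noise_sd > 0`).
#' @return A tibble with columns `time`, `value`.
#' @export
gen_epsc_trace <- function(y0, amp, x0, tau_rise, tau_decay, noise_sd = 0,
                           dt = 0.1, duration = 300, seed = NULL) {
  if (tau_rise >= tau_decay) stop_bad_input("need tau_rise < tau_decay")
  t <- seq(0, duration, by = dt)
  v <- epsc_model(t, y0, amp, x0, tau_rise, tau_decay)
  if (noise_sd > 0) {
    if (is.null(seed)) stop_bad_input("seed is required when noise_sd > 0")
    v <- v + withr::with_seed(seed, rnorm(length(t), 0, noise_sd))
  }
  tibble::tibble(time = t, value = v)
}

#' Generate a synthetic per-cell marker table
#'
#' Draws each tdTomato-positive cell's co-expression class from a
#' multinomial over `{only2d, only2c, both, neither}` and assigns puncta
#' counts (>= 1 for positive channels, 0 otherwise). Default class
#' probabilities follow the published grand-total proportions of VIP
#' neurons expressing only Glun2d (0.843), only Glun2c (0.010) and both
#' (0.071).
#'
#' @param n_cells Number of tdTomato-positive cells.
#' @param p_only2d,p_only2c,p_both Class probabilities (remainder is
#'   "neither").
#' @param seed Integer seed.
#' @param mean_puncta Mean of the (shifted) Poisson puncta count for
#'   positive channels.
#' @return A per-cell tibble as in [marker_table_from_counts()].
#' @export
#' @examples
#' summarize_expression(gen_marker_table(521, seed = 1))
gen_marker_table <- function(n_cells, p_only2d = 0.843, p_only2c = 0.010,
                             p_both = 0.071, seed, mean_puncta = 3) {
  p <- c(p_only2d, p_only2c, p_both)
  if (any(p < 0) || sum(p) > 1)
    stop_bad_input("class probabilities must be >= 0 and sum to <= 1")
  if (n_cells == 0) {
    return(tibble::tibble(cell_id = character(), tdtomato_positive = logical(),
                          glun2c_puncta = integer(), glun2d_puncta = integer()))
  }
  withr::with_seed(seed, {
    cls <- sample(c("only2d", "only2c", "both", "neither"), n_cells,
                  replace = TRUE, prob = c(p, 1 - sum(p)))
    pos_2d <- cls %in% c("only2d", "both")
    pos_2c <- cls %in% c("only2c", "both")
    draw <- function(pos) {
      k <- integer(length(pos))
      k[pos] <- 1L + rpois(sum(pos), mean_puncta - 1)
      k
    }
    tibble::tibble(
      cell_id = sprintf("cell%05d", seq_len(n_cells)),
      tdtomato_positive = TRUE,
      glun2c_puncta = draw(pos_2c),
      glun2d_puncta = draw(pos_2d)
    )
  })
}
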