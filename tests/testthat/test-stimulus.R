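test_that("periodic trains have the right count, spacing and floor rule", {
  tr <- make_train(16, 1000)
  expect_length(tr$onsets, 16)
  expect_equal(tr$onsets[1:3], c(0, 62.5, 125))
  expect_length(make_train(512, 1000)$onsets, 512)
  expect_length(make_train(100, 55)$onsets, 5)
  expect_true(all(diff(make_train(37, 800)$onsets) - 1000 / 37 < 1e-12))
  expect_error(make_train(0, 100), class = "nmdagain_invalid_input")
  expect_error(make_train(16, 100, offset = 200),
               class = "nmdagain_invalid_input")
})

test_that("the geometric frequency grid spans 16-512 Hz at 4 steps/octave with 21 points", {
  f <- frequency_grid(16, 512, 4)
  expect_length(f, 21)
  expect_equal(f[1], 16)
  expect_equal(f[21], 512)
  expect_equal(diff(log2(f)), rep(0.25, 20))
  expect_equal(frequency_grid(16, 32, 1), c(16, 32))
})

test_that("single-pulse conductance peaks exactly at g_max (analytic normalisation vs numeric maximisation)", {
  withr::with_seed(21, {
    for (i in 1:20) {
      tr <- runif(1, 0.1, 6)
      td <- tr * runif(1, 1.5, 40)
      peak <- optimize(function(t) synaptic_pulse(t, tr, td, g_max = 2.5),
                       c(0, 12 * td), maximum = TRUE, tol = 1e-10)
      expect_equal(peak$objective, 2.5, tolerance = 1e-7)
      expect_equal(peak$maximum, synaptic_peak_time(tr, td), tolerance = 1e-4)
    }
  })
  expect_error(synaptic_pulse(1, 5, 2), class = "nmdagain_invalid_input")
})

test_that("waveform superposition is exact and linear for off-grid onsets", {
  syn <- synapse_params(g_ampa = 0.3, nmda_saturation = FALSE)
  grid <- seq(0, 120, by = 0.01)
  # an irregular-period train puts onsets between grid points
  tr <- make_train(37, 120, offset = 0.003)
  wf <- conductance_waveform(tr, syn, grid)
  direct_a <- Reduce(`+`, lapply(tr$onsets, function(o) {
    synaptic_pulse(grid, syn$tau_rise_ampa, syn$tau_decay_ampa, t0 = o,
                   g_max = syn$g_ampa)
  }))
  direct_n <- Reduce(`+`, lapply(tr$onsets, function(o) {
    synaptic_pulse(grid, syn$tau_rise_nmda, syn$tau_decay_nmda, t0 = o,
                   g_max = syn$nmda_ratio * syn$g_ampa)
  }))
  expect_equal(wf$g_ampa, direct_a, tolerance = 1e-10)
  expect_equal(wf$g_nmda, direct_n, tolerance = 1e-10)
  expect_true(all(wf$g_ampa >= 0 & wf$g_nmda >= 0))

  # linearity: two-pulse waveform equals the sum of the single-pulse ones
  two <- make_train(1000 / 1.7, 4)
  expect_length(two$onsets, 2)
  one <- make_train(250, 4) # single onset at 0
  w2 <- conductance_waveform(two, syn, grid)
  w1a <- conductance_waveform(one, syn, grid)
  shifted <- synaptic_pulse(grid, syn$tau_rise_ampa, syn$tau_decay_ampa,
                            t0 = two$onsets[2], g_max = syn$g_ampa)
  expect_equal(w2$g_ampa, w1a$g_ampa + shifted, tolerance = 1e-10)
})

test_that("two closely spaced slow pulses sum to the analytic two-term maximum", {
  syn <- synapse_params(g_ampa = 1, tau_rise_ampa = 0.2, tau_decay_ampa = 50,
                        nmda_on = FALSE)
  grid <- seq(0, 300, by = 0.002)
  tr <- make_train(1000, 2) # onsets at 0 and 1 ms
  wf <- conductance_waveform(tr, syn, grid)
  # dense-grid maximisation of the closed-form two-term sum
  two_term <- function(t) {
    synaptic_pulse(t, 0.2, 50, t0 = 0) + synaptic_pulse(t, 0.2, 50, t0 = 1)
  }
  expect_equal(max(wf$g_ampa), max(two_term(grid)), tolerance = 1e-8)
  expect_gt(max(wf$g_ampa), 1.5) # genuine summation of the slow kinetics
})

test_that("NMDA saturation caps the summed conductance at its nominal maximum", {
  grid <- seq(0, 1000, by = 0.05)
  tr <- make_train(256, 1000)
  syn_lin <- synapse_params(g_ampa = 0.2, nmda_saturation = FALSE)
  syn_sat <- synapse_params(g_ampa = 0.2, nmda_saturation = TRUE)
  cap <- 0.25 * 0.2
  lin <- conductance_waveform(tr, syn_lin, grid)
  sat <- conductance_waveform(tr, syn_sat, grid)
  expect_gt(max(lin$g_nmda), 3 * cap) # unbounded linear accumulation
  expect_lte(max(sat$g_nmda), cap + 1e-12)
  expect_equal(sat$g_nmda, pmin(lin$g_nmda, cap))
  # the AMPA component is never capped
  expect_equal(sat$g_ampa, lin$g_ampa)
})

test_that("nmda_ratio = 0 and nmda_on = FALSE both silence the NMDA conductance", {
  grid <- seq(0, 100, by = 0.05)
  tr <- make_train(64, 100)
  w0 <- conductance_waveform(tr, synapse_params(g_ampa = 0.2, nmda_ratio = 0),
                             grid)
  woff <- conductance_waveform(tr, synapse_params(g_ampa = 0.2,
                                                  nmda_on = FALSE), grid)
  expect_true(all(w0$g_nmda == 0))
  expect_true(all(woff$g_nmda == 0))
})

test_that("synapse kinetics invariants are enforced", {
  expect_error(synapse_params(tau_rise_ampa = 3, tau_decay_ampa = 2),
               class = "nmdagain_invalid_input")
  expect_error(synapse_params(nmda_ratio = -0.1),
               class = "nmdagain_invalid_input")
  expect_error(conductance_waveform(make_train(16, 100), synapse_params(),
                                    seq(0, 100, 0.1)),
               class = "nmdagain_invalid_input") # g_ampa unset
})

test_that("calibration brackets the single-pulse threshold: scaled conductance is sub-, threshold is suprathreshold", {
  mem <- ref_membrane()
  syn <- ref_synapse()
  thr <- attr(syn, "g_threshold")
  expect_equal(syn$g_ampa, 0.85 * thr)
  probe <- function(g) {
    s <- syn
    s$g_ampa <- g
    s$nmda_on <- FALSE
    length(simulate_neuron(mem, make_train(10, 100, offset = 5), s,
                           duration = 100)$spikes)
  }
  expect_identical(probe(syn$g_ampa), 0L)
  expect_gte(probe(thr * 1.001), 1L)
})
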