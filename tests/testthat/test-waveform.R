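test_that("the double-exponential fit recovers noiseless parameters exactly", {
  truth <- c(y0 = 0, amp = -50, x0 = 20, tau_rise = 2, tau_decay = 40)
  tr <- gen_epsc_trace(0, -50, 20, 2, 40, noise_sd = 0, dt = 0.1,
                       duration = 300)
  fit <- fit_epsc(tr)
  expect_lt(max(abs(fit$estimate - truth) / pmax(abs(truth), 1)), 1e-6)
  expect_lt(fit$rss, 1e-12)

  td <- tidy(fit)
  expect_identical(td$term,
                   c("y0", "amp", "x0", "tau_rise", "tau_decay"))
  expect_true(glance(fit)$converged)
})

test_that("fitting refuses flat traces rather than returning a degenerate fit", {
  flat <- gen_epsc_trace(-60, 0, 20, 2, 40, noise_sd = 0, dt = 0.1,
                         duration = 100)
  expect_error(fit_epsc(flat), class = "nmdagain_invalid_input")
})

test_that("decay tau is recovered within 10% from 5%-noise traces (200 replicates)", {
  peak <- abs(-50) * (1 - exp(-synaptic_peak_time(2, 40) / 2)) *
    exp(-synaptic_peak_time(2, 40) / 40)
  est <- vapply(1:200, function(i) {
    tr <- gen_epsc_trace(0, -50, 20, 2, 40, noise_sd = 0.05 * peak,
                         dt = 0.1, duration = 300, seed = 5000 + i)
    fit_epsc(tr)$estimate[["tau_decay"]]
  }, numeric(1))
  rmse <- sqrt(mean((est - 40)^2))
  expect_lt(rmse / 40, 0.10)
  expect_lt(abs(mean(est) - 40) / 40, 0.05) # bias well below the spread
})

test_that("waveform metrics match dense-grid closed-form values for an ideal event", {
  # event from the fit equation; oracle values from a very dense grid of
  # the closed form, independent of measure_waveform internals
  y0 <- -60; amp <- -45; x0 <- 50; tr <- 1.5; td <- 35
  dense_t <- seq(0, 400, by = 1e-3)
  dense <- epsc_model(dense_t, y0, amp, x0, tr, td)
  dev <- dense - y0
  i_pk <- which.min(dense)
  amp_oracle <- dense[i_pk] - y0
  half <- dev <= amp_oracle / 2 # negative-going event
  hw_oracle <- diff(range(dense_t[half]))
  r10 <- min(dense_t[dev <= 0.1 * amp_oracle])
  r90 <- min(dense_t[dev <= 0.9 * amp_oracle])

  trace <- tibble::tibble(time = seq(0, 400, by = 0.05),
                          value = epsc_model(seq(0, 400, by = 0.05),
                                             y0, amp, x0, tr, td))
  m <- measure_waveform(trace, baseline_window = c(0, 45))
  expect_equal(m$baseline, y0, tolerance = 1e-10)
  expect_equal(m$amplitude, amp_oracle, tolerance = 1e-4)
  expect_equal(m$halfwidth, hw_oracle, tolerance = 1e-3)
  expect_equal(m$rise_time, r90 - r10, tolerance = 1e-3)
  # decay tau from single-exponential refit within 5% when tau_decay >= 5 tau_rise
  expect_lt(abs(m$decay_tau - td) / td, 0.05)
})

test_that("halfwidth of a rectangular pulse equals its width and a pure exponential returns its tau", {
  tt <- seq(0, 100, by = 0.01)
  rect <- tibble::tibble(time = tt, value = as.numeric(tt >= 40 & tt < 55))
  m <- measure_waveform(rect, c(0, 35))
  expect_equal(m$halfwidth, 15, tolerance = 1e-2)

  te <- seq(0, 250, by = 0.01)
  ex <- tibble::tibble(time = te,
                       value = ifelse(te >= 20, 10 * exp(-(te - 20) / 30), 0))
  expect_equal(measure_waveform(ex, c(0, 19),
                                polarity = "positive")$decay_tau, 30,
               tolerance = 0.01)
})

test_that("a trace that never crosses half amplitude flags halfwidth undefined", {
  tt <- seq(0, 50, 0.1)
  ramp <- tibble::tibble(time = tt, value = pmin(tt / 50, 1)) # never decays
  m <- measure_waveform(ramp, c(0, 2))
  expect_false(m$halfwidth_defined)
  expect_true(is.na(m$halfwidth))
})

test_that("sweep averaging is the pointwise mean and enforces a shared time base", {
  t <- seq(0, 10, 0.1)
  s1 <- tibble::tibble(time = t, value = sin(t))
  expect_equal(average_sweeps(list(s1, s1))$value, s1$value)
  s2 <- tibble::tibble(time = t, value = -sin(t))
  expect_equal(average_sweeps(list(s1, s2))$value, rep(0, length(t)))
  withr::with_seed(31, {
    sweeps <- lapply(1:5, function(i) tibble::tibble(time = t,
                                                     value = rnorm(length(t))))
    expect_equal(average_sweeps(sweeps)$value,
                 rowMeans(sapply(sweeps, `[[`, "value"))) # brute-force oracle
  })
  bad <- tibble::tibble(time = t + 0.05, value = sin(t))
  expect_error(average_sweeps(list(s1, bad)), class = "nmdagain_invalid_input")
})

test_that("summation metrics: slow-kinetics trains sum, fast ones do not, and AUC tracks the slow component", {
  onsets <- 100 + (0:4) * 1000 / 30 # 5 pulses at 30 Hz
  t <- seq(0, 500, by = 0.05)
  slow <- Reduce(`+`, lapply(onsets, function(o) epsc_model(t, 0, 4, o, 5, 100)))
  fast <- Reduce(`+`, lapply(onsets, function(o) epsc_model(t, 0, 6, o, 0.5, 8)))

  summating <- tibble::tibble(time = t, value = -65 + fast + slow)
  sm <- summation_metrics(summating, onsets, baseline_window = c(0, 90))
  expect_identical(nrow(sm$peaks), 5L)
  expect_true(all(diff(sm$peaks$amplitude) > 0)) # strictly increasing peaks

  independent <- tibble::tibble(time = t, value = -65 + fast)
  smi <- summation_metrics(independent, onsets, baseline_window = c(0, 90))
  expect_lt(diff(range(smi$peaks$amplitude)) / max(smi$peaks$amplitude), 0.02)

  reduced <- tibble::tibble(time = t, value = -65 + fast + 0.3 * slow)
  smr <- summation_metrics(reduced, onsets, baseline_window = c(0, 90))
  expect_lt(smr$auc, sm$auc) # blocking the slow conductance shrinks the AUC
  expect_identical(tidy(sm), sm$peaks)

  expect_error(summation_metrics(summating, onsets[1], c(0, 90)),
               class = "nmdagain_invalid_input")
})

test_that("zero-phase low-pass filtering preserves slow events", {
  tr <- gen_epsc_trace(0, -50, 20, 2, 40, noise_sd = 0, dt = 0.02,
                       duration = 200)
  lp <- lowpass_trace(tr, cutoff = 3)
  expect_equal(min(lp$value), min(tr$value), tolerance = 1e-2)
  # peak must not shift (zero phase)
  expect_equal(lp$time[which.min(lp$value)], tr$time[which.min(tr$value)],
               tolerance = 0.1)
})
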