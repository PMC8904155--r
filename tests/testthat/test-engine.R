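test_that("a zero-amplitude train leaves the cell at rest", {
  pair <- reduced_pair_cached(1)
  tr0 <- pulse_train(0, 0.5, 0, 120, 250)
  sz <- simulate_cell(pair$a2, tr0)
  sr <- simulate_cell(pair$a2, train = NULL, electrode = NULL,
                      duration = 250)
  expect_length(sz$spike_times, 0)
  expect_lt(abs(tail(sz$soma_voltage, 1) - tail(sr$soma_voltage, 1)), 1)
})

test_that("a passive compartment follows the RC charging curve", {
  cell <- passive_soma_cell()
  i_na <- 0.01 # nA
  sim <- simulate_cell(cell, train = NULL, electrode = NULL,
                       iclamp = data.frame(onset = 0, dur = 100, amp = i_na),
                       duration = 100)
  area <- pi * 20e-4 * 20e-4                 # cm^2
  r_in <- 1 / (5e-5 * area)                  # Ohm
  tau <- 1 / 5e-5 * 1e-6 * 1e3               # ms (Cm/gL)
  v_pred <- -65 + i_na * 1e-9 * r_in * (1 - exp(-1)) * 1e3
  v_sim <- sim$soma_voltage[which.min(abs(sim$time - tau))]
  expect_equal(v_sim - (-65), v_pred - (-65), tolerance = 0.01)
})

test_that("spike detection thresholds, interpolates and applies dead time", {
  st <- solver_settings(spike_threshold = -20, spike_deadtime = 1)
  tt <- seq(0, 50, by = 0.1)
  expect_length(detect_spikes(rep(-65, length(tt)), tt, st), 0)
  # two excursions 10 ms apart
  tr <- make_synthetic_trace(c(10, 20), duration = 50, dt = 0.1)
  expect_length(detect_spikes(tr$trace, tr$time, st), 2)
  # two crossings 0.5 ms apart with 1 ms dead time count once
  v <- rep(-65, length(tt))
  v[tt >= 10 & tt < 10.2] <- 0
  v[tt >= 10.5 & tt < 10.7] <- 0
  expect_length(detect_spikes(v, tt, st), 1)
})

test_that("spike metrics recover constructed width and latency", {
  st <- solver_settings()
  tt <- seq(0, 20, by = 0.01)
  # symmetric triangular spike with a 2 ms base: FWHM is 1 ms
  peak_t <- 10
  v <- -65 + pmax(0, 1 - abs(tt - peak_t) / 1) * 105
  m <- spike_metrics(v, tt, st, resting = -65, pulse_onsets = NULL)
  expect_equal(m$width_at_half_max, 1, tolerance = 0.02)
  expect_equal(m$peak, 40, tolerance = 1e-6)
  # latency zero when the crossing coincides with the onset
  cross_t <- peak_t - 1 + (45 / 105) # where v crosses -20 going up
  m2 <- spike_metrics(v, tt, st, resting = -65, pulse_onsets = cross_t)
  expect_equal(m2$latency_from_pulse_onset, 0, tolerance = 0.02)
  expect_error(spike_metrics(rep(-65, length(tt)), tt, st), "no spike")
})

test_that("latency shrinks when the stimulus is raised above threshold", {
  pair <- reduced_pair_cached(1)
  st <- solver_settings()
  lat <- function(amp) {
    sim <- simulate_cell(pair$a2, train = NULL, electrode = NULL,
                         iclamp = data.frame(onset = 20, dur = 1, amp = amp),
                         duration = 60)
    spike_metrics(sim$soma_voltage, sim$time, st,
                  pulse_onsets = 20)$latency_from_pulse_onset
  }
  expect_gt(lat(0.7), lat(1.05))
})

test_that("simulations are bit-deterministic", {
  pair <- reduced_pair_cached()
  tr <- pulse_train(20, 0.5, 0, 120, 100)
  s1 <- simulate_cell(pair$a2, tr)
  s2 <- simulate_cell(pair$a2, tr)
  expect_identical(s1$soma_voltage, s2$soma_voltage)
  expect_identical(s1$spike_times, s2$spike_times)
})

test_that("numerical divergence is reported with its time", {
  pair <- reduced_pair_cached()
  tr <- pulse_train(3000, 0.5, 0, 120, 50)
  expect_error(simulate_cell(pair$a2, tr), "divergence at t =")
})

test_that("anodic-first stimulation is never easier than cathodic-first", {
  pair <- reduced_pair_cached()
  prob_pol <- function(amp, pol) {
    tr <- pulse_train(amp, 0.5, 0, 120, 250, polarity = pol)
    spike_probability(simulate_cell(pair$a2, tr)$spike_times, tr)
  }
  for (amp in c(6, 8, 10)) {
    expect_gte(prob_pol(amp, "cathodic_first"), prob_pol(amp, "anodic_first"))
  }
})

test_that("paired-pulse intervals below the refractory period fail, above succeed", {
  pair <- reduced_pair_cached()
  rp <- measure_refractory(pair$a2, pulse_width = 0.5, resolution = 0.5)
  expect_true(rp >= 1 && rp <= 50)
  expect_equal(rp %% 0.5, 0)
  # bisection agrees with an exhaustive ascending scan
  rp_scan <- measure_refractory(pair$a2, pulse_width = 0.5, resolution = 0.5,
                                method = "scan")
  expect_identical(rp, rp_scan)
})
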