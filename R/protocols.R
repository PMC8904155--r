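#' Spike probability of a pulse-train response
#'
#' Total counted spikes divided by the number of delivered stimulus pulses,
#' with each stimulus period contributing at most one counted spike.
#'
#' @param spike_times Spike times, ms.
#' @param train The [pulse_train()] that was delivered (its duration must
#'   cover an integer number of periods).
#' @return Fraction in [0, 1].
#' @export
spike_probability <- function(spike_times, train) {
  nper <- round(train$duration / train$period)
  if (nper < 1) stop("train must contain at least one period")
  if (!length(spike_times)) return(0)
  bins <- floor(spike_times / train$period)
  bins <- bins[bins < nper]
  length(unique(bins)) / nper
}

#' @noRd
firing_rate <- function(prob, frequency) prob * frequency

#' @noRd
response_at <- function(cell, amplitude, pulse_width, ipg, frequency,
                        duration, electrode, settings) {
  train <- pulse_train(amplitude, pulse_width, ipg, frequency, duration)
  sim <- simulate_cell(cell, train, electrode, settings = settings)
  spike_probability(sim$spike_times, train)
}

#' Minimum current achieving a target spike probability
#'
#' Implements the operational threshold definition: the minimum stimulus
#' amplitude (on a fixed resolution grid) for which the spike probability
#' over the train reaches `target` -- by default 100% at 120 Hz, the tuning
#' frequency used before any frequency-response comparison.  An upper
#' bracket is found by amplitude doubling, then bisection refines to the
#' grid; the result carries a minimality certificate (the next lower grid
#' amplitude fails the target).
#'
#' @param cell A [build_preset_cell()] model.
#' @param pulse_width,ipg Phase width and interphase gap, ms.
#' @param frequency Tuning frequency, Hz.
#' @param target Target spike probability.
#' @param resolution Amplitude grid step, uA.
#' @param duration Train duration, ms.
#' @param amp_start Initial amplitude for the doubling bracket, uA.
#' @param amp_cap Largest amplitude tried, uA; if the target is not reached
#'   below the cap the cell is reported non-excitable (error).
#' @param electrode An [electrode_model()].
#' @param settings A [solver_settings()].
#' @param method `"bisection"` (default) or `"scan"` (exhaustive ascending
#'   scan at `resolution`, used as an oracle).
#' @return A `threshold_result`: list with `current` (uA), `charge` (nC),
#'   `achieved_probability`, and `search_trace` (amplitude, probability).
#' @export
find_threshold <- function(cell, pulse_width = 0.5, ipg = 0, frequency = 120,
                           target = 1.0, resolution = 1, duration = 1000,
                           amp_start = 10, amp_cap = 5000,
                           electrode = electrode_model(),
                           settings = solver_settings(),
                           method = c("bisection", "scan")) {
  method <- match.arg(method)
  trace <- data.frame(amplitude = numeric(0), probability = numeric(0))
  probe <- function(amp) {
    hit <- which(abs(trace$amplitude - amp) < 1e-9)
    if (length(hit)) return(trace$probability[hit[1]])
    p <- response_at(cell, amp, pulse_width, ipg, frequency, duration,
                     electrode, settings)
    trace[nrow(trace) + 1, ] <<- c(amp, p)
    p
  }
  snap_up <- function(a) ceiling(a / resolution - 1e-9) * resolution

  if (method == "scan") {
    amp <- resolution
    while (amp <= amp_cap) {
      if (probe(amp) >= target) {
        return(threshold_result(amp, pulse_width, probe(amp), trace))
      }
      amp <- amp + resolution
    }
    stop("non-excitable under protocol: target not reached below ", amp_cap,
         " uA")
  }

  amp <- amp_start
  while (probe(amp) < target) {
    amp <- amp * 2
    if (amp > amp_cap) {
      stop("non-excitable under protocol: target not reached below ",
           amp_cap, " uA")
    }
  }
  hi <- snap_up(amp)
  if (hi != amp && probe(hi) < target) {
    # snapped value must itself pass; widen by one grid step if not
    hi <- hi + resolution
    if (probe(hi) < target) stop("bracket lost while snapping to grid")
  }
  lo <- if (amp == amp_start) 0 else amp / 2
  lo <- floor(lo / resolution + 1e-9) * resolution
  while (hi - lo > resolution + 1e-9) {
    mid <- round((hi + lo) / 2 / resolution) * resolution
    if (mid <= lo || mid >= hi) mid <- lo + resolution
    if (probe(mid) >= target) hi <- mid else lo <- mid
  }
  # minimality certificate
  if (hi - resolution > 0 && probe(hi - resolution) >= target) {
    hi <- hi - resolution
    while (hi - resolution > 0 && probe(hi - resolution) >= target) {
      hi <- hi - resolution
    }
  }
  threshold_result(hi, pulse_width, probe(hi), trace)
}

#' @noRd
threshold_result <- function(current, pulse_width, prob, trace) {
  structure(list(current = current, charge = current * pulse_width,
                 achieved_probability = prob,
                 search_trace = trace[order(trace$amplitude), ]),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("threshold: %.4g uA (%.4g nC/phase), probability %.3g, %d evaluations\n",
              x$current, x$charge, x$achieved_probability,
              nrow(x$search_trace)))
  invisible(x)
}

#' Firing rate as a function of stimulus amplitude
#'
#' One simulation per amplitude on a regular grid (the published scans use
#' 5 uA steps).  Firing rates follow the one-spike-per-pulse counting rule:
#' `rate = spike_probability * frequency`.
#'
#' @param cell A [build_preset_cell()] model.
#' @param amplitudes Amplitude grid, uA (regular, ascending), or a length-2
#'   range used together with `step`.
#' @param step Grid step when `amplitudes` is a range, uA.
#' @param pulse_width,ipg,frequency,duration Stimulus parameters.
#' @param electrode,settings See [simulate_cell()].
#' @return A `response_curve`: data.frame with `amplitude`, `probability`,
#'   `rate`, plus context attributes.
#' @export
rate_vs_amplitude <- function(cell, amplitudes, step = 5, pulse_width = 0.1,
                              ipg = 0, frequency = 200, duration = 1000,
                              electrode = electrode_model(),
                              settings = solver_settings()) {
  if (length(amplitudes) == 2) {
    amplitudes <- seq(amplitudes[1], amplitudes[2], by = step)
  }
  prob <- vapply(amplitudes, function(a) {
    response_at(cell, a, pulse_width, ipg, frequency, duration, electrode,
                settings)
  }, numeric(1))
  curve <- data.frame(amplitude = amplitudes, probability = prob,
                      rate = firing_rate(prob, frequency))
  attr(curve, "context") <- list(cell = cell$label, pulse_width = pulse_width,
                                 ipg = ipg, frequency = frequency,
                                 duration = duration)
  class(curve) <- c("response_curve", "data.frame")
  curve
}

#' Widest flat stretch of a response curve
#'
#' Finds the widest contiguous amplitude interval over which the spike
#' probability stays within `tol` of `level` (default the half-maximum
#' plateau at 50% probability).
#'
#' @param curve A [rate_vs_amplitude()] result.
#' @param level Probability level of the plateau.
#' @param tol Probability tolerance defining "flat".
#' @return List with `width` (uA, 0 if no plateau) and `interval`.
#' @export
saturation_window <- function(curve, level = 0.5, tol = 0.02) {
  stopifnot(nrow(curve) > 0)
  ok <- abs(curve$probability - level) <= tol
  if (!any(ok)) return(list(width = 0, interval = NULL))
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  widths <- curve$amplitude[ends[runs]] - curve$amplitude[starts[runs]]
  b <- runs[which.max(widths)]
  list(width = max(widths),
       interval = c(curve$amplitude[starts[b]], curve$amplitude[ends[b]]))
}

#' @noRd
first_amp_reaching <- function(curve, target_rate) {
  i <- which(curve$rate >= target_rate)
  if (!length(i)) return(NA_real_)
  i <- i[1]
  if (i == 1) return(curve$amplitude[1])
  approx(curve$rate[(i - 1):i], curve$amplitude[(i - 1):i],
         xout = target_rate)$y
}

#' Firing-rate difference between two response curves
#'
#' The per-amplitude difference `curve_b - curve_a` (curves are linearly
#' interpolated onto a shared grid when their grids differ) and the
#' amplitude gap to reach a target firing rate -- the basis of the
#' selective-activation argument: a large gap means one cell can be driven
#' at the target rate while the other stays quiet.
#'
#' @param curve_a,curve_b [rate_vs_amplitude()] results.
#' @param target_rate Target firing rate for the gap, Hz.
#' @return List with `difference` (data.frame amplitude, rate_diff),
#'   `gap` (uA, `amp_b(target) - amp_a(target)`; NA with `reached_a`/`_b`
#'   flags when a curve never reaches the target).
#' @export
differential_response <- function(curve_a, curve_b, target_rate = 20) {
  grid <- curve_a$amplitude
  rb <- if (identical(curve_b$amplitude, grid)) curve_b$rate else {
    approx(curve_b$amplitude, curve_b$rate, xout = grid)$y
  }
  diff <- data.frame(amplitude = grid, rate_diff = rb - curve_a$rate)
  aa <- first_amp_reaching(curve_a, target_rate)
  ab <- first_amp_reaching(curve_b, target_rate)
  list(difference = diff, gap = ab - aa,
       reached_a = !is.na(aa), reached_b = !is.na(ab))
}

#' @noRd
sweep_core <- function(cell_a2, cell_d1, grid, grid_name, pulse_width, ipg,
                       tune_frequency, test_frequency, resolution, duration,
                       electrode, settings) {
  out <- lapply(grid, function(g) {
    pw <- if (grid_name == "pulse_width") g else pulse_width
    gap <- if (grid_name == "ipg") g else ipg
    th_a2 <- find_threshold(cell_a2, pw, gap, tune_frequency, 1.0,
                            resolution, duration, electrode = electrode,
                            settings = settings)
    th_d1 <- find_threshold(cell_d1, pw, gap, tune_frequency, 1.0,
                            resolution, duration, electrode = electrode,
                            settings = settings)
    p_a2 <- response_at(cell_a2, th_a2$current, pw, gap, test_frequency,
                        duration, electrode, settings)
    p_d1 <- response_at(cell_d1, th_d1$current, pw, gap, test_frequency,
                        duration, electrode, settings)
    data.frame(value = g, current_a2 = th_a2$current,
               current_d1 = th_d1$current,
               rate_a2 = firing_rate(p_a2, test_frequency),
               rate_d1 = firing_rate(p_d1, test_frequency))
  })
  res <- do.call(rbind, out)
  names(res)[1] <- grid_name
  res$rate_difference <- res$rate_d1 - res$rate_a2
  attr(res, "context") <- list(tune_frequency = tune_frequency,
                               test_frequency = test_frequency,
                               pulse_width = pulse_width, ipg = ipg,
                               resolution = resolution, duration = duration)
  class(res) <- c("sweep_result", "data.frame")
  res
}

#' Strength-duration sweep with a 200 Hz frequency-response test
#'
#' For each pulse width, tunes each cell's amplitude to 100% spike
#' probability at the tuning frequency (120 Hz), then measures both cells'
#' firing rates at the test frequency (200 Hz) with those tuned currents.
#' The rate difference is signed D1 - A2 (positive = D1 more responsive).
#'
#' @param cell_a2,cell_d1 The two cell models being compared.
#' @param pulse_widths Pulse-width grid, ms.
#' @param ipg Interphase gap held fixed, ms.
#' @param tune_frequency,test_frequency Hz.
#' @param resolution Threshold grid, uA (default 5, the granularity of the
#'   published amplitude scans; the tuned current then sits at most one grid
#'   step above the true threshold for every cell and grid value alike).
#' @param duration Train duration, ms.
#' @param electrode,settings See [simulate_cell()].
#' @return A `sweep_result` data.frame: pulse_width, tuned currents, rates
#'   at the test frequency, and `rate_difference`.
#' @export
strength_duration_sweep <- function(cell_a2, cell_d1,
                                    pulse_widths = c(0.1, 0.2, 0.3, 0.5,
                                                     0.8, 1.0, 1.2),
                                    ipg = 0, tune_frequency = 120,
                                    test_frequency = 200, resolution = 5,
                                    duration = 1000,
                                    electrode = electrode_model(),
                                    settings = solver_settings()) {
  stopifnot(length(pulse_widths) > 0)
  sweep_core(cell_a2, cell_d1, pulse_widths, "pulse_width", NA, ipg,
             tune_frequency, test_frequency, resolution, duration,
             electrode, settings)
}

#' Interphase-gap sweep at fixed pulse width
#'
#' As [strength_duration_sweep()], with the interphase gap swept at a fixed
#' pulse width (0.5 ms, the waveform used clinically).
#'
#' @inheritParams strength_duration_sweep
#' @param ipgs Interphase-gap grid, ms.
#' @param pulse_width Fixed phase width, ms.
#' @return A `sweep_result` data.frame with column `ipg`.
#' @export
ipg_sweep <- function(cell_a2, cell_d1,
                      ipgs = c(0, 0.1, 0.2, 0.5, 1.0), pulse_width = 0.5,
                      tune_frequency = 120, test_frequency = 200,
                      resolution = 5, duration = 1000,
                      electrode = electrode_model(),
                      settings = solver_settings()) {
  stopifnot(length(ipgs) > 0)
  sweep_core(cell_a2, cell_d1, ipgs, "ipg", pulse_width, NA,
             tune_frequency, test_frequency, resolution, duration,
             electrode, settings)
}

#' Swap one channel density and compare the elicited action potential
#'
#' Runs an identical stimulus on the base model and on a copy whose
#' `channel` density is set to `target_value` in the given regions, and
#' reports spike-metric changes.  The default stimulus is a brief
#' suprathreshold intracellular pulse at the soma.
#'
#' @param base A [build_preset_cell()] model.
#' @param channel Channel to change, e.g. `"g_Ca"`.
#' @param target_value New maximum conductance, S/cm^2.
#' @param regions Regions to change (default soma).
#' @param iclamp Intracellular stimulus (data.frame onset/dur/amp in
#'   ms/ms/nA).
#' @param duration Simulated time, ms.
#' @param settings A [solver_settings()].
#' @return List with `base`, `swapped` (sim_results), `metrics_base`,
#'   `metrics_swapped` and `delta` (swapped - base, width/peak).
#' @export
channel_swap_experiment <- function(base, channel, target_value,
                                    regions = "soma",
                                    iclamp = data.frame(onset = 20, dur = 1,
                                                        amp = 1),
                                    duration = 100,
                                    settings = solver_settings()) {
  swapped <- set_density(base, channel, target_value, regions)
  sim_b <- simulate_cell(base, train = NULL, electrode = NULL,
                         iclamp = iclamp, duration = duration,
                         settings = settings)
  sim_s <- simulate_cell(swapped, train = NULL, electrode = NULL,
                         iclamp = iclamp, duration = duration,
                         settings = settings)
  mb <- spike_metrics(sim_b$soma_voltage, sim_b$time, settings,
                      pulse_onsets = iclamp$onset)
  ms <- spike_metrics(sim_s$soma_voltage, sim_s$time, settings,
                      pulse_onsets = iclamp$onset)
  list(base = sim_b, swapped = sim_s, metrics_base = mb,
       metrics_swapped = ms,
       delta = list(width = ms$width_at_half_max - mb$width_at_half_max,
                    peak = ms$peak - mb$peak))
}

#' @noRd
paired_pulse_stim <- function(t, t0, interval, amplitude, pulse_width, ipg) {
  one <- function(tt, on) {
    out <- numeric(length(tt))
    ph1 <- tt >= on & tt < on + pulse_width
    ph2 <- tt >= on + pulse_width + ipg & tt < on + 2 * pulse_width + ipg
    out[ph1] <- -amplitude
    out[ph2] <- amplitude
    out
  }
  one(t, t0) + one(t, t0 + interval)
}

#' @noRd
second_pulse_spikes <- function(cell, interval, amplitude, pulse_width, ipg,
                                t0, electrode, settings) {
  dur <- t0 + interval + 2 * pulse_width + ipg + 15
  sim <- simulate_extracellular_fun(cell, function(t) {
    paired_pulse_stim(t, t0, interval, amplitude, pulse_width, ipg)
  }, dur, electrode, settings)
  any(sim$spike_times >= t0 + interval - 1e-9)
}

#' Paired-pulse refractory period
#'
#' Delivers two identical suprathreshold biphasic pulses and finds the
#' minimal inter-pulse interval at which the second pulse still elicits a
#' spike, by bisection on a 0.5 ms grid (or an exhaustive ascending scan).
#' The probe amplitude defaults to 1.5x the single-pulse threshold.
#'
#' @param cell A [build_preset_cell()] model.
#' @param amplitude Probe amplitude, uA; `NULL` uses 1.5x the single-pulse
#'   threshold.
#' @param pulse_width,ipg Pulse shape, ms.
#' @param search_range Interval search range, ms.
#' @param resolution Interval grid, ms.
#' @param electrode,settings See [simulate_cell()].
#' @param method `"bisection"` or `"scan"`.
#' @return Refractory period, ms (on the resolution grid).
#' @export
measure_refractory <- function(cell, amplitude = NULL, pulse_width = 0.5,
                               ipg = 0, search_range = c(1, 50),
                               resolution = 0.5,
                               electrode = electrode_model(),
                               settings = solver_settings(),
                               method = c("bisection", "scan")) {
  method <- match.arg(method)
  t0 <- 20
  if (is.null(amplitude)) {
    amplitude <- 1.5 * single_pulse_threshold(cell, pulse_width, ipg,
                                              electrode, settings)
  }
  # probe must be suprathreshold in isolation
  solo <- simulate_extracellular_fun(cell, function(t) {
    paired_pulse_stim(t, t0, 1e6, amplitude, pulse_width, ipg)
  }, t0 + 20, electrode, settings)
  if (!length(solo$spike_times)) {
    stop("probe pulse is subthreshold in isolation")
  }
  ok <- function(iv) second_pulse_spikes(cell, iv, amplitude, pulse_width,
                                         ipg, t0, electrode, settings)
  grid <- seq(search_range[1], search_range[2], by = resolution)
  if (method == "scan") {
    for (iv in grid) if (ok(iv)) return(iv)
    stop("second spike never elicited within the search range")
  }
  lo <- 1
  hi <- length(grid)
  if (!ok(grid[hi])) {
    stop("second spike never elicited within the search range")
  }
  if (ok(grid[lo])) return(grid[lo])
  while (hi - lo > 1) {
    mid <- (hi + lo) %/% 2
    if (ok(grid[mid])) hi <- mid else lo <- mid
  }
  grid[hi]
}

#' @noRd
single_pulse_threshold <- function(cell, pulse_width, ipg, electrode,
                                   settings, cap = 5000) {
  t0 <- 20
  spikes_at <- function(a) {
    sim <- simulate_extracellular_fun(cell, function(t) {
      paired_pulse_stim(t, t0, 1e6, a, pulse_width, ipg)
    }, t0 + 20, electrode, settings)
    length(sim$spike_times) > 0
  }
  amp <- 10
  while (!spikes_at(amp)) {
    amp <- amp * 2
    if (amp > cap) stop("non-excitable: no single-pulse response below cap")
  }
  lo <- if (amp == 10) 0 else amp / 2
  hi <- amp
  while (hi - lo > 1) {
    mid <- (hi + lo) / 2
    if (spikes_at(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Depolarizing sag under a hyperpolarizing current step
#'
#' Injects a sustained hyperpolarizing step at the soma and measures the
#' sag: the membrane-potential recovery from the early hyperpolarization
#' peak to the quasi-steady value at the end of the step,
#' `V(end of step) - V(peak hyperpolarization)`.  Positive when the
#' h-current is present; ~0 for a passive or h-free cell.
#'
#' @param cell A [build_preset_cell()] model.
#' @param amp Step amplitude, nA (must be negative), or `NULL` to scale the
#'   step to the cell's input resistance so that the early hyperpolarization
#'   is about `target_mV` -- this keeps the h-current operating range
#'   comparable across cells of different size and resting conductance.
#' @param target_mV Target early hyperpolarization used when `amp` is
#'   `NULL`, mV.
#' @param step_duration Step length, ms (>= 500 to reach quasi-steady
#'   state).
#' @param onset Step onset, ms.
#' @param settings A [solver_settings()].
#' @return Sag amplitude, mV.
#' @export
measure_sag <- function(cell, amp = NULL, target_mV = 25,
                        step_duration = 800, onset = 50,
                        settings = solver_settings()) {
  if (is.null(amp)) {
    # probe input resistance with a small brief step
    probe <- -0.002
    sim <- simulate_cell(cell, train = NULL, electrode = NULL,
                         iclamp = data.frame(onset = 20, dur = 150,
                                             amp = probe),
                         duration = 180, settings = settings)
    v0 <- sim$soma_voltage[which.min(abs(sim$time - 19))]
    v1 <- sim$soma_voltage[which.min(abs(sim$time - 169))]
    dv_per_na <- (v1 - v0) / probe
    if (!is.finite(dv_per_na) || dv_per_na < 100) {
      stop("cannot scale the step: the cell does not respond passively to ",
           "a small hyperpolarizing probe (spontaneously active?); ",
           "pass `amp` explicitly")
    }
    amp <- -target_mV / dv_per_na
  }
  stopifnot(amp < 0, step_duration >= 500)
  sim <- simulate_cell(cell, train = NULL, electrode = NULL,
                       iclamp = data.frame(onset = onset,
                                           dur = step_duration, amp = amp),
                       duration = onset + step_duration + 100,
                       settings = settings)
  in_step <- sim$time >= onset & sim$time <= onset + step_duration
  v <- sim$soma_voltage[in_step]
  v_end <- v[length(v)]
  v_min <- min(v)
  v_end - v_min
}
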