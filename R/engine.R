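#' Solver settings
#'
#' @param dt Time step, ms.  The solver refines `dt` so that it divides the
#'   pulse width and interphase gap exactly when possible, which keeps the
#'   sampled waveform charge-balanced period by period.
#' @param method `"backward_euler"` (robust default) or `"crank_nicolson"`
#'   (second-order in time).
#' @param spike_threshold Upward-crossing detection threshold, mV.  Set at
#'   -20 mV so that small sub-threshold membrane oscillations that can
#'   follow full action potentials in a pulse train are not counted.
#' @param spike_deadtime Refractory time of the detector, ms.
#' @param settle_ms Unstimulated settling time run before the stimulus so
#'   every simulation starts from the cell's resting state, ms.
#' @return An object of class `solver_settings`.
#' @export
solver_settings <- function(dt = 0.01,
                            method = c("backward_euler", "crank_nicolson"),
                            spike_threshold = -20, spike_deadtime = 1.5,
                            settle_ms = 500) {
  method <- match.arg(method)
  stopifnot(dt > 0, spike_deadtime >= 0, settle_ms >= 0)
  structure(list(dt = dt, method = method, spike_threshold = spike_threshold,
                 spike_deadtime = spike_deadtime, settle_ms = settle_ms),
            class = "solver_settings")
}

#' @noRd
snap_dt <- function(dt, train) {
  if (is.null(train)) return(dt)
  # largest step <= dt that divides both phase durations (us resolution)
  pw_us <- round(train$pulse_width * 1e3)
  ipg_us <- round(train$ipg * 1e3)
  g_us <- if (ipg_us == 0) pw_us else {
    a <- pw_us; b <- ipg_us
    while (b > 0) { t <- b; b <- a %% b; a <- t }
    a
  }
  g <- g_us / 1e3
  g / ceiling(g / dt - 1e-9)
}

#' @noRd
initial_state <- function(n_comp, v0, ca_rest) {
  x <- vapply(gate_names(), gate_steady_state, numeric(1), V = v0)
  st <- matrix(0, nrow = n_comp, ncol = 11)
  st[, 1] <- v0
  st[, 2:10] <- matrix(rep(x, each = n_comp), nrow = n_comp)
  st[, 11] <- ca_rest
  st
}

#' @noRd
ca_param_list <- function(mem) {
  list(cao = mem$ca_o, carest = mem$ca_rest, tau = mem$tau_ca,
       depth_cm = mem$pool_depth * 1e-4, khalf = mem$k_half,
       nernst = nernst_slope_ca(mem$temperature))
}

#' @noRd
run_core <- function(comp, cell, phi, istim, iinj, dt, theta, state0,
                     record_all = FALSE) {
  dens <- attr(comp, "densities")
  kin <- kinetics_matrix()
  mem <- cell$membrane
  .cpp_run_cable(as.integer(comp$parent) - 1L, comp$area, comp$gax,
                 dens, rep(cell$passive$g_leak * 1e3, nrow(comp)),
                 cell$passive$cm, cell$passive$e_leak, mem$e_na, mem$e_k,
                 mem$e_h, phi, istim, iinj, 0L, dt, theta, state0,
                 ca_param_list(mem), record_all, kin)
}

#' @noRd
settled_state <- function(comp, cell, dt, settle_ms) {
  n <- nrow(comp)
  state0 <- initial_state(n, cell$passive$e_leak, cell$membrane$ca_rest)
  if (settle_ms <= 0) return(state0)
  key <- rlang::hash(list(comp$area, comp$gax, comp$parent,
                          attr(comp, "densities"), cell$passive,
                          cell$membrane, dt, settle_ms))
  cache <- .rgcstim_env$settle_cache
  if (is.null(cache)) {
    cache <- new.env(parent = emptyenv())
    .rgcstim_env$settle_cache <- cache
  }
  if (!is.null(cache[[key]])) return(cache[[key]])
  nset <- round(settle_ms / dt)
  settled <- run_core(comp, cell, numeric(n), numeric(nset), numeric(nset),
                      dt, 1, state0)
  if (settled$diverged) {
    stop("numerical divergence during settling at t = ",
         signif(settled$t_diverged, 6), " ms")
  }
  cache[[key]] <- settled$state
  settled$state
}

#' Simulate a cell under extracellular and/or intracellular stimulation
#'
#' Integrates the compartmental cable equation
#' `C_m dV/dt = -I_ion + axial coupling`, with the extracellular potential
#' entering through the standard extracellular mechanism (axial currents are
#' driven by the intracellular potential `V_m + V_e`).  The cell is first
#' settled to rest with no stimulus, then the stimulus epoch is integrated;
#' results are deterministic for fixed inputs and time step.
#'
#' @param cell A [build_preset_cell()] model.
#' @param train A [pulse_train()] or `NULL` for no extracellular stimulus.
#' @param electrode An [electrode_model()]; `NULL` disables the
#'   extracellular field.
#' @param iclamp Optional intracellular current clamp at the soma: a
#'   data.frame with columns `onset`, `dur` (ms) and `amp` (nA).
#' @param duration Simulated time, ms; defaults to the train duration (or
#'   500 ms for purely intracellular runs).
#' @param settings A [solver_settings()].
#' @param record_all If `TRUE`, keep voltage traces for every compartment.
#' @return A `sim_result`: list with `time` (ms), `soma_voltage` (mV),
#'   `spike_times` (ms), `stimulus` (uA), `metadata`, and optionally
#'   `voltage` (matrix, time x compartments).
#' @export
simulate_cell <- function(cell, train = NULL, electrode = electrode_model(),
                          iclamp = NULL, duration = NULL,
                          settings = solver_settings(),
                          record_all = FALSE) {
  comp <- discretize_cell(cell, electrode)
  n <- nrow(comp)
  if (is.null(duration)) {
    duration <- if (!is.null(train)) train$duration else 500
  }
  dt <- snap_dt(settings$dt, train)
  theta <- if (settings$method == "backward_euler") 1 else 0.5
  nt <- round(duration / dt)
  tmid <- (seq_len(nt) - 0.5) * dt

  phi <- if (!is.null(train) && !is.null(electrode)) {
    map_extracellular(comp, electrode)
  } else {
    numeric(n)
  }
  istim <- if (!is.null(train)) waveform_current(tmid, train) else numeric(nt)
  iinj <- numeric(nt)
  if (!is.null(iclamp)) {
    for (k in seq_len(nrow(iclamp))) {
      on <- tmid >= iclamp$onset[k] & tmid < iclamp$onset[k] + iclamp$dur[k]
      iinj[on] <- iinj[on] + iclamp$amp[k]
    }
  }

  state0 <- settled_state(comp, cell, dt, settings$settle_ms)

  res <- run_core(comp, cell, phi, istim, iinj, dt, theta, state0,
                  record_all)
  if (res$diverged) {
    stop("numerical divergence at t = ", signif(res$t_diverged, 6), " ms")
  }
  time <- seq(0, by = dt, length.out = nt + 1)
  spikes <- detect_spikes(res$v_soma, time, settings)
  out <- list(time = time, soma_voltage = as.numeric(res$v_soma),
              spike_times = spikes, stimulus = istim,
              final_state = res$state,
              metadata = list(dt = dt, method = settings$method,
                              n_comp = n, duration = duration,
                              cell = cell$label,
                              amplitude = if (!is.null(train)) train$amplitude else NA,
                              settle_ms = settings$settle_ms))
  if (record_all) out$voltage <- res$v_all
  class(out) <- "sim_result"
  out
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("sim_result: %s, %g ms at dt %g ms, %d compartments, %d spikes\n",
              x$metadata$cell, x$metadata$duration, x$metadata$dt,
              x$metadata$n_comp, length(x$spike_times)))
  invisible(x)
}

#' Simulate a cell driven by an arbitrary electrode-current time course
#'
#' As [simulate_cell()], but the extracellular stimulus is given as a
#' function of time (uA) instead of a [pulse_train()] -- used by the
#' paired-pulse refractory protocol.
#'
#' @param cell A [build_preset_cell()] model.
#' @param stim_fun Function mapping time (ms, vectorized) to electrode
#'   current (uA).
#' @param duration Simulated time, ms.
#' @param electrode An [electrode_model()].
#' @param settings A [solver_settings()].
#' @return A `sim_result` (see [simulate_cell()]).
#' @export
simulate_extracellular_fun <- function(cell, stim_fun, duration,
                                       electrode = electrode_model(),
                                       settings = solver_settings()) {
  comp <- discretize_cell(cell, electrode)
  n <- nrow(comp)
  dt <- settings$dt
  theta <- if (settings$method == "backward_euler") 1 else 0.5
  nt <- round(duration / dt)
  tmid <- (seq_len(nt) - 0.5) * dt
  phi <- map_extracellular(comp, electrode)
  istim <- stim_fun(tmid)
  state0 <- settled_state(comp, cell, dt, settings$settle_ms)
  res <- run_core(comp, cell, phi, istim, numeric(nt), dt, theta, state0)
  if (res$diverged) {
    stop("numerical divergence at t = ", signif(res$t_diverged, 6), " ms")
  }
  time <- seq(0, by = dt, length.out = nt + 1)
  out <- list(time = time, soma_voltage = as.numeric(res$v_soma),
              spike_times = detect_spikes(res$v_soma, time, settings),
              stimulus = istim, final_state = res$state,
              metadata = list(dt = dt, method = settings$method, n_comp = n,
                              duration = duration, cell = cell$label,
                              amplitude = NA,
                              settle_ms = settings$settle_ms))
  class(out) <- "sim_result"
  out
}

#' Detect spikes as thresholded upward crossings
#'
#' A spike is an upward crossing of `spike_threshold`; crossings within
#' `spike_deadtime` of an accepted spike are ignored.  Spike times are
#' linearly interpolated between samples.
#'
#' @param trace Voltage trace, mV.
#' @param time Time grid, ms (same length).
#' @param settings A [solver_settings()] (threshold and deadtime are used).
#' @return Strictly increasing numeric vector of spike times, ms.
#' @export
detect_spikes <- function(trace, time, settings = solver_settings()) {
  stopifnot(length(trace) == length(time), all(is.finite(trace)))
  thr <- settings$spike_threshold
  up <- which(trace[-1] >= thr & trace[-length(trace)] < thr)
  if (!length(up)) return(numeric(0))
  frac <- (thr - trace[up]) / (trace[up + 1] - trace[up])
  tcross <- time[up] + frac * (time[up + 1] - time[up])
  keep <- numeric(0)
  last <- -Inf
  for (tc in tcross) {
    if (tc - last >= settings$spike_deadtime) {
      keep <- c(keep, tc)
      last <- tc
    }
  }
  keep
}

#' Spike shape metrics of the first spike in a trace
#'
#' Width is measured at half of (peak - resting) on the first spike; latency
#' is the first threshold crossing minus the most recent cathodic-phase
#' onset at or before it.
#'
#' @param trace,time Voltage trace (mV) and time grid (ms).
#' @param settings A [solver_settings()].
#' @param resting Resting potential, mV; defaults to the first sample.
#' @param pulse_onsets Optional cathodic-phase onset times, ms, for the
#'   latency measurement.
#' @return List with `width_at_half_max` (ms), `peak` (mV) and
#'   `latency_from_pulse_onset` (ms, `NA` if no onsets given).
#' @export
spike_metrics <- function(trace, time, settings = solver_settings(),
                          resting = trace[1], pulse_onsets = NULL) {
  spikes <- detect_spikes(trace, time, settings)
  if (!length(spikes)) stop("no spike present in trace")
  t0 <- spikes[1]
  i0 <- max(which(time <= t0))
  iend <- min(length(trace), i0 + ceiling(5 / (time[2] - time[1])))
  win <- i0:iend
  ipk <- win[which.max(trace[win])]
  peak <- trace[ipk]
  half <- resting + (peak - resting) / 2
  # crossing of the half level before and after the peak
  iup <- ipk
  while (iup > 1 && trace[iup - 1] > half) iup <- iup - 1
  idn <- ipk
  while (idn < length(trace) && trace[idn + 1] > half) idn <- idn + 1
  t_up <- if (iup == 1) time[1] else {
    approx(trace[(iup - 1):iup], time[(iup - 1):iup], xout = half)$y
  }
  t_dn <- if (idn == length(trace)) time[idn] else {
    approx(trace[idn:(idn + 1)], time[idn:(idn + 1)], xout = half)$y
  }
  latency <- NA_real_
  if (!is.null(pulse_onsets)) {
    prev <- pulse_onsets[pulse_onsets <= t0 + 1e-9]
    if (length(prev)) latency <- t0 - max(prev)
  }
  list(width_at_half_max = t_dn - t_up, peak = peak,
       latency_from_pulse_onset = latency)
}
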