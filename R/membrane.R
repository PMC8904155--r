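#' Membrane and calcium-pool parameters
#'
#' Reversal potentials, extracellular calcium, and the single-shell calcium
#' pool used for the Ca-activated K conductance.  Calcium reverses at the
#' Nernst potential computed from the instantaneous intracellular
#' concentration, so `E_Ca` is not a fixed parameter.
#'
#' @param e_na,e_k,e_h,e_leak Reversal potentials, mV.
#' @param ca_o Extracellular calcium, mM.
#' @param ca_rest Resting intracellular calcium, mM.
#' @param pool_depth Depth of the well-mixed submembrane shell, um.
#' @param tau_ca Calcium removal time constant, ms.  Together with
#'   `pool_depth` and `k_half` this is calibrated so that the K_Ca
#'   conductance operates on the rising part of its activation curve at the
#'   calcium loads the Ca-rich preset accumulates during sustained firing:
#'   the coupling then discriminates firing histories at 120 Hz versus
#'   200 Hz inter-pulse intervals (see the package vignette).
#' @param k_half Half-activation calcium concentration of the K_Ca
#'   conductance, mM.
#' @param temperature Temperature, degrees C (enters the Nernst slope only;
#'   gating kinetics are used at their reference temperature, Q10 = 1).
#' @return An object of class `membrane_params`.
#' @export
membrane_params <- function(e_na = 35, e_k = -75, e_h = -32.5, e_leak = -65,
                            ca_o = 1.8, ca_rest = 1e-4, pool_depth = 0.05,
                            tau_ca = 5, k_half = 0.1, temperature = 22) {
  stopifnot(ca_o > 0, ca_rest > 0, pool_depth > 0, tau_ca > 0, k_half > 0)
  p <- list(e_na = e_na, e_k = e_k, e_h = e_h, e_leak = e_leak,
            ca_o = ca_o, ca_rest = ca_rest, pool_depth = pool_depth,
            tau_ca = tau_ca, k_half = k_half, temperature = temperature)
  class(p) <- "membrane_params"
  p
}

#' Nernst slope RT/(2F) for a divalent ion, in mV
#' @noRd
nernst_slope_ca <- function(temperature) {
  8.31446 * (273.15 + temperature) / (2 * 96485) * 1000
}

#' Calcium reversal potential from the Nernst equation
#'
#' @param ca_i Intracellular calcium, mM.
#' @param params A [membrane_params()] object.
#' @return E_Ca in mV.
#' @export
nernst_eca <- function(ca_i, params = membrane_params()) {
  stopifnot(all(ca_i > 0))
  nernst_slope_ca(params$temperature) * log(params$ca_o / ca_i)
}

#' Valid gating state for one compartment
#'
#' @param V Voltage at which gates are set to steady state, mV.
#' @param ca_i Intracellular calcium, mM.
#' @return Named list of the nine gating variables plus `ca_i`.
#' @export
gating_state <- function(V = -65, ca_i = 1e-4) {
  x <- vapply(gate_names(), gate_steady_state, numeric(1), V = V)
  c(as.list(x), list(ca_i = ca_i))
}

#' Total ionic membrane current density and per-channel breakdown
#'
#' Each channel current is `g_max * gating_product * (V - E_channel)` in
#' uA/cm^2; outward currents are positive.  The calcium-activated potassium
#' conductance is scaled by `(Ca/K_half)^2 / (1 + (Ca/K_half)^2)`; Ca-carried
#' currents (`Ca`, `T`) reverse at the Nernst potential.
#'
#' @param V Membrane voltage, mV.
#' @param state Gating state as from [gating_state()] (all gates in [0, 1],
#'   `ca_i > 0`).
#' @param densities Named numeric vector of maximum conductances in S/cm^2
#'   with names `g_Na`, `g_K`, `g_KA`, `g_KCa`, `g_Ca`, `g_h`, `g_T`.
#' @param g_leak Leak conductance, S/cm^2.
#' @param params A [membrane_params()] object.
#' @return List with `total` (uA/cm^2) and `by_channel` breakdown.
#' @export
ionic_current <- function(V, state, densities, g_leak = 5e-5,
                          params = membrane_params()) {
  x <- state
  stopifnot(all(vapply(x[gate_names()], function(v) v >= 0 && v <= 1,
                       logical(1))), x$ca_i > 0)
  d <- as.list(densities)
  to_ms <- 1e3 # S/cm^2 * mV -> mA/cm^2; use mS/cm^2 so g*V is uA/cm^2
  eca <- nernst_eca(x$ca_i, params)
  r <- (x$ca_i / params$k_half)^2
  fca <- r / (1 + r)
  by <- c(
    Na = to_ms * d$g_Na * x$m^3 * x$h * (V - params$e_na),
    K = to_ms * d$g_K * x$n^4 * (V - params$e_k),
    KA = to_ms * d$g_KA * x$a^3 * x$ha * (V - params$e_k),
    KCa = to_ms * d$g_KCa * fca * (V - params$e_k),
    Ca = to_ms * d$g_Ca * x$c^3 * (V - eca),
    h = to_ms * d$g_h * x$q * (V - params$e_h),
    T = to_ms * d$g_T * x$tm^2 * x$th * (V - eca),
    leak = to_ms * g_leak * (V - params$e_leak)
  )
  list(total = sum(by), by_channel = by)
}

#' Advance the intracellular calcium pool by one time step
#'
#' `dCa/dt = -I_Ca / (2 F depth) - (Ca - Ca_rest) / tau`, with the influx
#' term converted so that an inward (negative) calcium current raises the
#' concentration.  With `I_Ca = 0` the pool relaxes exponentially to
#' `ca_rest` with time constant `tau_ca`.
#'
#' @param i_ca Calcium-carried membrane current density, uA/cm^2 (inward
#'   negative).
#' @param ca_i Current concentration, mM.
#' @param dt Time step, ms (> 0).
#' @param params A [membrane_params()] object.
#' @return Updated concentration, mM (always > 0).
#' @export
step_calcium <- function(i_ca, ca_i, dt, params = membrane_params()) {
  stopifnot(dt > 0, ca_i > 0)
  depth_cm <- params$pool_depth * 1e-4
  cascale <- 1e-3 / (2 * 96485 * depth_cm) # uA/cm^2 -> mM/ms
  dca <- -i_ca * cascale - (ca_i - params$ca_rest) / params$tau_ca
  max(ca_i + dt * dca, 1e-9)
}
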