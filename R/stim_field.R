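#' Symmetric charge-balanced biphasic pulse train
#'
#' Cathodic-first by convention (the negative, depolarizing phase for an
#' epiretinal electrode above the cell comes first), followed by an optional
#' zero-current interphase gap and the charge-balancing anodic phase.
#'
#' @param amplitude Phase current magnitude, uA (>= 0).
#' @param pulse_width Duration of one phase, ms.
#' @param ipg Interphase gap, ms.
#' @param frequency Pulse repetition rate, Hz.
#' @param duration Train duration, ms (at least one period).
#' @param polarity `"cathodic_first"` (default) or `"anodic_first"` (used
#'   only for the documented polarity sanity check).
#' @return An object of class `pulse_train`.
#' @export
pulse_train <- function(amplitude, pulse_width = 0.5, ipg = 0,
                        frequency = 120, duration = 1000,
                        polarity = c("cathodic_first", "anodic_first")) {
  polarity <- match.arg(polarity)
  stopifnot(amplitude >= 0, pulse_width > 0, ipg >= 0, frequency > 0)
  period <- 1000 / frequency
  if (2 * pulse_width + ipg > period + 1e-12) {
    stop("2*pulse_width + ipg must fit within one period (",
         signif(period, 4), " ms)")
  }
  if (duration < period - 1e-9) stop("duration must cover at least one period")
  structure(list(amplitude = amplitude, pulse_width = pulse_width,
                 ipg = ipg, frequency = frequency, duration = duration,
                 polarity = polarity, symmetric = TRUE, period = period),
            class = "pulse_train")
}

#' @export
print.pulse_train <- function(x, ...) {
  cat(sprintf("biphasic pulse train: %.4g uA, PW %.3g ms, IPG %.3g ms, %g Hz, %g ms (%s)\n",
              x$amplitude, x$pulse_width, x$ipg, x$frequency, x$duration,
              x$polarity))
  invisible(x)
}

#' Instantaneous electrode current of a pulse train
#'
#' Within each period: `-amplitude` during the first (cathodic) phase, zero
#' during the interphase gap, `+amplitude` during the second phase, zero for
#' the rest of the period (signs flipped for anodic-first trains).
#'
#' @param t Time, ms (vectorized, >= 0).
#' @param train A [pulse_train()].
#' @return Current in uA.
#' @export
waveform_current <- function(t, train) {
  stopifnot(all(t >= 0))
  tp <- t %% train$period
  sgn <- if (train$polarity == "cathodic_first") 1 else -1
  ph1 <- tp < train$pulse_width
  ph2 <- tp >= train$pulse_width + train$ipg &
         tp < 2 * train$pulse_width + train$ipg
  live <- t < train$duration
  out <- numeric(length(t))
  out[ph1 & live] <- -sgn * train$amplitude
  out[ph2 & live] <- sgn * train$amplitude
  out
}

#' Charge delivered per phase
#'
#' @param train A [pulse_train()].
#' @return Charge in nC (`amplitude [uA] * pulse_width [ms]`).
#' @export
charge_per_phase <- function(train) {
  train$amplitude * train$pulse_width
}

#' Disk stimulating electrode in a semi-infinite homogeneous medium
#'
#' @param radius Disk radius, um.
#' @param center 3-D center of the disk on the tissue surface plane (z = 0),
#'   um.
#' @param sigma Medium conductivity, S/m.
#' @param distance_to_soma Nominal standoff between the disk and the cell
#'   body, um (used when placing cells).
#' @return An object of class `electrode_model`.
#' @export
electrode_model <- function(radius = 100, center = c(0, 0, 0), sigma = 0.1,
                            distance_to_soma = 50) {
  stopifnot(radius > 0, sigma > 0)
  structure(list(radius = radius, center = as.numeric(center), sigma = sigma,
                 distance_to_soma = distance_to_soma),
            class = "electrode_model")
}

#' Extracellular potential of an equipotential disk electrode
#'
#' Analytic solution for a perfectly conducting disk carrying current `I`
#' into a semi-infinite homogeneous medium:
#' `V(r, z) = I/(4 sigma a) * (2/pi) * asin(2a / (sqrt((r-a)^2+z^2) + sqrt((r+a)^2+z^2)))`.
#' At the disk surface (r = 0, z = 0) this reduces to `I/(4 sigma a)`; far
#' away it approaches the point source `I/(4 pi sigma R)`.
#'
#' @param radial Radial distance from the disk axis, um (vectorized).
#' @param depth Depth below the disk plane, um (vectorized).
#' @param I Electrode current, uA.
#' @param electrode An [electrode_model()].
#' @return Potential in mV.
#' @export
disk_potential <- function(radial, depth, I, electrode = electrode_model()) {
  if (electrode$sigma <= 0) stop("conductivity must be positive")
  a <- electrode$radius * 1e-6          # m
  r <- radial * 1e-6
  z <- abs(depth) * 1e-6
  s <- sqrt((r - a)^2 + z^2) + sqrt((r + a)^2 + z^2)
  arg <- pmin(2 * a / s, 1)
  v_volts <- (I * 1e-6) / (4 * electrode$sigma * a) * (2 / pi) * asin(arg)
  v_volts * 1e3
}

#' Per-compartment extracellular coupling coefficients
#'
#' Unit-current potentials (mV per uA of electrode current) at each
#' compartment center under the quasi-static assumption: the extracellular
#' potential time course at a compartment is this coefficient times
#' [waveform_current()].
#'
#' @param comp Compartment table as produced by [discretize_cell()]
#'   (columns x, y, z in um, in the electrode frame: disk on the z = 0
#'   plane).
#' @param electrode An [electrode_model()].
#' @return Numeric vector, mV/uA per compartment.
#' @export
map_extracellular <- function(comp, electrode = electrode_model()) {
  dx <- comp$x - electrode$center[1]
  dy <- comp$y - electrode$center[2]
  dz <- comp$z - electrode$center[3]
  r <- sqrt(dx^2 + dy^2)
  if (any(abs(dz) < 1e-9 & r <= electrode$radius)) {
    stop("compartment lies inside the electrode disk")
  }
  disk_potential(r, dz, 1, electrode)
}
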