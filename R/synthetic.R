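#' Specification for a stylized RGC morphology
#'
#' Geometric stand-in for the reconstructed cells: a soma cylinder with
#' radial primary dendrites reaching the dendritic-field radius in one
#' (monostratified) or two (bistratified) stratification planes.  The
#' shipped geometry emulates the two study cells: A2 soma 20 um / field
#' 320 um (mono), D1 soma 12 um / field 144 um (bi).
#'
#' @param soma_diameter Soma diameter, um.
#' @param field_diameter Dendritic field diameter, um (> soma diameter).
#' @param stratification `"mono"` or `"bi"`.
#' @param branches Number of primary dendrites (>= 1).
#' @param layer_depths Depth(s) of the stratification plane(s) below the
#'   soma, um; the first is used for mono, the first two for bi.
#' @param seed Integer seed controlling the (deterministic) azimuthal
#'   layout.
#' @return An object of class `stylized_cell_spec`.
#' @export
stylized_cell_spec <- function(soma_diameter, field_diameter,
                               stratification = c("mono", "bi"),
                               branches = 6, layer_depths = c(10, 30),
                               seed = 1) {
  stratification <- match.arg(stratification)
  stopifnot(field_diameter > soma_diameter, branches >= 1,
            soma_diameter > 0)
  structure(list(soma_diameter = soma_diameter,
                 field_diameter = field_diameter,
                 stratification = stratification, branches = branches,
                 layer_depths = layer_depths, seed = as.integer(seed)),
            class = "stylized_cell_spec")
}

#' A2-like and D1-like stylized morphology specs
#' @param which `"A2"` or `"D1"`.
#' @param ... Passed to [stylized_cell_spec()] to override defaults.
#' @return A [stylized_cell_spec()].
#' @export
preset_cell_spec <- function(which = c("A2", "D1"), ...) {
  which <- match.arg(which)
  if (which == "A2") {
    stylized_cell_spec(20, 320, "mono", ...)
  } else {
    stylized_cell_spec(12, 144, "bi", ...)
  }
}

#' Generate a stylized morphology from a spec
#'
#' Deterministic for a fixed spec (the seed only rotates the dendrite
#' azimuths).  Dendrites are straight radial cables in the stratification
#' plane(s), tapering in three steps from 1.5 to 0.5 um diameter; the soma
#' is a cylinder of equal length and diameter laid along +x.
#'
#' @param spec A [stylized_cell_spec()].
#' @return An [morphology()] object (without axon; see [attach_axon()]).
#' @export
generate_stylized_morphology <- function(spec) {
  stopifnot(inherits(spec, "stylized_cell_spec"))
  sd <- spec$soma_diameter
  R <- spec$field_diameter / 2
  planes <- if (spec$stratification == "mono") {
    rep(spec$layer_depths[1], spec$branches)
  } else {
    spec$layer_depths[1 + (seq_len(spec$branches) - 1) %% 2]
  }
  offset <- 2 * pi * ((spec$seed * 2654435761) %% 360) / 360
  angles <- offset + 2 * pi * (seq_len(spec$branches) - 1) / spec$branches

  secs <- list(data.frame(id = 1L, parent_id = NA_integer_, kind = "soma",
                          length = sd, diameter = sd,
                          n_segments = NA_integer_))
  paths <- list("1" = rbind(c(-sd / 2, 0, 0), c(sd / 2, 0, 0)))
  next_id <- 2L
  taper <- c(1.5, 1.0, 0.5)
  for (b in seq_len(spec$branches)) {
    ux <- cos(angles[b])
    uy <- sin(angles[b])
    z1 <- planes[b]
    # proximal segment descends to the stratification plane, the rest of
    # the dendrite runs radially within it
    r0 <- sd / 2
    r1 <- min(r0 + 10, R)
    knots <- list(c(ux * r0, uy * r0, 0),
                  c(ux * r1, uy * r1, z1),
                  c(ux * (r1 + (R - r1) / 2), uy * (r1 + (R - r1) / 2), z1),
                  c(ux * R, uy * R, z1))
    parent <- 1L
    for (k in 1:3) {
      p0 <- knots[[k]]
      p1 <- knots[[k + 1]]
      len <- sqrt(sum((p1 - p0)^2))
      secs[[length(secs) + 1]] <- data.frame(
        id = next_id, parent_id = parent, kind = "dendrite",
        length = len, diameter = taper[k], n_segments = NA_integer_)
      paths[[as.character(next_id)]] <- rbind(p0, p1)
      parent <- next_id
      next_id <- next_id + 1L
    }
  }
  morphology(do.call(rbind, secs), paths, soma_position = c(0, 0, 0),
             stratification = if (spec$stratification == "mono")
               "monostratified" else "bistratified")
}

#' Reduced A2-like / D1-like cell pair for protocol experiments
#'
#' Two small cell models that differ only in soma diameter and in the
#' preset channel densities, placed identically relative to the electrode,
#' with identical passive parameters -- the controlled comparison used by
#' the protocol suite at desk scale.  With `budget = 1` each cell is a
#' single soma compartment (used for intracellular experiments; a
#' spatially uniform extracellular potential cannot excite an isopotential
#' compartment).  With `budget >= 5` the four axon bands are attached with
#' a coarse compartment allocation (1 each for AH/SOCB/NS, the remainder
#' for the distal axon), which makes the pair extracellularly excitable.
#'
#' @param budget Total compartments per cell (>= 1).
#' @param passive Shared [passive_params()].
#' @param membrane Shared [membrane_params()].
#' @details With `budget >= 9` an equivalent-cylinder dendrite (3 um
#'   diameter, length equal to the cell's dendritic-field radius: 160 um
#'   A2-like, 72 um D1-like) carries the preset's dendrite densities --
#'   without it the reduction loses the dendritic calcium load of the large
#'   cell and the dendritic T/h currents of the small cell, which are part
#'   of the intrinsic difference between the presets.
#' @return List with elements `a2` and `d1` (cell models).
#' @export
make_reduced_pair <- function(budget = 12, passive = passive_params(),
                              membrane = membrane_params()) {
  stopifnot(budget >= 1)
  soma_only <- function(d) {
    morphology(data.frame(id = 1L, parent_id = NA_integer_, kind = "soma",
                          length = d, diameter = d, n_segments = 1L),
               paths = list("1" = rbind(c(-d / 2, 0, 0), c(d / 2, 0, 0))))
  }
  build <- function(name, d, dend_len) {
    m <- soma_only(d)
    with_dend <- budget >= 9
    if (budget >= 5) {
      nda <- budget - 4L - (if (with_dend) 3L else 0L)
      m <- attach_axon(m, n_segments = c(1L, 1L, 1L, max(1L, nda)))
    }
    if (with_dend) {
      s <- m$sections
      id <- max(s$id) + 1L
      s <- rbind(s, data.frame(id = id, parent_id = 1L, kind = "dendrite",
                               length = dend_len, diameter = 3,
                               n_segments = 2L))
      p <- m$paths
      p[[as.character(id)]] <- rbind(c(0, d / 2, 0), c(0, d / 2 + dend_len, 10))
      m <- morphology(s, p, m$soma_position, m$stratification)
    }
    build_preset_cell(name, m, passive = passive, membrane = membrane)
  }
  list(a2 = build("A2", 20, 160), d1 = build("D1", 12, 72))
}

#' Synthetic voltage trace with planted spikes
#'
#' Builds a deterministic trace from a spike template placed at known
#' times over a resting baseline, plus optional Gaussian noise -- ground
#' truth for testing the spike detector and spike metrics.
#'
#' @param spike_times Planted spike times, ms (must be separated by more
#'   than the template width).
#' @param duration Trace duration, ms.
#' @param dt Sample interval, ms.
#' @param baseline Resting level, mV.
#' @param peak Spike peak, mV.
#' @param width Template full width at its base, ms (triangular template).
#' @param noise_sd Gaussian noise s.d., mV.
#' @param seed Seed for the noise.
#' @return List with `time`, `trace` and `true_times` (the planted times).
#' @export
make_synthetic_trace <- function(spike_times, duration = 100, dt = 0.01,
                                 baseline = -65, peak = 40, width = 2,
                                 noise_sd = 0, seed = 1) {
  spike_times <- sort(spike_times)
  if (any(spike_times < 0 | spike_times > duration)) {
    stop("spike times must lie within the trace duration")
  }
  if (length(spike_times) > 1 && any(diff(spike_times) <= width)) {
    stop("planted spikes closer than the template width")
  }
  time <- seq(0, duration, by = dt)
  trace <- rep(baseline, length(time))
  rise <- 2 * dt # steep upstroke so the threshold crossing sits at the
  for (ts in spike_times) { # planted time within detector resolution
    up <- pmax(0, pmin(1, (time - ts) / rise))
    down <- pmax(0, pmin(1, 1 - (time - ts - rise) / (width - rise)))
    bump <- pmin(up, down)
    trace <- pmax(trace, baseline + bump * (peak - baseline))
  }
  if (noise_sd > 0) {
    set.seed(seed)
    trace <- trace + stats::rnorm(length(time), 0, noise_sd)
  }
  list(time = time, trace = trace, true_times = spike_times)
}
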