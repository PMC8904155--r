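#' @noRd
section_kinds <- function() c("soma", "dendrite", "AH", "SOCB", "NS", "DA")

#' @noRd
axon_kinds <- function() c("AH", "SOCB", "NS", "DA")

#' @noRd
region_names <- function() section_kinds()

#' @noRd
channel_names <- function() c("g_Na", "g_K", "g_KA", "g_KCa", "g_Ca", "g_h", "g_T")

#' Construct a morphology from a section table
#'
#' Sections form a tree rooted at the soma.  Each section is an unbranched
#' cable piece with a kind (`soma`, `dendrite`, or one of the axon bands
#' `AH`, `SOCB`, `NS`, `DA`), a length and diameter in um, and an optional
#' 3-D path.  Axon bands, when present, must occur in the order
#' soma -> AH -> SOCB -> NS -> DA, and the distal axon is terminal.
#'
#' @param sections data.frame with columns `id`, `parent_id` (NA for the
#'   root), `kind`, `length`, `diameter`, `n_segments` (NA lets the solver
#'   choose by the spatial-resolution rule).
#' @param paths Named list (by section id) of n x 3 matrices of points in um;
#'   sections without a path are laid out by the solver.
#' @param soma_position 3-D position of the soma center, um.
#' @param stratification `"monostratified"` or `"bistratified"`.
#' @return An object of class `rgc_morphology`.
#' @export
morphology <- function(sections, paths = list(),
                       soma_position = c(0, 0, 0),
                       stratification = c("monostratified", "bistratified")) {
  stratification <- match.arg(stratification)
  req <- c("id", "parent_id", "kind", "length", "diameter", "n_segments")
  stopifnot(is.data.frame(sections), all(req %in% names(sections)))
  s <- sections[, req]
  if (anyDuplicated(s$id)) stop("duplicate section ids")
  if (any(s$length <= 0)) stop("section length must be > 0")
  if (any(s$diameter <= 0)) stop("section diameter must be > 0")
  if (any(!is.na(s$n_segments) & s$n_segments < 1)) {
    stop("n_segments must be >= 1")
  }
  if (!all(s$kind %in% section_kinds())) stop("unknown section kind")
  root <- s$id[is.na(s$parent_id)]
  if (length(root) != 1) stop("morphology must have exactly one root section")
  if (s$kind[s$id == root] != "soma") stop("root section must be the soma")
  if (!all(s$parent_id[!is.na(s$parent_id)] %in% s$id)) {
    stop("parent_id refers to a missing section")
  }
  # acyclicity / connectedness: every section must reach the root
  idx <- setNames(seq_len(nrow(s)), s$id)
  for (i in seq_len(nrow(s))) {
    seen <- integer(0)
    j <- i
    while (!is.na(s$parent_id[j])) {
      if (j %in% seen) stop("cycle detected in section tree")
      seen <- c(seen, j)
      j <- idx[[as.character(s$parent_id[j])]]
    }
    if (s$id[j] != root) stop("section tree is not connected")
  }
  kind_of <- setNames(s$kind, s$id)
  children_of <- split(s$id, factor(s$parent_id, levels = s$id))
  for (i in seq_len(nrow(s))) {
    k <- s$kind[i]
    if (k == "DA" && length(children_of[[as.character(s$id[i])]]) > 0) {
      stop("DA (distal axon) section must be terminal")
    }
    if (k %in% axon_kinds()) {
      pk <- if (is.na(s$parent_id[i])) NA else kind_of[[as.character(s$parent_id[i])]]
      # DA may also hang directly off the soma: imported SWC axons carry no
      # band subdivision and are treated as generic distal axon
      ok <- switch(k, AH = "soma", SOCB = "AH", NS = "SOCB",
                   DA = c("NS", "soma"))
      if (is.na(pk) || !pk %in% ok) {
        stop("axon bands must occur in order soma -> AH -> SOCB -> NS -> DA")
      }
    }
  }
  structure(list(sections = s, paths = paths,
                 soma_position = as.numeric(soma_position),
                 stratification = stratification),
            class = "rgc_morphology")
}

#' @export
print.rgc_morphology <- function(x, ...) {
  tab <- table(x$sections$kind)
  cat("RGC morphology (", x$stratification, "): ",
      nrow(x$sections), " sections [",
      paste(names(tab), tab, sep = ":", collapse = ", "), "]\n", sep = "")
  invisible(x)
}

#' Default axon band geometry
#'
#' Band lengths/diameters shipped as configurable stand-ins for the usual
#' four-band RGC axon parameterization (the axon hillock and sodium channel
#' band taper into a narrow segment followed by the distal axon).
#'
#' @return data.frame with columns `kind`, `length`, `diameter` (um).
#' @export
default_axon_bands <- function() {
  data.frame(kind = axon_kinds(),
             length = c(40, 40, 90, 1000),
             diameter = c(1.0, 1.0, 0.6, 1.0))
}

#' Append the four-band axon to a morphology
#'
#' Adds AH, SOCB, NS and DA sections in order, rooted at the soma, laid out
#' as a straight line along +x from the soma surface.
#'
#' @param morph An [morphology()] object without existing axon bands.
#' @param bands data.frame as [default_axon_bands()]; lengths and diameters
#'   must be positive.
#' @param n_segments Optional integer vector (length 4) overriding the
#'   per-band compartment counts.
#' @return The augmented morphology.
#' @export
attach_axon <- function(morph, bands = default_axon_bands(),
                        n_segments = rep(NA_integer_, 4)) {
  stopifnot(inherits(morph, "rgc_morphology"))
  if (any(morph$sections$kind %in% axon_kinds())) {
    stop("morphology already has axon bands")
  }
  stopifnot(is.data.frame(bands), nrow(bands) == 4,
            identical(bands$kind, axon_kinds()))
  if (any(bands$length <= 0)) stop("axon band length must be > 0")
  if (any(bands$diameter <= 0)) stop("axon band diameter must be > 0")
  s <- morph$sections
  soma_id <- s$id[is.na(s$parent_id)]
  next_id <- max(s$id) + 1L
  soma <- s[s$id == soma_id, ]
  x0 <- morph$soma_position[1] + soma$length / 2
  yz <- morph$soma_position[2:3]
  parent <- soma_id
  paths <- morph$paths
  for (b in seq_len(4)) {
    id <- next_id + b - 1L
    s <- rbind(s, data.frame(id = id, parent_id = parent,
                             kind = bands$kind[b], length = bands$length[b],
                             diameter = bands$diameter[b],
                             n_segments = n_segments[b]))
    paths[[as.character(id)]] <- rbind(c(x0, yz), c(x0 + bands$length[b], yz))
    x0 <- x0 + bands$length[b]
    parent <- id
  }
  morphology(s, paths, morph$soma_position, morph$stratification)
}

#' Passive electrical parameters
#'
#' @param cm Specific membrane capacitance, uF/cm^2.
#' @param ra Axial resistivity, Ohm cm.
#' @param g_leak Leak conductance, S/cm^2.
#' @param e_leak Leak reversal, mV.
#' @param temperature Temperature, degrees C.
#' @return An object of class `passive_params`.
#' @export
passive_params <- function(cm = 1, ra = 110, g_leak = 5e-5, e_leak = -65,
                           temperature = 22) {
  stopifnot(cm > 0, ra > 0, g_leak > 0)
  structure(list(cm = cm, ra = ra, g_leak = g_leak, e_leak = e_leak,
                 temperature = temperature), class = "passive_params")
}

parse_density_cell <- function(val, g_k) {
  if (val == "3*g_K") return(3 * g_k)
  if (val == "0.004*g_K") return(0.004 * g_k)
  as.numeric(val)
}

#' Channel-density presets for the A2 and D1 cells
#'
#' Reads the shipped conductance tables (soma/dendrite per cell type, plus
#' the shared four-band axon table) and resolves the derived entries
#' `g_KA = 3 g_K` and `g_KCa = 0.004 g_K`.  The axon table is not split by
#' cell type and is applied identically to both presets; channels it does
#' not list are zero on the axon.
#'
#' @param name `"A2"` or `"D1"`.
#' @return Numeric matrix, regions (soma, dendrite, AH, SOCB, NS, DA) by
#'   channels, in S/cm^2.
#' @export
preset_densities <- function(name = c("A2", "D1")) {
  name <- match.arg(name)
  sd_file <- system.file("extdata", "conductances_soma_dendrite.csv",
                         package = "rgcstim")
  ax_file <- system.file("extdata", "conductances_axon.csv",
                         package = "rgcstim")
  sd <- read.csv(sd_file, comment.char = "#", stringsAsFactors = FALSE,
                 check.names = FALSE)
  ax <- read.csv(ax_file, comment.char = "#", stringsAsFactors = FALSE,
                 check.names = FALSE)
  dens <- matrix(0, nrow = length(region_names()),
                 ncol = length(channel_names()),
                 dimnames = list(region_names(), channel_names()))
  for (region in c("soma", "dendrite")) {
    col <- paste(name, region, sep = ".")
    g_k <- as.numeric(sd[sd$channel == "g_K", col])
    for (ch in sd$channel) {
      dens[region, ch] <- parse_density_cell(sd[sd$channel == ch, col], g_k)
    }
  }
  for (region in axon_kinds()) {
    g_k <- as.numeric(ax[ax$channel == "g_K", region])
    for (ch in ax$channel) {
      dens[region, ch] <- parse_density_cell(ax[ax$channel == ch, region], g_k)
    }
  }
  dens
}

#' Assemble a cell model from a preset
#'
#' Combines a morphology with the named channel-density preset, passive
#' parameters and reversal potentials.  Optional overrides may change
#' individual densities (`densities = list(region = list(g_x = value))`) or
#' the soma diameter (`soma_diameter`, um), which rescales only the soma
#' section (modeled as a cylinder of equal length and diameter).
#'
#' @param name `"A2"` or `"D1"`.
#' @param morph An [morphology()] object containing a soma.
#' @param overrides Optional named list; unknown regions, channels or keys
#'   are an error.
#' @param passive A [passive_params()] object.
#' @param membrane A [membrane_params()] object.
#' @return An object of class `cell_model`.
#' @export
build_preset_cell <- function(name = c("A2", "D1"), morph,
                              overrides = NULL,
                              passive = passive_params(),
                              membrane = membrane_params()) {
  name <- match.arg(name)
  stopifnot(inherits(morph, "rgc_morphology"))
  if (!any(morph$sections$kind == "soma")) stop("morphology must have a soma")
  dens <- preset_densities(name)
  if (!is.null(overrides)) {
    known <- c("densities", "soma_diameter")
    bad <- setdiff(names(overrides), known)
    if (length(bad)) stop("unknown override key(s): ", paste(bad, collapse = ", "))
    if (!is.null(overrides$densities)) {
      for (region in names(overrides$densities)) {
        if (!region %in% rownames(dens)) stop("unknown region: ", region)
        for (ch in names(overrides$densities[[region]])) {
          if (!ch %in% colnames(dens)) stop("unknown channel: ", ch)
          dens[region, ch] <- overrides$densities[[region]][[ch]]
        }
      }
    }
    if (!is.null(overrides$soma_diameter)) {
      d <- overrides$soma_diameter
      stopifnot(d > 0)
      i <- which(morph$sections$kind == "soma")
      morph$sections$diameter[i] <- d
      morph$sections$length[i] <- d
    }
  }
  structure(list(morphology = morph, densities = dens, passive = passive,
                 membrane = membrane, label = name),
            class = "cell_model")
}

#' @export
print.cell_model <- function(x, ...) {
  cat("RGC cell model '", x$label, "': ", nrow(x$morphology$sections),
      " sections, soma g_Na = ", x$densities["soma", "g_Na"], " S/cm^2\n",
      sep = "")
  invisible(x)
}

#' Modify one channel density of an existing cell model
#'
#' @param cell A [build_preset_cell()] model.
#' @param channel Channel name, e.g. `"g_Ca"`.
#' @param value New maximum conductance, S/cm^2.
#' @param regions Regions to modify (default soma only).
#' @return The modified cell model.
#' @export
set_density <- function(cell, channel, value, regions = "soma") {
  stopifnot(inherits(cell, "cell_model"))
  if (!channel %in% colnames(cell$densities)) stop("unknown channel: ", channel)
  if (!all(regions %in% rownames(cell$densities))) stop("unknown region")
  cell$densities[regions, channel] <- value
  cell
}
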