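#' @noRd
seg_max_len <- function(kind) {
  # resolves the extracellular gradient near a 200 um disk electrode
  if (kind %in% c("soma", "AH", "SOCB", "NS")) 10 else 25
}

interp_path <- function(path, s_target) {
  xyz <- path[, 1:3, drop = FALSE]
  if (nrow(xyz) == 1) {
    return(matrix(rep(xyz[1, ], each = length(s_target)), ncol = 3))
  }
  d <- sqrt(rowSums((xyz[-1, , drop = FALSE] -
                     xyz[-nrow(xyz), , drop = FALSE])^2))
  s <- c(0, cumsum(d))
  if (s[length(s)] == 0) {
    return(matrix(rep(xyz[1, ], each = length(s_target)), ncol = 3))
  }
  st <- pmin(pmax(s_target, 0), s[length(s)])
  out <- vapply(1:3, function(k) approx(s, xyz[, k], xout = st)$y,
                numeric(length(s_target)))
  matrix(out, ncol = 3)
}

#' Compartmentalize a cell model and place it relative to the electrode
#'
#' Splits every section into segments no longer than 10 um (soma and axon
#' hillock/sodium-channel band/narrow segment) or 25 um (dendrite, distal
#' axon) unless the section carries an explicit `n_segments`, computes
#' compartment centers from the section paths, membrane areas (cylinder
#' lateral surface), and axial coupling conductances from the axial
#' resistivity.  The cell is translated so that the soma center sits on the
#' electrode axis at the electrode's nominal standoff depth (disk on the
#' z = 0 plane, tissue at z > 0).
#'
#' @param cell A [build_preset_cell()] model.
#' @param electrode An [electrode_model()], or `NULL` to keep morphology
#'   coordinates.
#' @return A data.frame (one row per compartment, soma first) with columns
#'   `sec_id`, `kind`, `x`, `y`, `z` (um), `length`, `diameter` (um),
#'   `area` (cm^2), `parent` (1-based index, 0 for the root) and `gax`
#'   (uS, coupling to parent); attribute `densities` holds the per-compartment
#'   conductance matrix in mS/cm^2.
#' @export
discretize_cell <- function(cell, electrode = electrode_model()) {
  stopifnot(inherits(cell, "cell_model"))
  morph <- cell$morphology
  s <- morph$sections
  ra <- cell$passive$ra

  shift <- c(0, 0, 0)
  if (!is.null(electrode)) {
    target <- electrode$center + c(0, 0, electrode$distance_to_soma)
    shift <- target - morph$soma_position
  }

  # topological order (parents first)
  ord <- integer(0)
  remaining <- s$id
  placed <- integer(0)
  while (length(remaining)) {
    ready <- remaining[is.na(s$parent_id[match(remaining, s$id)]) |
                       s$parent_id[match(remaining, s$id)] %in% placed]
    if (!length(ready)) stop("section tree is not topologically orderable")
    ord <- c(ord, ready)
    placed <- c(placed, ready)
    remaining <- setdiff(remaining, ready)
  }

  half_r <- function(len_um, diam_um, n) {
    # axial resistance of half a segment, Ohm
    seg_cm <- (len_um / n) * 1e-4 / 2
    rad_cm <- (diam_um / 2) * 1e-4
    ra * seg_cm / (pi * rad_cm^2)
  }

  rows <- list()
  comp_range <- list() # sec id -> compartment indices
  n_comp <- 0L
  for (sid in ord) {
    i <- match(sid, s$id)
    n <- s$n_segments[i]
    if (is.na(n)) n <- max(1L, ceiling(s$length[i] / seg_max_len(s$kind[i])))
    path <- morph$paths[[as.character(sid)]]
    if (is.null(path)) stop("section ", sid, " has no path; cannot discretize")
    centers <- interp_path(path, (seq_len(n) - 0.5) / n * s$length[i])
    seg_l <- s$length[i] / n
    d <- s$diameter[i]
    area <- pi * (d * 1e-4) * (seg_l * 1e-4)
    hr <- half_r(s$length[i], d, n)
    idx <- n_comp + seq_len(n)
    parent <- integer(n)
    gax <- numeric(n)
    if (n > 1) {
      parent[-1] <- idx[-n]
      gax[-1] <- 1 / (2 * hr) * 1e6 # uS between neighbor centers
    }
    if (is.na(s$parent_id[i])) {
      parent[1] <- 0L
    } else {
      prange <- comp_range[[as.character(s$parent_id[i])]]
      pcomp <- do.call(rbind, rows)[prange, , drop = FALSE]
      att <- path[1, 1:3] + shift
      dist <- sqrt((pcomp$x - att[1])^2 + (pcomp$y - att[2])^2 +
                   (pcomp$z - att[3])^2)
      k <- which.min(dist)
      parent[1] <- prange[k]
      hr_p <- ra * (pcomp$length[k] * 1e-4 / 2) /
        (pi * ((pcomp$diameter[k] / 2) * 1e-4)^2)
      gax[1] <- 1 / (hr + hr_p) * 1e6
    }
    rows[[length(rows) + 1]] <- data.frame(
      sec_id = sid, kind = s$kind[i],
      x = centers[, 1] + shift[1], y = centers[, 2] + shift[2],
      z = centers[, 3] + shift[3],
      length = seg_l, diameter = d, area = area,
      parent = parent, gax = gax)
    comp_range[[as.character(sid)]] <- idx
    n_comp <- n_comp + n
  }
  comp <- do.call(rbind, rows)
  rownames(comp) <- NULL
  dens <- cell$densities[comp$kind, , drop = FALSE] * 1e3 # S/cm^2 -> mS/cm^2
  rownames(dens) <- NULL
  attr(comp, "densities") <- dens
  attr(comp, "cell_label") <- cell$label
  comp
}
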