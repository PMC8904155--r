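#' Read a neuron morphology from SWC text
#'
#' Standard 7-column SWC (`id type x y z radius parent`), 1-based ids,
#' radii in um.  Type codes: 1 = soma, 2 = axon (mapped to the distal-axon
#' region kind `DA`), 3/4 = dendrite; unknown codes are mapped to dendrite
#' with a warning.  One section is created per contiguous same-type
#' unbranched chain of points; the soma section collects all type-1 points.
#'
#' @param src File path, or a character vector of SWC lines.
#' @return An [morphology()] object.  Attribute `swc_n_points` records the
#'   number of sample points read; per-point coordinates and radii are kept
#'   in the section paths (columns x, y, z, r).
#' @export
load_swc <- function(src) {
  lines <- if (length(src) == 1 && !grepl("\n", src) && file.exists(src)) {
    readLines(src)
  } else {
    unlist(strsplit(src, "\n"))
  }
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty SWC input")
  flds <- strsplit(lines, "[[:space:]]+")
  if (any(lengths(flds) != 7)) stop("SWC lines must have 7 columns")
  m <- matrix(as.numeric(unlist(flds)), ncol = 7, byrow = TRUE)
  pts <- data.frame(id = as.integer(m[, 1]), type = as.integer(m[, 2]),
                    x = m[, 3], y = m[, 4], z = m[, 5], r = m[, 6],
                    parent = as.integer(m[, 7]))
  if (any(pts$r <= 0)) stop("non-positive radius in SWC input")
  if (sum(pts$parent == -1) > 1) stop("multiple roots in SWC input")
  if (sum(pts$parent == -1) == 0) stop("no root point in SWC input")
  known <- pts$parent == -1 | pts$parent %in% pts$id
  if (!all(known)) stop("orphan parent reference in SWC input")
  if (anyDuplicated(pts$id)) stop("duplicate point ids in SWC input")
  if (!any(pts$type == 1)) stop("no soma (type 1) points in SWC input")
  if (any(!pts$type %in% c(1, 2, 3, 4))) {
    warning("unknown SWC type code(s) mapped to dendrite")
  }
  kind_of_type <- function(tp) {
    if (tp == 1) "soma" else if (tp == 2) "DA" else "dendrite"
  }
  row_of <- setNames(seq_len(nrow(pts)), pts$id)
  kids <- split(pts$id, factor(pts$parent, levels = pts$id))
  n_children <- function(id) length(kids[[as.character(id)]])

  soma_rows <- which(pts$type == 1)
  sec_of_point <- integer(nrow(pts))
  sec_of_point[soma_rows] <- 1L

  sections <- list()
  paths <- list()
  seg_len <- function(p) {
    if (nrow(p) < 2) return(0)
    sum(sqrt(rowSums((p[-1, 1:3, drop = FALSE] -
                      p[-nrow(p), 1:3, drop = FALSE])^2)))
  }
  soma_path <- as.matrix(pts[soma_rows, c("x", "y", "z", "r")])
  soma_diam <- 2 * mean(pts$r[soma_rows])
  soma_len <- max(seg_len(soma_path), soma_diam)
  sections[[1]] <- data.frame(id = 1L, parent_id = NA_integer_,
                              kind = "soma", length = soma_len,
                              diameter = soma_diam,
                              n_segments = NA_integer_)
  paths[["1"]] <- soma_path

  next_sec <- 2L
  # seeds: non-soma points whose parent is soma or is a branch point or has
  # different type; walk each chain forward
  starts <- which(pts$type != 1 &
                  (pts$parent == -1 |
                   pts$type[row_of[as.character(pts$parent)]] != pts$type |
                   vapply(pts$parent, function(p) p != -1 && n_children(p) > 1,
                          logical(1))))
  # process in tree order so parent sections exist first
  depth <- integer(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    p <- pts$parent[i]
    depth[i] <- if (p == -1) 0L else depth[row_of[as.character(p)]] + 1L
  }
  for (s0 in starts[order(depth[starts])]) {
    chain <- s0
    repeat {
      tip <- chain[length(chain)]
      ch <- kids[[as.character(pts$id[tip])]]
      if (length(ch) != 1) break
      chrow <- row_of[as.character(ch)]
      if (pts$type[chrow] != pts$type[tip] || pts$type[chrow] == 1) break
      chain <- c(chain, chrow)
    }
    sec_of_point[chain] <- next_sec
    prow <- pts$parent[s0]
    parent_sec <- if (prow == -1) 1L else sec_of_point[row_of[as.character(prow)]]
    if (parent_sec == 0) stop("internal error: unresolved parent section")
    ppath <- if (prow == -1) NULL else {
      pr <- row_of[as.character(prow)]
      as.matrix(pts[pr, c("x", "y", "z", "r")])
    }
    path <- rbind(ppath, as.matrix(pts[chain, c("x", "y", "z", "r")]))
    sections[[next_sec]] <- data.frame(
      id = next_sec, parent_id = parent_sec,
      kind = kind_of_type(pts$type[chain[1]]),
      length = max(seg_len(path), 1e-6),
      diameter = 2 * mean(pts$r[chain]),
      n_segments = NA_integer_)
    paths[[as.character(next_sec)]] <- path
    next_sec <- next_sec + 1L
  }
  sec <- do.call(rbind, sections)
  morph <- morphology(sec, paths,
                      soma_position = colMeans(soma_path[, 1:3, drop = FALSE]),
                      stratification = "monostratified")
  attr(morph, "swc_n_points") <- nrow(pts)
  morph
}

#' Serialize a morphology to SWC text
#'
#' Inverse of [load_swc()] for loaded morphologies: soma writes as type 1,
#' dendrites as type 3, axon kinds as type 2.  For sections with a parent,
#' the first path row (the attachment point, owned by the parent) is not
#' re-written.
#'
#' @param morph An [morphology()] object whose sections carry paths.
#' @param file Optional path; if `NULL`, the SWC lines are returned.
#' @return Character vector of SWC lines (invisibly when written to file).
#' @export
write_swc <- function(morph, file = NULL) {
  stopifnot(inherits(morph, "rgc_morphology"))
  type_of_kind <- function(k) {
    if (k == "soma") 1L else if (k == "dendrite") 3L else 2L
  }
  s <- morph$sections
  ord <- order(s$id)
  lines <- character(0)
  next_pt <- 1L
  pts_of_sec <- list() # section id -> matrix(id, x, y, z) of written points
  for (i in ord) {
    id <- s$id[i]
    path <- morph$paths[[as.character(id)]]
    if (is.null(path)) stop("section ", id, " has no path; cannot serialize")
    if (ncol(path) == 3) {
      path <- cbind(path, s$diameter[i] / 2)
    }
    root <- is.na(s$parent_id[i])
    rows <- if (root) seq_len(nrow(path)) else seq_len(nrow(path))[-1]
    if (root) {
      prev <- -1L
    } else {
      # attach to the parent's written point closest to the attachment row
      pp <- pts_of_sec[[as.character(s$parent_id[i])]]
      d2 <- (pp[, 2] - path[1, 1])^2 + (pp[, 3] - path[1, 2])^2 +
        (pp[, 4] - path[1, 3])^2
      prev <- as.integer(pp[which.min(d2), 1])
    }
    written <- matrix(numeric(0), ncol = 4)
    for (r in rows) {
      lines <- c(lines, sprintf("%d %d %.10g %.10g %.10g %.10g %d",
                                next_pt, type_of_kind(s$kind[i]),
                                path[r, 1], path[r, 2], path[r, 3],
                                path[r, 4], prev))
      written <- rbind(written, c(next_pt, path[r, 1:3]))
      prev <- next_pt
      next_pt <- next_pt + 1L
    }
    pts_of_sec[[as.character(id)]] <- written
  }
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
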