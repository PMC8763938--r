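# SWC morphology handling: reading/validation, alveus-referenced Sholl
# length binning, and soma-relative morphometrics.

#' Read and validate an SWC morphology
#'
#' Standard 7-column SWC (`id, type, x, y, z, radius, parent`), `#`
#' comments allowed. Validates a single root, acyclic parentage, and
#' parents defined before use. SWC types: 1 soma, 2 axon, 3 basal
#' dendrite, 4 apical dendrite.
#'
#' @param path SWC file path.
#' @param reference_line Optional 2 x 2 matrix, two (x, y) points
#'   defining the alveus reference line.
#' @return A `morphology` object (`nodes` data frame + `reference_line`).
#' @export
read_swc <- function(path, reference_line = NULL) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("SWC file has no data rows: ", path)
  fields <- strsplit(lines, "\\s+")
  bad <- which(lengths(fields) != 7)
  if (length(bad)) stop("SWC row ", bad[1], " does not have 7 fields")
  m <- matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE)
  nodes <- data.frame(id = as.integer(m[, 1]), type = as.integer(m[, 2]),
                      x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
                      parent = as.integer(m[, 7]))
  morphology(nodes, reference_line)
}

#' Construct and validate a morphology from an SWC node table
#'
#' @param nodes Data frame with SWC columns
#'   `id, type, x, y, z, radius, parent`.
#' @param reference_line Optional 2 x 2 matrix of two (x, y) points (the
#'   alveus line).
#' @return A `morphology` object.
#' @export
morphology <- function(nodes, reference_line = NULL) {
  req <- c("id", "type", "x", "y", "z", "radius", "parent")
  stopifnot(is.data.frame(nodes), all(req %in% names(nodes)))
  if (anyDuplicated(nodes$id)) stop("duplicate SWC node ids")
  roots <- nodes$id[nodes$parent == -1]
  if (length(roots) != 1) {
    stop("morphology must have exactly one root, found ", length(roots))
  }
  idx <- match(nodes$parent, nodes$id)
  orphan <- which(nodes$parent != -1 & is.na(idx))
  if (length(orphan)) {
    stop("node ", nodes$id[orphan[1]], " references missing parent ",
         nodes$parent[orphan[1]])
  }
  # walk to root from every node; revisiting a node means a cycle
  for (i in seq_len(nrow(nodes))) {
    seen <- integer(0); j <- i
    while (nodes$parent[j] != -1) {
      if (j %in% seen) stop("cycle detected at node ", nodes$id[j])
      seen <- c(seen, j)
      j <- match(nodes$parent[j], nodes$id)
    }
  }
  if (!is.null(reference_line)) {
    reference_line <- as.matrix(reference_line)
    stopifnot(nrow(reference_line) == 2, ncol(reference_line) >= 2)
  }
  structure(list(nodes = nodes, reference_line = reference_line,
                 root = roots),
            class = "morphology")
}

point_line_distance <- function(px, py, line) {
  p1 <- line[1, 1:2]; p2 <- line[2, 1:2]
  d <- p2 - p1
  len <- sqrt(sum(d^2))
  if (len == 0) stop("degenerate reference line")
  abs(d[2] * (px - p1[1]) - d[1] * (py - p1[2])) / len
}

segment_table <- function(morph) {
  nodes <- morph$nodes
  child <- which(nodes$parent != -1)
  par <- match(nodes$parent[child], nodes$id)
  data.frame(child = child, parent = par,
             length = sqrt((nodes$x[child] - nodes$x[par])^2 +
                             (nodes$y[child] - nodes$y[par])^2 +
                             (nodes$z[child] - nodes$z[par])^2),
             mid_x = (nodes$x[child] + nodes$x[par]) / 2,
             mid_y = (nodes$y[child] + nodes$y[par]) / 2,
             type = nodes$type[child])
}

#' Dendritic length per distance-from-alveus bin
#'
#' Each dendritic segment's length is accumulated into bins by the
#' perpendicular distance of its midpoint from the alveus reference
#' line, separately for apical (SWC type 4) and basal (type 3)
#' compartments. Bins are half-open `[lo, hi)`.
#'
#' @param morph A [morphology()] with a reference line.
#' @param bin_width Bin width, micrometres (default 10).
#' @return Data frame: `bin_lo`, `bin_hi`, `apical`, `basal` (summed
#'   lengths, micrometres).
#' @export
sholl_from_reference <- function(morph, bin_width = 10) {
  stopifnot(inherits(morph, "morphology"))
  if (is.null(morph$reference_line)) {
    stop("morphology has no alveus reference line")
  }
  seg <- segment_table(morph)
  seg <- seg[seg$type %in% c(3, 4), , drop = FALSE]
  if (!nrow(seg)) {
    return(data.frame(bin_lo = numeric(0), bin_hi = numeric(0),
                      apical = numeric(0), basal = numeric(0)))
  }
  dist <- point_line_distance(seg$mid_x, seg$mid_y, morph$reference_line)
  bin <- floor(dist / bin_width)
  n_bins <- max(bin) + 1
  acc <- function(type) {
    sel <- seg$type == type
    vapply(seq_len(n_bins) - 1,
           function(b) sum(seg$length[sel & bin == b]), numeric(1))
  }
  data.frame(bin_lo = (seq_len(n_bins) - 1) * bin_width,
             bin_hi = seq_len(n_bins) * bin_width,
             apical = acc(4), basal = acc(3))
}

path_length_to_root <- function(morph, i) {
  nodes <- morph$nodes
  total <- 0; j <- i
  while (nodes$parent[j] != -1) {
    p <- match(nodes$parent[j], nodes$id)
    total <- total + sqrt((nodes$x[j] - nodes$x[p])^2 +
                            (nodes$y[j] - nodes$y[p])^2 +
                            (nodes$z[j] - nodes$z[p])^2)
    j <- p
  }
  total
}

#' Soma-relative morphometrics
#'
#' `farthest_tip`: maximum Euclidean distance from the soma to any
#' dendritic terminal. `apical_bifurcation`: path distance from the soma
#' to the first apical (type 4) node with two or more children; `NaN`
#' with a flag when the apical trunk never bifurcates.
#'
#' @param morph A [morphology()].
#' @return List `farthest_tip` (micrometres), `apical_bifurcation`
#'   (micrometres or `NaN`), `has_apical_bifurcation`.
#' @export
morph_metrics <- function(morph) {
  stopifnot(inherits(morph, "morphology"))
  nodes <- morph$nodes
  soma_i <- match(morph$root, nodes$id)
  n_children <- tabulate(match(nodes$parent, nodes$id), nbins = nrow(nodes))
  dend <- nodes$type %in% c(3, 4)
  tips <- which(dend & n_children == 0)
  farthest <- if (length(tips)) {
    max(sqrt((nodes$x[tips] - nodes$x[soma_i])^2 +
               (nodes$y[tips] - nodes$y[soma_i])^2 +
               (nodes$z[tips] - nodes$z[soma_i])^2))
  } else NaN
  forks <- which(nodes$type == 4 & n_children >= 2)
  if (length(forks)) {
    dists <- vapply(forks, function(i) path_length_to_root(morph, i),
                    numeric(1))
    apical <- min(dists)
    has_fork <- TRUE
  } else {
    apical <- NaN
    has_fork <- FALSE
  }
  list(farthest_tip = farthest, apical_bifurcation = apical,
       has_apical_bifurcation = has_fork)
}
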