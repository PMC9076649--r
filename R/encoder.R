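#' Delaunay neighbor graph of a particle pattern
#'
#' Two particles are "neighbors" when the Delaunay triangulation of the
#' particle centers joins them with an edge. The triangulation also yields the
#' pattern's convex-hull (boundary) particles: vertices incident to an edge
#' that belongs to a single triangle. Boundary particles have artificially
#' truncated neighborhoods, so the encoder discards their strings by default.
#'
#' Cocircular degeneracies (four or more points on one circle) admit more than
#' one valid triangulation; which one is returned is implementation-defined,
#' but the adjacency is always symmetric and every edge satisfies the
#' empty-circumcircle property.
#'
#' @param particles data frame with columns `x`, `y` (image convention:
#'   y increases downward); a `color` column is allowed but not required
#'   here.
#' @return A list of class `neighbor_graph` with elements
#'   * `edges`: tibble of triangulation edges (`from`, `to`, 1-based row
#'     indices, `from < to`),
#'   * `adjacency`: list of sorted integer neighbor vectors, one per particle,
#'   * `hull`: integer vector of boundary particle indices.
#' @examples
#' pts <- tibble::tibble(x = c(0, 1, 0, 1), y = c(0, 0, 1, 1.2))
#' delaunay_graph(pts)$edges
#' @export
delaunay_graph <- function(particles) {
  if (!all(c("x", "y") %in% names(particles)))
    abort("particles must have columns x and y")
  if (any(!is.finite(particles$x)) || any(!is.finite(particles$y)))
    abort("coordinates must be finite")
  dup <- duplicated(paste(particles$x, particles$y, sep = ","))
  if (any(dup))
    abort(sprintf("duplicate particle coordinates in row %d", which(dup)[1]))
  if (nrow(particles) < 3)
    abort("degenerate geometry: need at least 3 particles")
  g <- .cpp_delaunay(particles$x, particles$y)
  out <- list(
    edges = tibble(from = g$edges[, 1], to = g$edges[, 2]),
    adjacency = g$adjacency,
    hull = sort(g$hull)
  )
  class(out) <- "neighbor_graph"
  out
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("<neighbor_graph: %d vertices, %d edges, %d on hull>\n",
              length(x$adjacency), nrow(x$edges), length(x$hull)))
  invisible(x)
}

#' Order neighbors clockwise around a center particle
#'
#' Neighbors are sorted by increasing `atan2(y - y_c, x - x_c)`. In the y-down
#' image frame this is the clockwise direction as the pattern is displayed on
#' screen. The result is a cyclic sequence: the starting element is arbitrary
#' (it is fixed later by [canonical_rotation()]).
#'
#' @param center a length-2 numeric `c(x, y)` or a 1-row data frame with `x`
#'   and `y`.
#' @param neighbors data frame of neighbor particles with columns `x`, `y`.
#' @return Integer permutation of `seq_len(nrow(neighbors))` in clockwise
#'   order.
#' @export
order_neighbors_clockwise <- function(center, neighbors) {
  if (is.data.frame(center)) center <- c(center$x[1], center$y[1])
  dx <- neighbors$x - center[1]
  dy <- neighbors$y - center[2]
  if (any(dx == 0 & dy == 0))
    abort("neighbor coincides with the center particle")
  order(atan2(dy, dx))
}

#' Canonical rotation of a cyclic letter sequence
#'
#' Returns the lexicographically smallest rotation of the cycle, read in the
#' fixed clockwise direction. This generalizes the start-at-the-alphabetically-
#' first-letter rule: when several neighbors tie for the earliest letter, the
#' winner is the one whose following letters (continuing clockwise) compare
#' smallest, with ties resolved to arbitrary depth. The result is independent
#' of which neighbor the cycle happened to start at.
#'
#' @param cycle a character vector of single letters, or one string.
#' @return A single string: the canonical reading of the cycle.
#' @examples
#' canonical_rotation(c("G", "W", "W", "G", "Y")) # "GWWGY"
#' @export
canonical_rotation <- function(cycle) {
  s <- if (length(cycle) == 1L && nchar(cycle) > 1L) {
    strsplit(cycle, "")[[1]]
  } else {
    as.character(cycle)
  }
  if (length(s) == 0) abort("cycle must be non-empty")
  k <- length(s)
  rotations <- vapply(seq_len(k), function(i) {
    paste(s[c(i:k, seq_len(i - 1L))], collapse = "")
  }, character(1))
  min(rotations)
}

#' Encode one neighborhood as a string
#'
#' A neighborhood string is the center particle's letter followed by its
#' neighbors' letters read clockwise from the canonical starting point.
#'
#' @param center_color single letter of the center particle.
#' @param cycle neighbors' letters in clockwise cyclic order (any starting
#'   point).
#' @return The neighborhood string.
#' @examples
#' encode_neighborhood("P", c("D", "G", "R", "P", "W", "W")) # "PDGRPWW"
#' @export
encode_neighborhood <- function(center_color, cycle) {
  paste0(center_color, canonical_rotation(cycle))
}

#' Convert a particle pattern to its canonical string set
#'
#' The core encoding: each particle becomes a candidate string (its own color
#' letter, then its Delaunay neighbors' letters clockwise, canonicalized with
#' [canonical_rotation()]), and low-quality candidates are discarded:
#'
#' * strings whose center lies on the convex hull (`discard_hull`), because
#'   boundary neighborhoods are truncated and unstable between photographs;
#' * strings with fewer than `min_distinct_colors` distinct letters, which are
#'   too likely to recur on other pills (important when one color, such as
#'   white, is heavily over-represented);
#' * strings with fewer than `min_neighbors` neighbors.
#'
#' Duplicate strings from different neighborhoods of the same pill are kept:
#' the result is a multiset, and matching uses multiset-intersection counts.
#'
#' @inheritParams delaunay_graph
#' @param alphabet optional [candy_alphabet()] used to validate colors.
#' @param discard_hull drop strings centered on convex-hull particles
#'   (default `TRUE`).
#' @param min_distinct_colors minimum number of distinct letters a retained
#'   string must contain (default 4).
#' @param min_neighbors minimum number of neighbors (default 2).
#' @return Sorted character vector (a multiset) of retained neighborhood
#'   strings, with the input's `code_id` attribute carried through.
#' @examples
#' set.seed(1)
#' code <- simulate_candycode(40)
#' encode_candycode(code)
#' @export
encode_candycode <- function(particles, alphabet = NULL, discard_hull = TRUE,
                             min_distinct_colors = 4, min_neighbors = 2) {
  particles <- validate_particles(particles, alphabet)
  if (nrow(particles) < 3)
    abort("degenerate geometry: need at least 3 particles")
  if (any(nchar(particles$color) != 1))
    abort("colors must be single letters")
  if (min_distinct_colors < 1 || min_neighbors < 1)
    abort("filter thresholds must be >= 1")
  out <- .cpp_encode(particles$x, particles$y, particles$color,
                     isTRUE(discard_hull), as.integer(min_distinct_colors),
                     as.integer(min_neighbors))
  attr(out, "code_id") <- attr(particles, "code_id")
  out
}
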