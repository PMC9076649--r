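# Independent oracles used across the test files.

# Brute-force Delaunay edge set via the empty-circumcircle property: a
# triangle (i, j, k) belongs to the triangulation iff no other point lies
# strictly inside its circumcircle; the Delaunay edges are the edges of those
# triangles. O(n^4), fine for n <= 25.
oracle_delaunay_edges <- function(particles) {
  x <- particles$x
  y <- particles$y
  n <- length(x)
  edges <- character(0)
  for (i in 1:(n - 2)) {
    for (j in (i + 1):(n - 1)) {
      for (k in (j + 1):n) {
        ax <- x[i]; ay <- y[i]; bx <- x[j]; by <- y[j]; cx <- x[k]; cy <- y[k]
        d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
        if (abs(d) < 1e-12) next  # collinear triple
        ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
                 (cx^2 + cy^2) * (ay - by)) / d
        uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
                 (cx^2 + cy^2) * (bx - ax)) / d
        r2 <- (ax - ux)^2 + (ay - uy)^2
        d2 <- (x - ux)^2 + (y - uy)^2
        inside <- d2 < r2 * (1 - 1e-9)
        inside[c(i, j, k)] <- FALSE
        if (!any(inside)) {
          edges <- c(edges,
                     paste(sort(c(i, j)), collapse = "-"),
                     paste(sort(c(i, k)), collapse = "-"),
                     paste(sort(c(j, k)), collapse = "-"))
        }
      }
    }
  }
  sort(unique(edges))
}

graph_edge_keys <- function(g) {
  sort(paste(g$edges$from, g$edges$to, sep = "-"))
}

# Reference encoder built from the exported building blocks (delaunay_graph,
# order_neighbors_clockwise, encode_neighborhood); `mirror` reverses each
# neighbor cycle, the expected effect of reflecting the coordinates.
encode_reference <- function(particles, discard_hull = TRUE,
                             min_distinct = 4, min_neighbors = 2,
                             mirror = FALSE) {
  g <- delaunay_graph(particles)
  out <- character(0)
  for (v in seq_len(nrow(particles))) {
    if (discard_hull && v %in% g$hull) next
    nb <- g$adjacency[[v]]
    if (length(nb) < min_neighbors) next
    ord <- order_neighbors_clockwise(c(particles$x[v], particles$y[v]),
                                     particles[nb, ])
    cyc <- particles$color[nb][ord]
    if (mirror) cyc <- rev(cyc)
    s <- encode_neighborhood(particles$color[v], cyc)
    if (length(unique(strsplit(s, "")[[1]])) < min_distinct) next
    out <- c(out, s)
  }
  sort(out)
}

naive_max_shared <- function(strings) {
  n <- length(strings)
  if (n < 2) return(0L)
  best <- 0L
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      best <- max(best, count_shared(strings[[i]], strings[[j]]))
    }
  }
  best
}

random_particles <- function(n, letters = c("D", "G", "L", "O", "P", "R",
                                            "W", "Y")) {
  tibble::tibble(
    x = stats::runif(n),
    y = stats::runif(n),
    color = sample(letters, n, replace = TRUE)
  )
}
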