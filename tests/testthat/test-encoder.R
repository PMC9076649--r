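test_that("a single triangle gives two neighbors each, all on the hull", {
  pts <- tibble::tibble(x = c(0, 1, 0.3), y = c(0, 0, 0.8),
                        color = c("W", "G", "P"))
  g <- delaunay_graph(pts)
  expect_equal(lengths(g$adjacency), rep(2L, 3))
  expect_equal(g$hull, 1:3)
  expect_equal(nrow(g$edges), 3)
})

test_that("degenerate geometry is rejected", {
  expect_error(delaunay_graph(tibble::tibble(x = c(0, 1), y = c(0, 0))),
               "at least 3")
  collinear <- tibble::tibble(x = 0:4, y = 2 * (0:4))
  expect_error(delaunay_graph(collinear), "collinear")
})

test_that("a cocircular square yields both sides and exactly one diagonal", {
  sq <- tibble::tibble(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  g <- delaunay_graph(sq)
  keys <- graph_edge_keys(g)
  sides <- c("1-2", "2-3", "3-4", "1-4")
  expect_true(all(sides %in% keys))
  expect_equal(nrow(g$edges), 5)
  expect_true(("1-3" %in% keys) || ("2-4" %in% keys))
  # adjacency symmetric
  for (v in 1:4) for (u in g$adjacency[[v]]) {
    expect_true(v %in% g$adjacency[[u]])
  }
})

test_that("Delaunay edges match the brute-force empty-circumcircle oracle", {
  set.seed(501)
  for (n in c(8, 15, 20, 25)) {
    pts <- random_particles(n)
    g <- delaunay_graph(pts)
    expect_equal(graph_edge_keys(g), oracle_delaunay_edges(pts),
                 info = paste("n =", n))
  }
})

test_that("Delaunay edges agree with deldir on larger patterns", {
  set.seed(502)
  for (n in c(40, 94)) {
    pts <- random_particles(n)
    g <- delaunay_graph(pts)
    dd <- deldir::deldir(pts$x, pts$y)$delsgs
    keys <- sort(paste(pmin(dd$ind1, dd$ind2), pmax(dd$ind1, dd$ind2),
                       sep = "-"))
    expect_equal(graph_edge_keys(g), keys, info = paste("n =", n))
  }
})

test_that("hull vertices are exactly the convex-hull boundary points", {
  set.seed(503)
  pts <- random_particles(60)
  g <- delaunay_graph(pts)
  expect_setequal(g$hull, sort(grDevices::chull(pts$x, pts$y)))
})

test_that("clockwise ordering follows increasing atan2 in the y-down frame", {
  nb <- tibble::tibble(x = c(0, 1, 0, -1), y = c(-1, 0, 1, 0))
  ord <- order_neighbors_clockwise(c(0, 0), nb)
  # displayed clockwise: above, right, below, left
  expect_equal(ord, c(1L, 2L, 3L, 4L))
  expect_equal(order_neighbors_clockwise(c(0, 0),
                                         tibble::tibble(x = 2, y = 3)), 1L)
  expect_error(order_neighbors_clockwise(c(1, 1),
                                         tibble::tibble(x = 1, y = 1)),
               "coincides")
})

test_that("canonical rotation picks the lexicographically smallest reading", {
  expect_equal(canonical_rotation(c("D", "G", "R", "P", "W", "W")), "DGRPWW")
  expect_equal(canonical_rotation(c("G", "W", "W", "G", "Y")), "GWWGY")
  expect_equal(canonical_rotation(c("W", "W", "W")), "WWW")
  expect_equal(canonical_rotation("YGW"), "GWY")
})

test_that("canonical rotation is independent of the cycle's starting point", {
  set.seed(504)
  letters8 <- candy_alphabet("A")$letter
  for (rep in 1:50) {
    k <- sample(3:9, 1)
    cyc <- sample(letters8, k, replace = TRUE)
    ref <- canonical_rotation(cyc)
    for (shift in seq_len(k - 1)) {
      rotated <- cyc[c((shift + 1):k, 1:shift)]
      expect_identical(canonical_rotation(rotated), ref)
    }
  }
})

test_that("neighborhood strings start with the center color", {
  expect_equal(encode_neighborhood("P", c("D", "G", "R", "P", "W", "W")),
               "PDGRPWW")
  expect_equal(encode_neighborhood("W", c("G", "W", "W", "G", "Y")),
               "WGWWGY")
  expect_equal(encode_neighborhood("G", "Y"), "GY")
})

test_that("with all filters off, every particle yields one string", {
  set.seed(505)
  code <- simulate_candycode(94)
  s <- encode_candycode(code, discard_hull = FALSE, min_distinct_colors = 1,
                        min_neighbors = 1)
  expect_length(s, 94)
})

test_that("a monochrome pattern encodes to the empty string set", {
  set.seed(506)
  code <- simulate_candycode(40)
  code$color <- "W"
  expect_length(encode_candycode(code), 0)
})

test_that("the compiled encoder matches the step-by-step reference pipeline", {
  set.seed(507)
  for (rep in 1:5) {
    code <- simulate_candycode(60)
    expect_identical(encode_candycode(code), {
      s <- encode_reference(code)
      attributes(s) <- NULL
      s
    })
    # and with the filters disabled
    expect_identical(
      as.character(encode_candycode(code, discard_hull = FALSE,
                                    min_distinct_colors = 1,
                                    min_neighbors = 1)),
      encode_reference(code, discard_hull = FALSE, min_distinct = 1,
                       min_neighbors = 1))
  }
})

test_that("encoding is invariant under translation and rotation", {
  set.seed(508)
  code <- simulate_candycode(50)
  s0 <- as.character(encode_candycode(code))
  shifted <- code
  shifted$x <- code$x + 17.3
  shifted$y <- code$y - 4.1
  expect_identical(as.character(encode_candycode(shifted)), s0)
  th <- 0.7
  rotated <- code
  rotated$x <- cos(th) * code$x - sin(th) * code$y + 2
  rotated$y <- sin(th) * code$x + cos(th) * code$y - 1
  expect_identical(as.character(encode_candycode(rotated)), s0)
})

test_that("a mirrored pattern encodes as the reversed neighbor cycles", {
  set.seed(509)
  code <- simulate_candycode(40)
  mirrored <- code
  mirrored$x <- -code$x
  expect_identical(as.character(encode_candycode(mirrored)),
                   encode_reference(code, mirror = TRUE))
})

test_that("retained strings respect the filters", {
  set.seed(510)
  code <- simulate_candycode(94)
  s <- encode_candycode(code, min_distinct_colors = 4)
  distinct <- vapply(strsplit(s, ""), function(x) length(unique(x)),
                     integer(1))
  expect_true(all(distinct >= 4))
  # hull centers are excluded: filters-off minus hull strings == default
  # pool at min_distinct 1
  g <- delaunay_graph(code)
  all_on <- encode_candycode(code, discard_hull = TRUE,
                             min_distinct_colors = 1, min_neighbors = 2)
  expect_length(all_on, nrow(code) - length(g$hull))
  expect_error(encode_candycode(code, min_distinct_colors = 0), ">= 1")
})

test_that("encoding the same pattern twice is deterministic", {
  set.seed(511)
  code <- simulate_candycode(70)
  expect_identical(encode_candycode(code), encode_candycode(code))
})
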