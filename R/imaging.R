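#' Display palette for rendering and detecting synthetic pill images
#'
#' Maps each alphabet letter to an sRGB display color, plus two reserved
#' roles: the pill face and the image background. The built-in colors are
#' chosen so that every pair of palette entries is at least 0.25 apart in
#' Euclidean RGB distance (unit cube), which makes nearest-centroid pixel
#' classification unambiguous on clean renders and robust to moderate pixel
#' noise. Custom palettes below a separation of 0.2 are rejected.
#'
#' @param alphabet a [candy_alphabet()] whose letters must all have palette
#'   entries (the 15 built-in letters are covered).
#' @param colors optional named list/vector of hex colors or RGB triples
#'   (0-255) overriding or extending the built-in letter colors.
#' @return Tibble of class `candy_palette` with columns `name`, `role`
#'   (`"particle"`, `"pill"` or `"background"`) and `r`, `g`, `b` in \[0, 1\].
#' @export
candy_palette <- function(alphabet = candy_alphabet("A"), colors = NULL) {
  builtin <- list(
    D = c(0, 0, 153),      # dark blue
    G = c(0, 153, 0),      # green
    L = c(102, 204, 255),  # light blue
    O = c(255, 128, 0),    # orange
    P = c(255, 105, 180),  # pink
    R = c(230, 0, 0),      # red
    W = c(255, 255, 255),  # white
    Y = c(255, 255, 0),    # yellow
    K = c(0, 0, 0),        # black
    A = c(105, 105, 105),  # dark gray
    E = c(200, 200, 200),  # light gray
    N = c(0, 80, 0),       # dark green
    M = c(255, 0, 255),    # magenta
    U = c(128, 0, 200),    # purple
    B = c(139, 69, 19)     # brown
  )
  if (!is.null(colors)) {
    for (nm in names(colors)) {
      v <- colors[[nm]]
      if (is.character(v)) v <- grDevices::col2rgb(v)[, 1]
      builtin[[nm]] <- as.numeric(v)
    }
  }
  letters <- alphabet_letters(alphabet)
  missing <- setdiff(letters, names(builtin))
  if (length(missing))
    abort(paste0("no palette color for letter(s): ",
                 paste(missing, collapse = ", ")))
  rows <- c(
    purrr::map(letters, function(l) {
      tibble(name = l, role = "particle",
             r = builtin[[l]][1] / 255, g = builtin[[l]][2] / 255,
             b = builtin[[l]][3] / 255)
    }),
    list(tibble(name = "pill", role = "pill",
                r = 45 / 255, g = 30 / 255, b = 60 / 255),
         tibble(name = "background", role = "background",
                r = 10 / 255, g = 70 / 255, b = 110 / 255))
  )
  out <- bind_rows(rows)
  sep <- palette_separation(out)
  if (sep < 0.2)
    abort(sprintf(
      "palette entries are too close (min separation %.3f < 0.2)", sep))
  class(out) <- c("candy_palette", class(out))
  out
}

#' @rdname candy_palette
#' @param palette a `candy_palette`.
#' @return `palette_separation()`: the minimum pairwise Euclidean RGB
#'   distance.
#' @export
palette_separation <- function(palette) {
  m <- as.matrix(palette[, c("r", "g", "b")])
  min(stats::dist(m))
}

#' Render a particle pattern as a synthetic pill photograph
#'
#' Draws the pill as a filled disk on a plain background and each particle as
#' a filled circle of its palette color, in the y-down image frame (row 1 is
#' the top of the image). Particle edges are anti-aliased (boundary pixels
#' blend the particle color with what lies beneath in proportion to coverage)
#' — as in a real photograph — which lets [detect_particles()] recover
#' centers with deep sub-pixel accuracy. The output is a deterministic
#' function of its inputs, so renders can serve as reproducible fixtures
#' standing in for photographs.
#'
#' @param particles particle tibble (`x`, `y`, `color`).
#' @param palette a [candy_palette()] covering the particle colors.
#' @param pixels_per_unit scale from coordinate units to pixels.
#' @param pill_radius,particle_radius geometry; default to the tibble's
#'   attributes (as set by [simulate_candycode()]).
#' @return Numeric array `height x width x 3` with values in \[0, 1\], suitable
#'   for [png::writePNG()]. The scale is stored in the `"pixels_per_unit"`
#'   attribute.
#' @export
render_candycode <- function(particles, palette = NULL, pixels_per_unit = 200,
                             pill_radius = NULL, particle_radius = NULL) {
  particles <- validate_particles(particles)
  palette <- palette %||% candy_palette(attr(particles, "alphabet") %||%
                                          candy_alphabet("A"))
  pill_radius <- pill_radius %||% attr(particles, "pill_radius") %||% 1
  particle_radius <- particle_radius %||% attr(particles, "particle_radius") %||%
    (sqrt(0.45 / max(nrow(particles), 1)) * pill_radius)
  if (pixels_per_unit <= 0) abort("`pixels_per_unit` must be positive")
  # particles are drawn at 90% of their physical radius so that tangent
  # same-color particles remain separate connected components after
  # rasterization
  pr_px <- 0.9 * particle_radius * pixels_per_unit
  if (pr_px < 2)
    abort(sprintf(
      "particle circles would be %.2f px (< 2 px); increase `pixels_per_unit`",
      pr_px))
  half <- pill_radius * 1.1
  wh <- ceiling(2 * half * pixels_per_unit)
  pal <- function(nm) unlist(palette[palette$name == nm, c("r", "g", "b")])
  bg <- pal("background")
  pill <- pal("pill")
  img <- array(rep(bg, each = wh * wh), dim = c(wh, wh, 3))
  # pixel centers in image coordinates
  cc <- (seq_len(wh) - 0.5)
  cx <- half * pixels_per_unit
  d2 <- outer((cc - cx)^2, (cc - cx)^2, `+`)  # rows (y) x cols (x)
  pill_mask <- d2 <= (pill_radius * pixels_per_unit)^2
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[pill_mask] <- pill[ch]
    img[, , ch] <- plane
  }
  px <- (particles$x + half) * pixels_per_unit
  py <- (particles$y + half) * pixels_per_unit
  for (i in seq_len(nrow(particles))) {
    col3 <- pal(particles$color[i])
    rows <- max(1, floor(py[i] - pr_px - 1)):min(wh, ceiling(py[i] + pr_px + 1))
    cols <- max(1, floor(px[i] - pr_px - 1)):min(wh, ceiling(px[i] + pr_px + 1))
    if (!length(rows) || !length(cols)) next
    dd <- sqrt(outer((rows - 0.5 - py[i])^2, (cols - 0.5 - px[i])^2, `+`))
    alpha <- pmin(pmax(pr_px - dd + 0.5, 0), 1)  # approximate coverage
    for (ch in 1:3) {
      plane <- matrix(img[rows, cols, ch], nrow = length(rows))
      plane <- (1 - alpha) * plane + alpha * col3[ch]
      img[rows, cols, ch] <- plane
    }
  }
  attr(img, "pixels_per_unit") <- pixels_per_unit
  img
}

#' Detect particles in a synthetic pill image
#'
#' Each pixel is classified by linear unmixing against the pill face: a pixel
#' on the edge of a particle is a blend `alpha * letter + (1 - alpha) * pill`,
#' so classification assigns the pixel to whichever palette segment
#' (pill-to-letter line in RGB space), pill color or background color it is
#' nearest to, and a pixel belongs to a particle when its coverage `alpha`
#' exceeds 0.5. Connected components of each letter are then labeled and each
#' sufficiently large component becomes one particle at its coverage-weighted
#' centroid (computed over the component and a one-pixel dilation ring), in
#' y-down pixel coordinates.
#'
#' The coverage weighting exploits the anti-aliased particle edges that
#' [render_candycode()] (and any real camera) produces, recovering particle
#' centers to roughly a hundredth of a pixel; that is accurate enough that
#' encoding the detected pattern almost always reproduces the directly
#' encoded string set edge for edge — only a Delaunay quad within that
#' distance of exact cocircularity (rare at the default render scale) can
#' flip. Real-photograph effects (shadows, specularities, occlusion) are out
#' of scope.
#'
#' @param image numeric array `height x width x 3` in \[0, 1\] (e.g. from
#'   [png::readPNG()] or [render_candycode()]).
#' @param palette the [candy_palette()] the image was rendered with.
#' @param alphabet alphabet restricting which particle letters are searched.
#' @param min_pixels smallest component accepted as a particle (default 4),
#'   screening out isolated noise pixels.
#' @return Particle tibble (`x`, `y`, `color`) in pixel units.
#' @export
detect_particles <- function(image, palette = candy_palette(),
                             alphabet = candy_alphabet("A"), min_pixels = 4) {
  if (length(dim(image)) == 2) {
    abort("image must have 3 channels")
  }
  if (dim(image)[3] > 3) image <- image[, , 1:3, drop = FALSE]
  h <- dim(image)[1]
  w <- dim(image)[2]
  n <- h * w
  px <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
              as.vector(image[, , 3]))
  getcol <- function(nm) {
    unlist(palette[palette$name == nm, c("r", "g", "b")], use.names = FALSE)
  }
  pill <- getcol("pill")
  bg <- getcol("background")
  letters <- intersect(alphabet_letters(alphabet), palette$name)

  # distance to the pill->letter segment and the coverage alpha (projection)
  # for every letter; plus the pill and background point classes
  seg_stats <- function(col3) {
    v <- col3 - pill
    len2 <- sum(v * v)
    t <- ((px[, 1] - pill[1]) * v[1] + (px[, 2] - pill[2]) * v[2] +
            (px[, 3] - pill[3]) * v[3]) / len2
    tc <- pmin(pmax(t, 0), 1)
    dx <- px[, 1] - (pill[1] + tc * v[1])
    dy <- px[, 2] - (pill[2] + tc * v[2])
    dz <- px[, 3] - (pill[3] + tc * v[3])
    list(d2 = dx * dx + dy * dy + dz * dz, alpha = tc)
  }
  L <- length(letters)
  # every pill->letter segment passes through the pill color, so seed the
  # classification with the pill and background point classes and let a
  # letter claim a pixel only by strictly improving the distance; whether a
  # claimed pixel is actually part of a particle is decided by its coverage
  d_pill <- (px[, 1] - pill[1])^2 + (px[, 2] - pill[2])^2 +
    (px[, 3] - pill[3])^2
  d_bg <- (px[, 1] - bg[1])^2 + (px[, 2] - bg[2])^2 + (px[, 3] - bg[3])^2
  bestd <- d_pill
  besti <- rep(L + 1L, n)
  upd <- d_bg < bestd
  bestd[upd] <- d_bg[upd]
  besti[upd] <- L + 2L
  alphas <- matrix(0, n, L)
  for (k in seq_len(L)) {
    st <- seg_stats(getcol(letters[k]))
    alphas[, k] <- st$alpha
    upd <- st$d2 < bestd
    bestd[upd] <- st$d2[upd]
    besti[upd] <- k
  }
  if (!any(besti == L + 1L)) abort("no pill found in image")

  out <- list()
  for (k in seq_len(L)) {
    mask <- matrix(besti == k & alphas[, k] >= 0.5, nrow = h, ncol = w)
    if (!any(mask)) next
    labels <- EBImage::bwlabel(mask)
    nlab <- max(labels)
    sizes <- tabulate(labels[labels > 0], nbins = nlab)
    keep <- which(sizes >= min_pixels)
    if (!length(keep)) next
    am <- matrix(alphas[, k], nrow = h, ncol = w)
    xs <- ys <- numeric(length(keep))
    for (j in seq_along(keep)) {
      idx <- which(labels == keep[j], arr.ind = TRUE)
      # the sub-0.5-coverage edge pixels carry the sub-pixel position
      # information: weight a one-pixel (Chebyshev) dilation of the component
      # by the coverage map
      rows <- max(1, min(idx[, 1]) - 1):min(h, max(idx[, 1]) + 1)
      cols <- max(1, min(idx[, 2]) - 1):min(w, max(idx[, 2]) + 1)
      local <- matrix(FALSE, length(rows), length(cols))
      local[cbind(idx[, 1] - rows[1] + 1, idx[, 2] - cols[1] + 1)] <- TRUE
      dil <- local
      nr <- nrow(local)
      nc <- ncol(local)
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        src_r <- max(1, 1 - dr):min(nr, nr - dr)
        src_c <- max(1, 1 - dc):min(nc, nc - dc)
        dil[src_r + dr, src_c + dc] <-
          dil[src_r + dr, src_c + dc] | local[src_r, src_c]
      }
      wts <- am[rows, cols] * dil
      ys[j] <- sum((rows - 0.5) * rowSums(wts)) / sum(wts)
      xs[j] <- sum((cols - 0.5) * colSums(wts)) / sum(wts)
    }
    out[[letters[k]]] <- tibble(x = xs, y = ys, color = letters[k])
  }
  if (!length(out)) abort("no particles detected")
  res <- bind_rows(out) %>% arrange(.data$y, .data$x)
  attr(res, "alphabet") <- alphabet
  res
}
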