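test_that("palette entries are widely separated in RGB space", {
  expect_gte(palette_separation(candy_palette(candy_alphabet("A"))), 0.25)
  expect_gte(palette_separation(candy_palette(candy_alphabet("C"))), 0.25)
  expect_error(
    candy_palette(candy_alphabet(letters = c("W", "E")),
                  colors = list(E = c(250, 250, 250))),
    "too close")
  expect_error(candy_palette(candy_alphabet(letters = c("Q", "W"))),
               "no palette color")
})

test_that("rendering is deterministic and an empty code is a plain pill", {
  set.seed(901)
  code <- simulate_candycode(30)
  img1 <- render_candycode(code, pixels_per_unit = 120)
  img2 <- render_candycode(code, pixels_per_unit = 120)
  expect_identical(img1, img2)

  empty <- tibble::tibble(x = numeric(0), y = numeric(0),
                          color = character(0))
  pill <- render_candycode(empty, pixels_per_unit = 80, pill_radius = 1,
                           particle_radius = 0.05)
  flat <- apply(pill, 3, as.vector)
  expect_lte(nrow(unique(flat)), 2)  # pill face + background only

  expect_error(render_candycode(code, pixels_per_unit = 10), "< 2 px")
})

test_that("detection inverts rendering on a clean image", {
  set.seed(902)
  code <- simulate_candycode(94)
  pal <- candy_palette(candy_alphabet("A"))
  ppu <- 200
  img <- render_candycode(code, pal, pixels_per_unit = ppu)
  found <- detect_particles(img, pal, candy_alphabet("A"))
  expect_equal(nrow(found), 94)
  # match each true particle to the nearest detection: position within 1 px,
  # color exact
  half <- 1.1  # pill_radius * 1.1 margin used by the renderer
  tx <- (code$x + half) * ppu
  ty <- (code$y + half) * ppu
  for (i in seq_len(nrow(code))) {
    d2 <- (found$x - tx[i])^2 + (found$y - ty[i])^2
    j <- which.min(d2)
    expect_lt(sqrt(d2[j]), 1)
    expect_equal(found$color[j], code$color[i])
  }
})

test_that("render -> detect -> encode reproduces the direct string set", {
  set.seed(903)
  for (rep in 1:3) {
    code <- simulate_candycode(94)
    img <- render_candycode(code, pixels_per_unit = 200)
    found <- detect_particles(img)
    expect_identical(as.character(encode_candycode(found)),
                     as.character(encode_candycode(code)))
  }
})

test_that("detection tolerates moderate pixel noise", {
  set.seed(904)
  code <- simulate_candycode(94)
  img <- render_candycode(code, pixels_per_unit = 150)
  noisy <- img + array(stats::rnorm(length(img), 0, 8 / 255), dim = dim(img))
  noisy[] <- pmin(pmax(noisy, 0), 1)
  found <- detect_particles(noisy)
  ppu <- 150
  half <- 1.1
  tx <- (code$x + half) * ppu
  ty <- (code$y + half) * ppu
  ok <- 0
  for (i in seq_len(nrow(code))) {
    d2 <- (found$x - tx[i])^2 + (found$y - ty[i])^2
    j <- which.min(d2)
    if (sqrt(d2[j]) < 2 && found$color[j] == code$color[i]) ok <- ok + 1
  }
  expect_gte(ok / nrow(code), 0.95)
})

test_that("images without a pill or particles raise detection errors", {
  blank <- array(0, c(20, 20, 3))
  blank[, , 1] <- 10 / 255
  blank[, , 2] <- 70 / 255
  blank[, , 3] <- 110 / 255
  expect_error(detect_particles(blank), "no pill")
  empty <- tibble::tibble(x = numeric(0), y = numeric(0),
                          color = character(0))
  pill_only <- render_candycode(empty, pixels_per_unit = 80,
                                particle_radius = 0.05)
  expect_error(detect_particles(pill_only), "no particles")
})
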