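test_that("library maximum shared strings handles edge cases", {
  expect_equal(max_shared_in_library(list(c("AB"))), 0L)
  expect_equal(max_shared_in_library(list(c("AB"), c("CD"))), 0L)
  dup <- replicate(2, sprintf("S%02d", 1:53), simplify = FALSE)
  expect_equal(max_shared_in_library(dup), 53L)
  det <- max_shared_in_library(
    tibble::tibble(code_id = c("a", "b"), strings = dup), details = TRUE)
  expect_equal(det$max_shared, 53L)
  expect_setequal(c(det$i, det$j), c("a", "b"))
})

test_that("index-based library maximum equals the naive double loop", {
  set.seed(801)
  pool <- replicate(40, paste(sample(LETTERS[1:6], 5, TRUE), collapse = ""))
  strings <- purrr::map(1:50, ~ sample(pool, sample(3:15, 1), replace = TRUE))
  expect_equal(max_shared_in_library(strings), naive_max_shared(strings))
})

test_that("exact log-linear data is fitted to machine precision", {
  sizes <- c(10, 100, 1000, 10000)
  sweep <- tibble::tibble(size = rep(sizes, each = 3), replicate = rep(1:3, 4),
                          max_shared = 3 + 0.9 * log10(rep(sizes, each = 3)))
  fit <- fit_scaling(sweep)
  expect_equal(fit$slope_per_decade, 0.9, tolerance = 1e-12)
  expect_equal(fit$intercept, 3, tolerance = 1e-12)
  expect_equal(fit$residuals, rep(0, 4), tolerance = 1e-12)
  expect_equal(glance(fit)$r.squared, 1, tolerance = 1e-12)
  td <- tidy(fit)
  expect_equal(td$estimate, c(3, 0.9), tolerance = 1e-12)
})

test_that("size-1 libraries contribute zero and are excluded from the fit", {
  sweep <- tibble::tibble(size = c(1, 10, 100), replicate = 1,
                          max_shared = c(0, 1, 2))
  fit <- fit_scaling(sweep)
  expect_equal(nrow(fit$summary), 2)
  expect_equal(fit$slope_per_decade, 1)
  expect_error(fit_scaling(tibble::tibble(size = c(1, 10), replicate = 1,
                                          max_shared = c(0, 1))),
               "at least 2 usable")
})

test_that("extrapolation evaluates the fitted line", {
  flat <- structure(list(slope_per_decade = 0, intercept = 5),
                    class = "scaling_fit")
  expect_equal(extrapolate_shared(flat, 12345), 5)
  b_like <- structure(list(slope_per_decade = 0.9, intercept = 0),
                      class = "scaling_fit")
  expect_equal(extrapolate_shared(b_like, 1e17), 15.3)
  expect_error(extrapolate_shared(flat, 0.5), ">= 1")
})

test_that("sweeps are reproducible and well-formed", {
  sw1 <- run_sweep(sizes = c(5, 20), replicates = 2, n_particles = 40,
                   seed = 802)
  sw2 <- run_sweep(sizes = c(5, 20), replicates = 2, n_particles = 40,
                   seed = 802)
  expect_identical(sw1$max_shared, sw2$max_shared)
  expect_equal(nrow(sw1), 4)
  s <- summarise_sweep(sw1)
  expect_equal(s$replicates, c(2L, 2L))
  expect_error(run_sweep(sizes = c(10, 10), replicates = 2),
               "strictly increasing")
})

test_that("extrapolation inside the swept range tracks the observations", {
  set.seed(803)
  sw <- run_sweep(sizes = c(10, 30, 100, 300), replicates = 8)
  fit <- fit_scaling(sw)
  s <- summarise_sweep(sw)
  for (k in seq_len(nrow(s))) {
    expect_lt(abs(extrapolate_shared(fit, s$size[k]) - s$mean_max_shared[k]),
              2 * max(s$sd_max_shared[k], 0.25))
  }
})
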