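#' Largest shared-string count within a library
#'
#' The library-level collision statistic: the maximum, over all unordered
#' pairs of distinct codes, of the shared-string count. Computed with an
#' inverted index so that large libraries (10^5 codes) remain tractable. A
#' library with fewer than two codes has no pairs and scores 0.
#'
#' @param library tibble with a `strings` list-column (see
#'   [simulate_library()]), or a bare list of character vectors.
#' @param details return the achieving pair as well.
#' @return Integer maximum, or (with `details`) a list with `max_shared` and
#'   the two code indices/ids.
#' @export
max_shared_in_library <- function(library, details = FALSE) {
  strings <- if (is.data.frame(library)) library$strings else library
  if (length(strings) < 2) {
    if (details) return(list(max_shared = 0L, i = NA, j = NA))
    return(0L)
  }
  res <- .cpp_max_shared(strings)
  if (!details) return(res[1])
  ids <- if (is.data.frame(library)) library$code_id else seq_along(strings)
  list(max_shared = res[1], i = ids[res[2]], j = ids[res[3]])
}

#' Sweep library sizes and record maximum shared strings
#'
#' For each library size and replicate, simulates a fresh library, encodes it
#' and records [max_shared_in_library()]. This is the raw material for the
#' log-scaling fit: collisions grow logarithmically with library size, so a
#' sweep over a few decades pins down the growth per decade.
#'
#' @inheritParams simulate_library
#' @param sizes strictly increasing vector of library sizes (default
#'   `c(10, 100, 1000, 10000)`).
#' @param replicates fresh libraries per size (default 20).
#' @return Tibble of class `candy_sweep` with columns `size`, `replicate`,
#'   `max_shared`, and the alphabet in an attribute.
#' @examples
#' sw <- run_sweep(sizes = c(5, 20), replicates = 2, n_particles = 40,
#'                 seed = 3)
#' @export
run_sweep <- function(sizes = c(10, 100, 1000, 10000), replicates = 20,
                      n_particles = 94, alphabet = candy_alphabet("A"),
                      pill_radius = 1, particle_radius = NULL,
                      max_attempts = 10000, discard_hull = TRUE,
                      min_distinct_colors = 4, min_neighbors = 2,
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.unsorted(sizes, strictly = TRUE))
    abort("`sizes` must be strictly increasing")
  if (replicates < 1) abort("`replicates` must be >= 1")
  grid <- tidyr_expand(sizes, replicates)
  grid$max_shared <- purrr::map2_int(grid$size, grid$replicate, function(s, r) {
    lib <- simulate_library(s, n_particles = n_particles, alphabet = alphabet,
                            pill_radius = pill_radius,
                            particle_radius = particle_radius,
                            max_attempts = max_attempts,
                            discard_hull = discard_hull,
                            min_distinct_colors = min_distinct_colors,
                            min_neighbors = min_neighbors)
    as.integer(max_shared_in_library(lib))
  })
  attr(grid, "alphabet") <- alphabet
  class(grid) <- c("candy_sweep", class(grid))
  grid
}

# size-major grid so the RNG stream is consumed in a documented order
tidyr_expand <- function(sizes, replicates) {
  tibble(size = rep(as.integer(sizes), each = replicates),
         replicate = rep(seq_len(replicates), times = length(sizes)))
}

#' Summarise a sweep per library size
#'
#' @param sweep a [run_sweep()] result.
#' @return Tibble with `size`, `mean_max_shared`, `sd_max_shared`,
#'   `replicates`.
#' @export
summarise_sweep <- function(sweep) {
  sweep %>%
    group_by(.data$size) %>%
    summarise(mean_max_shared = mean(.data$max_shared),
              sd_max_shared = stats::sd(.data$max_shared),
              replicates = dplyr::n(), .groups = "drop") %>%
    arrange(.data$size)
}

#' Log-linear scaling fit of maximum shared strings
#'
#' Ordinary least squares of the per-size mean maximum shared-string count on
#' `log10(size)`. The slope is the expected growth in worst-case shared
#' strings per tenfold increase of the library; the intercept is the value at
#' size 1. Sizes with fewer than 2 codes have no pairs and are excluded.
#'
#' @param sweep a [run_sweep()] tibble (raw per-replicate rows).
#' @return Object of class `scaling_fit`: list with `slope_per_decade`,
#'   `intercept`, `summary` (per-size means), `residuals` and the underlying
#'   `lm` model. Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' sw <- tibble::tibble(size = rep(c(10, 100, 1000), each = 2),
#'                      replicate = rep(1:2, 3),
#'                      max_shared = c(1, 1, 2, 2, 3, 3))
#' fit_scaling(sw)
#' @export
fit_scaling <- function(sweep) {
  stopifnot(all(c("size", "max_shared") %in% names(sweep)))
  s <- summarise_sweep(sweep) %>% filter(.data$size >= 2)
  if (nrow(s) < 2) abort("need at least 2 usable (size >= 2) library sizes")
  model <- lm(mean_max_shared ~ log10(size), data = s)
  out <- list(
    slope_per_decade = unname(coef(model)[2]),
    intercept = unname(coef(model)[1]),
    summary = s,
    residuals = unname(stats::residuals(model)),
    model = model,
    alphabet_name = attr(attr(sweep, "alphabet"), "alphabet_name") %||% NA
  )
  class(out) <- "scaling_fit"
  out
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf(
    "<scaling_fit: +%.3f shared strings per 10x library size (intercept %.3f)>\n",
    x$slope_per_decade, x$intercept))
  invisible(x)
}

#' @describeIn fit_scaling coefficient table (term, estimate, std.error,
#'   statistic, p.value).
#' @param x a `scaling_fit`.
#' @param ... unused.
#' @export
tidy.scaling_fit <- function(x, ...) {
  sm <- suppressWarnings(summary(x$model))$coefficients
  tibble(term = rownames(sm), estimate = unname(sm[, 1]),
         std.error = unname(sm[, 2]), statistic = unname(sm[, 3]),
         p.value = unname(sm[, 4]))
}

#' @describeIn fit_scaling one-row model summary (r.squared, sigma, nobs).
#' @export
glance.scaling_fit <- function(x, ...) {
  sm <- suppressWarnings(summary(x$model))
  tibble(r.squared = sm$r.squared, adj.r.squared = sm$adj.r.squared,
         sigma = sm$sigma, nobs = nrow(x$summary))
}

#' Extrapolate the scaling law to a target library size
#'
#' Evaluates `intercept + slope_per_decade * log10(target_size)`: the
#' predicted worst-case shared-string count for a library of `target_size`
#' codes. Extrapolating to 1e17 codes (the scale at which version-4 UUID
#' collisions reach 1% probability) is the benchmark for "universally
#' unique".
#'
#' @param fit a [fit_scaling()] object.
#' @param target_size library size (>= 1); may exceed the swept range.
#' @return Predicted maximum shared strings (real, not rounded).
#' @examples
#' f <- structure(list(slope_per_decade = 0.9, intercept = 0),
#'                class = "scaling_fit")
#' extrapolate_shared(f, 1e17) # 15.3
#' @export
extrapolate_shared <- function(fit, target_size) {
  stopifnot(inherits(fit, "scaling_fit"))
  if (any(target_size < 1)) abort("`target_size` must be >= 1")
  fit$intercept + fit$slope_per_decade * log10(target_size)
}
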