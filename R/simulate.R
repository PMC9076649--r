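#' Simulate one pill's particle pattern
#'
#' Particles are modeled as equal circles scattered on a circular pill face by
#' random sequential adsorption (RSA): candidate centers are proposed
#' uniformly over the allowed disk and rejected if they overlap an already
#' placed particle, up to `max_attempts` proposals per particle. Colors are
#' drawn independently from the alphabet's probabilities.
#'
#' The default particle radius `sqrt(0.45 / n_particles) * pill_radius`
#' targets a covered area fraction of 0.45, safely below the RSA jamming
#' limit (~0.547) so packing essentially always succeeds. Configurations with
#' area fraction above 0.55 are rejected up front.
#'
#' All randomness comes from R's global RNG, so `set.seed()` (or the `seed`
#' argument) makes simulations exactly reproducible.
#'
#' @param n_particles number of particles (default 94, the median count on
#'   the commercial candies the model emulates).
#' @param alphabet a [candy_alphabet()] (default `"A"`).
#' @param pill_radius radius of the pill face (default 1; geometry is
#'   unitless).
#' @param particle_radius particle radius (default targets area fraction
#'   0.45).
#' @param max_attempts RSA proposals per particle before giving up (default
#'   10000).
#' @param seed optional integer passed to [set.seed()].
#' @return Tibble of particles (`x`, `y`, `color`) with `pill_radius`,
#'   `particle_radius` and `alphabet` attributes.
#' @examples
#' code <- simulate_candycode(94, seed = 1)
#' nrow(code)
#' @export
simulate_candycode <- function(n_particles = 94,
                               alphabet = candy_alphabet("A"),
                               pill_radius = 1,
                               particle_radius = NULL,
                               max_attempts = 10000,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  particle_radius <- particle_radius %||%
    (sqrt(0.45 / n_particles) * pill_radius)
  check_density(n_particles, pill_radius, particle_radius)
  sim <- .cpp_sim_code(as.integer(n_particles), pill_radius, particle_radius,
                       as.integer(max_attempts), alphabet$prob)
  out <- tibble(x = sim$x, y = sim$y,
                color = alphabet_letters(alphabet)[sim$color])
  attr(out, "pill_radius") <- pill_radius
  attr(out, "particle_radius") <- particle_radius
  attr(out, "alphabet") <- alphabet
  out
}

#' Perturb a particle pattern (re-photograph / wear model)
#'
#' Emulates the differences between two photographs of the same pill, and
#' mechanical wear: each particle's coordinates are displaced by independent
#' zero-mean Gaussian noise of scale `jitter_sigma`, each color is replaced
#' by a uniformly chosen *other* letter with probability `color_error_rate`,
#' and a fraction `drop_fraction` of particles is removed at random.
#'
#' The default jitter, a quarter of the particle radius, was calibrated so
#' that a perturbed copy retains roughly half of its neighborhood strings,
#' bracketing the 40-61% retention observed between real re-photographs.
#' Delaunay neighborhoods are sensitive to the angles between nearby
#' particles, so even small coordinate noise flips some edges.
#'
#' @param particles particle tibble (e.g. from [simulate_candycode()]).
#' @param jitter_sigma Gaussian displacement scale; default
#'   `0.25 * particle_radius` (taken from the input's attribute when
#'   present).
#' @param color_error_rate per-particle probability of a color misreading
#'   (default 0).
#' @param drop_fraction fraction of particles lost (default 0).
#' @param alphabet alphabet used to draw replacement colors; defaults to the
#'   input's attribute.
#' @param seed optional integer passed to [set.seed()].
#' @return A particle tibble of the same shape, attributes carried over.
#' @export
perturb_candycode <- function(particles, jitter_sigma = NULL,
                              color_error_rate = 0, drop_fraction = 0,
                              alphabet = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  particles <- validate_particles(particles)
  alphabet <- alphabet %||% attr(particles, "alphabet")
  r <- attr(particles, "particle_radius")
  jitter_sigma <- jitter_sigma %||% (0.25 * (r %||% abort(
    "no particle_radius attribute: give `jitter_sigma` explicitly")))
  if (jitter_sigma < 0) abort("`jitter_sigma` must be >= 0")
  if (color_error_rate < 0 || color_error_rate > 1)
    abort("`color_error_rate` must be in [0, 1]")
  n <- nrow(particles)
  out <- particles
  out$x <- out$x + rnorm(n, 0, jitter_sigma)
  out$y <- out$y + rnorm(n, 0, jitter_sigma)
  if (color_error_rate > 0) {
    if (is.null(alphabet)) abort("an alphabet is needed for color errors")
    letters <- alphabet_letters(alphabet)
    flip <- runif(n) < color_error_rate
    out$color[flip] <- vapply(out$color[flip], function(cl) {
      sample(setdiff(letters, cl), 1)
    }, character(1))
  }
  if (drop_fraction > 0) {
    keep <- runif(n) >= drop_fraction
    out <- out[keep, , drop = FALSE]
  }
  for (a in c("pill_radius", "particle_radius", "alphabet", "code_id"))
    attr(out, a) <- attr(particles, a)
  out
}

#' Simulate a library of encoded pills
#'
#' Generates `size` independent particle patterns and encodes each with the
#' default filters, mirroring the manufacturing side of the workflow: every
#' pill is photographed once and its canonical string set stored. Codes are
#' labeled `sim_000001`, `sim_000002`, ...
#'
#' @inheritParams simulate_candycode
#' @param size number of codes.
#' @param discard_hull,min_distinct_colors,min_neighbors encoder filters, see
#'   [encode_candycode()].
#' @param keep_particles also return the raw particle tibbles in a
#'   `particles` list-column (default `FALSE`; string sets are all the
#'   database needs).
#' @return Tibble with columns `code_id` and `strings` (list of sorted
#'   character vectors), plus `particles` when requested.
#' @examples
#' lib <- simulate_library(5, n_particles = 40, seed = 2)
#' lengths(lib$strings)
#' @export
simulate_library <- function(size, n_particles = 94,
                             alphabet = candy_alphabet("A"),
                             pill_radius = 1, particle_radius = NULL,
                             max_attempts = 10000, discard_hull = TRUE,
                             min_distinct_colors = 4, min_neighbors = 2,
                             keep_particles = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (size < 1) abort("`size` must be >= 1")
  particle_radius <- particle_radius %||%
    (sqrt(0.45 / n_particles) * pill_radius)
  check_density(n_particles, pill_radius, particle_radius)
  letters <- alphabet_letters(alphabet)
  strings <- vector("list", size)
  parts <- if (keep_particles) vector("list", size)
  for (i in seq_len(size)) {
    sim <- sim_code_retry(n_particles, pill_radius, particle_radius,
                          max_attempts, alphabet$prob)
    cols <- letters[sim$color]
    strings[[i]] <- .cpp_encode(sim$x, sim$y, cols, isTRUE(discard_hull),
                                as.integer(min_distinct_colors),
                                as.integer(min_neighbors))
    if (keep_particles) {
      p <- tibble(x = sim$x, y = sim$y, color = cols)
      attr(p, "pill_radius") <- pill_radius
      attr(p, "particle_radius") <- particle_radius
      attr(p, "alphabet") <- alphabet
      parts[[i]] <- p
    }
  }
  out <- tibble(code_id = sprintf("sim_%06d", seq_len(size)),
                strings = strings)
  if (keep_particles) out$particles <- parts
  attr(out, "alphabet") <- alphabet
  out
}

# At the default area fraction (0.45) a single RSA run very occasionally
# (~1e-5 per code) fails to seat the last particle within max_attempts. When
# generating whole libraries such a configuration is redrawn from scratch:
# conditioning on packability is a negligible perturbation of the ensemble,
# whereas a hard error would abort multi-hundred-thousand-code sweeps.
sim_code_retry <- function(n, R, r, max_attempts, probs, retries = 20) {
  for (k in seq_len(retries)) {
    sim <- tryCatch(
      .cpp_sim_code(as.integer(n), R, r, as.integer(max_attempts), probs),
      error = function(e) NULL
    )
    if (!is.null(sim)) return(sim)
  }
  abort(sprintf(
    "packing failed %d times in a row; the density is infeasible", retries))
}

check_density <- function(n, R, r) {
  if (r >= R) abort("`particle_radius` must be smaller than `pill_radius`")
  phi <- n * r^2 / R^2
  if (phi > 0.55)
    abort(sprintf(
      "requested packing density %.3f exceeds 0.55 (near the RSA jamming limit)",
      phi))
  invisible(phi)
}
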