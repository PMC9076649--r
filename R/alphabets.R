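#' Color alphabets for particle identifiers
#'
#' A color alphabet is the set of single-letter color labels a pill's
#' particles can carry, together with the probability that a manufactured
#' particle has each color. Three built-in alphabets cover the systems studied
#' with this package:
#'
#' * `"A"` — the eight commercial colors, dark blue (D), green (G), light blue
#'   (L), orange (O), pink (P), red (R), white (W) and yellow (Y), with white
#'   five times more probable than each other color (P(W) = 5/12, others 1/12
#'   each). This idealizes the measured composition of commercial
#'   nonpareil-coated candies, where roughly 41.5% of particles are white.
#' * `"B"` — the same eight colors with equal probabilities (1/8).
#' * `"C"` — fifteen equiprobable colors (1/15): the eight above plus black
#'   (K), dark gray (A), light gray (E), dark green (N), magenta (M), purple
#'   (U) and brown (B).
#'
#' @param name one of `"A"`, `"B"`, `"C"`, ignored when `letters` is given.
#' @param letters optional character vector of unique single uppercase letters
#'   (at least two) defining a custom alphabet.
#' @param probs optional numeric vector of sampling probabilities matching
#'   `letters`; defaults to equal probabilities. Must be nonnegative and sum
#'   to 1 (within 1e-9).
#'
#' @return A tibble of class `candy_alphabet` with columns `letter` and
#'   `prob`.
#' @examples
#' candy_alphabet("A")
#' candy_alphabet(letters = c("R", "G", "B"))
#' @export
candy_alphabet <- function(name = c("A", "B", "C"), letters = NULL,
                           probs = NULL) {
  if (is.null(letters)) {
    name <- match.arg(name)
    letters <- switch(name,
      A = ,
      B = c("D", "G", "L", "O", "P", "R", "W", "Y"),
      C = c("A", "B", "D", "E", "G", "K", "L", "M", "N", "O", "P", "R", "U",
            "W", "Y")
    )
    probs <- switch(name,
      A = ifelse(letters == "W", 5 / 12, 1 / 12),
      B = rep(1 / 8, 8),
      C = rep(1 / 15, 15)
    )
  } else {
    name <- "custom"
    if (is.null(probs)) probs <- rep(1 / length(letters), length(letters))
  }
  letters <- as.character(letters)
  if (length(letters) < 2) abort("an alphabet needs at least 2 letters")
  if (anyDuplicated(letters)) abort("alphabet letters must be unique")
  if (any(nchar(letters) != 1) || any(letters != toupper(letters)))
    abort("alphabet letters must be single uppercase characters")
  if (length(probs) != length(letters))
    abort("`probs` must have one entry per letter")
  if (any(probs < 0)) abort("probabilities must be nonnegative")
  if (abs(sum(probs) - 1) > 1e-9) abort("probabilities must sum to 1")
  out <- tibble(letter = letters, prob = as.numeric(probs))
  class(out) <- c("candy_alphabet", class(out))
  attr(out, "alphabet_name") <- name
  out
}

#' Theoretical information content of a particle pattern
#'
#' If every one of `n_particles` particles independently took one of
#' `n_colors` colors, the pattern could encode `n_particles * log2(n_colors)`
#' bits. A typical 93-particle, 8-color pill could in principle carry 279
#' bits, more than double the 122 random bits of a version-4 UUID. The
#' neighborhood-string encoding actually used for matching retains much less
#' than this, by design: it trades capacity for robustness to re-photography.
#'
#' @param n_particles number of particles (>= 0).
#' @param n_colors number of distinct colors (>= 1).
#' @return Number of bits (unrounded).
#' @examples
#' theoretical_bits(93, 8)
#' @export
theoretical_bits <- function(n_particles, n_colors) {
  if (n_particles < 0) abort("`n_particles` must be >= 0")
  if (n_colors < 1) abort("`n_colors` must be >= 1")
  n_particles * log2(n_colors)
}

# letters of an alphabet (helper used throughout)
alphabet_letters <- function(alphabet) {
  stopifnot(inherits(alphabet, "candy_alphabet"))
  alphabet$letter
}
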