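#' Read a particle list from CSV or JSON
#'
#' Particle lists are tables of `(x, y, color)` records in image coordinates
#' (y increases downward, as in a photograph). Two dialects are supported:
#' a CSV file with header `x,y,color`, and a JSON document
#' `{"id": ..., "particles": [[x, y, "P"], ...]}` (chosen by the `.json` file
#' extension).
#'
#' @param path file to read.
#' @param alphabet a [candy_alphabet()]; every color letter in the file must
#'   belong to it.
#' @return A tibble with columns `x`, `y`, `color` (the particles in file
#'   order), with the code id (JSON `id` field, or the file stem) in the
#'   `"code_id"` attribute.
#' @seealso [write_candycode()]
#' @export
read_candycode <- function(path, alphabet = candy_alphabet("A")) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (is.null(doc$particles)) abort("JSON document has no `particles` field")
    particles <- tibble(
      x = vapply(doc$particles, function(p) as.numeric(p[[1]]), numeric(1)),
      y = vapply(doc$particles, function(p) as.numeric(p[[2]]), numeric(1)),
      color = vapply(doc$particles, function(p) as.character(p[[3]]),
                     character(1))
    )
    id <- if (!is.null(doc$id)) as.character(doc$id) else file_stem(path)
  } else {
    df <- read.csv(path, colClasses = c("numeric", "numeric", "character"),
                   strip.white = TRUE)
    if (!all(c("x", "y", "color") %in% names(df)))
      abort("CSV must have columns x, y, color")
    particles <- as_tibble(df[, c("x", "y", "color")])
    id <- file_stem(path)
  }
  particles <- validate_particles(particles, alphabet)
  attr(particles, "code_id") <- id
  particles
}

#' Write a particle list to CSV or JSON
#'
#' Coordinates are serialized with 6 fractional digits, which is lossless for
#' pixel-level data; [read_candycode()] of the written file reproduces the
#' particles exactly at that precision.
#'
#' @param particles data frame with columns `x`, `y`, `color`.
#' @param path output file; a `.json` extension selects the JSON dialect.
#' @param id code identifier stored in the JSON dialect (defaults to the
#'   `"code_id"` attribute, or the file stem).
#' @return `path`, invisibly.
#' @export
write_candycode <- function(particles, path, id = NULL) {
  stopifnot(all(c("x", "y", "color") %in% names(particles)))
  if (is.null(id)) id <- attr(particles, "code_id") %||% file_stem(path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    doc <- list(
      id = id,
      particles = purrr::pmap(particles[, c("x", "y", "color")],
                              function(x, y, color) {
                                list(round6(x), round6(y), color)
                              })
    )
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  } else {
    out <- data.frame(
      x = sprintf("%.6f", particles$x),
      y = sprintf("%.6f", particles$y),
      color = particles$color
    )
    write.csv(out, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read / write string-set libraries
#'
#' A string-set file holds one code per line: the code id followed by its
#' whitespace-separated neighborhood strings, sorted lexicographically so that
#' files diff reproducibly. This is the on-disk form of both simulated
#' libraries and known-good databases.
#'
#' @param path file to read or write.
#' @return `read_string_sets()` returns a tibble with columns `code_id`
#'   (character) and `strings` (list of character vectors). A line with only
#'   an id yields an empty string set.
#' @export
read_string_sets <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  tibble(
    code_id = vapply(parts, `[[`, character(1), 1),
    strings = purrr::map(parts, function(p) sort(p[-1]))
  )
}

#' @rdname read_string_sets
#' @param library tibble with columns `code_id` and `strings` (list-column of
#'   character vectors), as produced by [simulate_library()].
#' @export
write_string_sets <- function(library, path) {
  stopifnot(all(c("code_id", "strings") %in% names(library)))
  lines <- purrr::map2_chr(library$code_id, library$strings, function(id, s) {
    paste(c(id, sort(s)), collapse = " ")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Validate a particle table
#'
#' Checks the contract every encoder-facing function relies on: columns `x`,
#' `y`, `color`; finite coordinates; colors drawn from the alphabet; no two
#' particles at identical coordinates (exact equality, appropriate for
#' pixel-precision data).
#'
#' @inheritParams read_candycode
#' @param particles data frame of particles.
#' @return The particles as a tibble, invisibly validated.
#' @export
validate_particles <- function(particles, alphabet = NULL) {
  if (!all(c("x", "y", "color") %in% names(particles)))
    abort("particles must have columns x, y, color")
  particles <- as_tibble(particles)
  if (!is.numeric(particles$x) || !is.numeric(particles$y))
    abort("x and y must be numeric")
  if (any(!is.finite(particles$x)) || any(!is.finite(particles$y)))
    abort("coordinates must be finite")
  if (!is.null(alphabet)) {
    ok <- particles$color %in% alphabet_letters(alphabet)
    if (!all(ok))
      abort(sprintf("unknown color letter '%s' in row %d",
                    particles$color[which(!ok)[1]], which(!ok)[1]))
  }
  dup <- duplicated(paste(particles$x, particles$y, sep = ","))
  if (any(dup))
    abort(sprintf("duplicate particle coordinates in row %d", which(dup)[1]))
  particles
}

file_stem <- function(path) sub("\\.[^.]*$", "", basename(path))

round6 <- function(x) as.numeric(sprintf("%.6f", x))

`%||%` <- function(a, b) if (is.null(a)) b else a
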