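#' End-to-end authentication demo
#'
#' Walks the full workflow on synthetic data: a manufacturer simulates
#' `n_codes` pills and stores their canonical string sets in a database; a
#' consumer re-photographs one genuine pill (modeled by coordinate jitter,
#' rendering and re-detection of the image) and queries it, which should come
#' back `"authentic"` with a large margin; a second consumer holds a
#' counterfeit pill (a fresh random pattern), whose query should come back
#' `"not_authentic"` with at most a couple of coincidentally shared strings.
#'
#' @inheritParams simulate_library
#' @param n_codes number of manufactured pills (default 120).
#' @param genuine_index which pill the genuine consumer holds (default 7).
#' @param threshold verdict threshold, see [db_query()].
#' @param pixels_per_unit render scale for the consumer photo.
#' @param out_dir optional directory; when given, the database
#'   (`known_good.txt`), the consumer photo (`suspect.png`) and a JSON
#'   summary (`report.json`) are written there.
#' @return A list of class `candy_demo` with the two [db_query()] reports
#'   (`genuine`, `counterfeit`) and the run parameters.
#' @examples
#' demo <- demo_end_to_end(n_codes = 20, n_particles = 40, seed = 11)
#' demo$genuine$verdict
#' @export
demo_end_to_end <- function(n_codes = 120, n_particles = 94,
                            alphabet = candy_alphabet("A"), seed = NULL,
                            genuine_index = 7, threshold = 10,
                            pixels_per_unit = 200, out_dir = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genuine_index <- min(genuine_index, n_codes)
  lib <- simulate_library(n_codes, n_particles = n_particles,
                          alphabet = alphabet, keep_particles = TRUE)
  db <- candy_db(lib[, c("code_id", "strings")])
  palette <- candy_palette(alphabet)

  # consumer 1: genuine pill, new photo = jitter + render + re-detect
  genuine <- perturb_candycode(lib$particles[[genuine_index]])
  photo <- render_candycode(genuine, palette,
                            pixels_per_unit = pixels_per_unit)
  seen <- detect_particles(photo, palette, alphabet)
  suspect_strings <- encode_candycode(seen)
  genuine_report <- db_query(db, suspect_strings, threshold = threshold,
                             suspect_id = lib$code_id[genuine_index])

  # consumer 2: counterfeit pill never entered in the database
  fake <- simulate_candycode(n_particles, alphabet = alphabet)
  fake_report <- db_query(db, encode_candycode(fake), threshold = threshold,
                          suspect_id = "counterfeit")

  out <- list(genuine = genuine_report, counterfeit = fake_report,
              n_codes = n_codes, n_particles = n_particles,
              threshold = threshold,
              alphabet_name = attr(alphabet, "alphabet_name"))
  class(out) <- "candy_demo"
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_db(db, file.path(out_dir, "known_good.txt"))
    png::writePNG(photo, file.path(out_dir, "suspect.png"))
    jsonlite::write_json(
      list(genuine = unclass(genuine_report)[
             c("suspect_id", "best_id", "best_shared", "runner_up_shared",
               "verdict")],
           counterfeit = unclass(fake_report)[
             c("suspect_id", "best_id", "best_shared", "runner_up_shared",
               "verdict")]),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.candy_demo <- function(x, ...) {
  cat(sprintf("End-to-end demo: %d codes, %d particles, alphabet %s\n",
              x$n_codes, x$n_particles, x$alphabet_name))
  cat("-- consumer with a genuine pill --\n")
  print(x$genuine)
  cat("-- consumer with a counterfeit pill --\n")
  print(x$counterfeit)
  invisible(x)
}
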