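#' Database of known-good string sets
#'
#' A `candy_db` stores the canonical string sets of manufactured pills, keyed
#' by code id. Matching a suspect against the database uses shared-string
#' counts (multiset intersections) computed through an inverted index, so only
#' codes that share at least one string with the suspect cost any work.
#'
#' @param library optional tibble with columns `code_id` and `strings`
#'   (list-column of character vectors), e.g. from [simulate_library()] or
#'   [read_string_sets()].
#' @return An object of class `candy_db`.
#' @examples
#' set.seed(7)
#' db <- candy_db(simulate_library(5, n_particles = 40))
#' db
#' @export
candy_db <- function(library = NULL) {
  db <- list(entries = list())
  class(db) <- "candy_db"
  if (!is.null(library)) {
    stopifnot(all(c("code_id", "strings") %in% names(library)))
    if (anyDuplicated(library$code_id))
      abort("duplicate code_id in library")
    db$entries <- setNames(purrr::map(library$strings, sort),
                           library$code_id)
  }
  db
}

#' @export
print.candy_db <- function(x, ...) {
  ns <- lengths(x$entries)
  cat(sprintf("<candy_db: %d codes, %s strings total>\n", length(ns),
              format(sum(ns), big.mark = ",")))
  invisible(x)
}

#' @rdname candy_db
#' @param db a `candy_db`.
#' @param strings character vector: one code's string multiset.
#' @param code_id identifier for the new code (defaults to the vector's
#'   `"code_id"` attribute).
#' @export
db_add <- function(db, strings, code_id = NULL) {
  stopifnot(inherits(db, "candy_db"))
  code_id <- code_id %||% attr(strings, "code_id")
  if (is.null(code_id)) abort("`code_id` is required")
  if (code_id %in% names(db$entries))
    abort(sprintf("code_id '%s' already present", code_id))
  db$entries[[code_id]] <- sort(as.character(strings))
  db
}

#' Shared strings between two string multisets
#'
#' The match statistic: the multiset intersection cardinality, i.e. the sum
#' over distinct strings of the smaller of the two multiplicities. Symmetric;
#' `count_shared(a, a)` equals `length(a)`.
#'
#' @param a,b character vectors of neighborhood strings.
#' @return Integer count of shared strings.
#' @examples
#' count_shared(c("X", "X", "Y"), c("X", "Z")) # 1
#' @export
count_shared <- function(a, b) {
  ta <- table(a)
  tb <- table(b)
  common <- intersect(names(ta), names(tb))
  if (length(common) == 0) return(0L)
  as.integer(sum(pmin(ta[common], tb[common])))
}

#' Match a suspect string set against the database
#'
#' Computes the shared-string count between the suspect and every stored
#' code, and issues a verdict: `"authentic"` when the best match shares at
#' least `threshold` strings, `"not_authentic"` otherwise. In practice the
#' separation is dramatic: re-photographs of a genuine pill shared 21-32
#' strings with their database entry while the best impostor shared at most
#' 2, so the default threshold of 10 sits between the two regimes with a wide
#' margin on both sides.
#'
#' Ties for the best match are broken by lexicographic code id and recorded in
#' the report's `tied` field.
#'
#' @param db a [candy_db()].
#' @param suspect character vector of the suspect's strings.
#' @param threshold minimum shared strings for an `"authentic"` verdict
#'   (default 10).
#' @param suspect_id optional label for the report.
#' @return A `candy_match` report: a list with `suspect_id`, `best_id`,
#'   `best_shared`, `runner_up_shared`, `tied`, `verdict`, `threshold` and
#'   `histogram` (tibble of shared-count vs number of database codes; its
#'   counts total the database size).
#' @export
db_query <- function(db, suspect, threshold = 10, suspect_id = NULL) {
  stopifnot(inherits(db, "candy_db"))
  if (length(db$entries) == 0) abort("database is empty")
  suspect_id <- suspect_id %||% attr(suspect, "code_id") %||% "suspect"
  ids <- names(db$entries)
  shared <- .cpp_query(unname(db$entries), as.character(suspect))
  ord <- order(-shared, ids)
  best <- ord[1]
  best_shared <- shared[best]
  tied <- ids[shared == best_shared]
  runner_up <- if (length(ids) > 1) shared[ord[2]] else 0L
  tb <- table(shared)
  hist <- tibble(shared = as.integer(names(tb)), codes = as.integer(tb))
  out <- list(
    suspect_id = suspect_id,
    best_id = if (length(ids)) ids[best] else NA_character_,
    best_shared = as.integer(best_shared),
    runner_up_shared = as.integer(runner_up),
    tied = if (length(tied) > 1) tied else character(0),
    verdict = if (best_shared >= threshold) "authentic" else "not_authentic",
    threshold = threshold,
    histogram = hist
  )
  class(out) <- "candy_match"
  out
}

#' @export
print.candy_match <- function(x, ...) {
  cat(sprintf("Suspect '%s': %s\n", x$suspect_id, x$verdict))
  cat(sprintf("  best match %s with %d shared strings (runner-up %d, threshold %g)\n",
              x$best_id, x$best_shared, x$runner_up_shared, x$threshold))
  if (length(x$tied))
    cat("  tie among:", paste(x$tied, collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn db_query tidy the match report into the shared-count histogram
#'   (one row per distinct shared count, with the number of database codes).
#' @param x a `candy_match`.
#' @param ... unused.
#' @export
tidy.candy_match <- function(x, ...) x$histogram

#' Shared-string histogram over all pairs of database codes
#'
#' Counts, for every unordered pair of distinct codes, how many strings the
#' two codes share, and tabulates the result. A 120-code library has
#' `choose(120, 2) = 7140` pairs; in a well-behaved library the vast majority
#' share 0 strings and almost all of the rest share exactly 1.
#'
#' @param db a [candy_db()] with at least 2 codes.
#' @return Tibble with columns `shared` and `pairs`; `sum(pairs)` equals
#'   `choose(n, 2)`.
#' @export
pairwise_stats <- function(db) {
  stopifnot(inherits(db, "candy_db"))
  if (length(db$entries) < 2) abort("need at least 2 codes")
  h <- .cpp_pair_hist(unname(db$entries))
  tibble(shared = seq_along(h) - 1L, pairs = h) %>%
    filter(.data$pairs > 0 | .data$shared == 0)
}

#' @rdname read_string_sets
#' @param db a [candy_db()].
#' @export
write_db <- function(db, path) {
  stopifnot(inherits(db, "candy_db"))
  write_string_sets(tibble(code_id = names(db$entries),
                           strings = unname(db$entries)), path)
}

#' @rdname read_string_sets
#' @export
read_db <- function(path) candy_db(read_string_sets(path))
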