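test_that("shared-string counting follows multiset-intersection rules", {
  a <- rep("S", 0)
  set.seed(601)
  s53 <- replicate(53, paste(sample(LETTERS[1:8], 6, TRUE), collapse = ""))
  expect_equal(count_shared(s53, s53), 53)
  expect_equal(count_shared(c("AB", "CD"), c("EF", "GH")), 0)
  expect_equal(count_shared(c("X", "X", "Y"), c("X", "Z", "Z", "Z", "Z")), 1)
  expect_equal(count_shared(c("X", "X", "Y"), c("X", "Z")),
               count_shared(c("X", "Z"), c("X", "X", "Y")))
})

test_that("adding and querying a code finds it with full overlap", {
  set.seed(602)
  lib <- simulate_library(3, n_particles = 50)
  db <- candy_db()
  for (i in 1:3) db <- db_add(db, lib$strings[[i]], lib$code_id[i])
  rep <- db_query(db, lib$strings[[2]], threshold = 10)
  expect_equal(rep$best_id, "sim_000002")
  expect_equal(rep$best_shared, length(lib$strings[[2]]))
  expect_equal(rep$verdict, "authentic")
  expect_error(db_add(db, lib$strings[[1]], "sim_000001"), "already present")
})

test_that("a suspect with no overlap is rejected", {
  db <- candy_db(tibble::tibble(code_id = c("a", "b"),
                                strings = list(c("WGLD"), c("PDGR"))))
  rep <- db_query(db, c("YYyy", "ZZzz"), threshold = 10)
  expect_equal(rep$best_shared, 0L)
  expect_equal(rep$verdict, "not_authentic")
  expect_equal(sum(rep$histogram$codes), 2)
  expect_error(db_query(candy_db(), c("X")), "empty")
})

test_that("ties for the best match are reported", {
  db <- candy_db(tibble::tibble(code_id = c("b", "a"),
                                strings = list(c("WGLD", "PDGR"),
                                               c("WGLD", "PDGR"))))
  rep <- db_query(db, c("WGLD"), threshold = 1)
  expect_equal(rep$best_id, "a")  # lexicographic tie-break
  expect_setequal(rep$tied, c("a", "b"))
})

test_that("inverted-index query equals naive per-code counting", {
  set.seed(603)
  pool <- replicate(30, paste(sample(LETTERS[1:6], 5, TRUE), collapse = ""))
  lib <- tibble::tibble(
    code_id = sprintf("c%03d", 1:80),
    strings = purrr::map(1:80, ~ sample(pool, sample(3:12, 1),
                                        replace = TRUE))
  )
  db <- candy_db(lib)
  suspect <- sample(pool, 8, replace = TRUE)
  rep <- db_query(db, suspect, threshold = 5)
  naive <- vapply(lib$strings, count_shared, integer(1), b = suspect)
  expect_equal(rep$best_shared, max(naive))
  expect_equal(rep$best_id, lib$code_id[order(-naive, lib$code_id)[1]])
  hist_naive <- table(naive)
  expect_equal(rep$histogram$codes,
               as.integer(hist_naive))
  expect_equal(rep$histogram$shared, as.integer(names(hist_naive)))
})

test_that("pairwise statistics cover every unordered pair", {
  lib <- tibble::tibble(code_id = c("a", "b"),
                        strings = list(rep("WXYZ", 7), rep("WXYZ", 7)))
  ps <- pairwise_stats(candy_db(lib))
  expect_equal(ps$pairs[ps$shared == 7], 1)
  disjoint <- tibble::tibble(code_id = c("a", "b", "c"),
                             strings = list("AB", "CD", "EF"))
  ps3 <- pairwise_stats(candy_db(disjoint))
  expect_equal(ps3, tibble::tibble(shared = 0L, pairs = 3))
})

test_that("pairwise histogram matches naive counting on a mixed library", {
  set.seed(604)
  pool <- replicate(25, paste(sample(LETTERS[1:5], 5, TRUE), collapse = ""))
  strings <- purrr::map(1:40, ~ sample(pool, sample(2:10, 1), replace = TRUE))
  ps <- pairwise_stats(candy_db(tibble::tibble(
    code_id = sprintf("c%02d", 1:40), strings = strings)))
  naive <- integer(0)
  for (i in 1:39) for (j in (i + 1):40) {
    naive <- c(naive, count_shared(strings[[i]], strings[[j]]))
  }
  expect_equal(sum(ps$pairs), choose(40, 2))
  for (k in ps$shared) {
    expect_equal(ps$pairs[ps$shared == k], sum(naive == k))
  }
})

test_that("a perturbed library member beats every impostor clearly", {
  set.seed(605)
  lib <- simulate_library(120, keep_particles = TRUE)
  db <- candy_db(lib[, c("code_id", "strings")])
  suspect <- encode_candycode(perturb_candycode(lib$particles[[7]]))
  rep <- db_query(db, suspect, threshold = 10)
  expect_equal(rep$best_id, "sim_000007")
  expect_equal(rep$verdict, "authentic")
  expect_gt(rep$best_shared, rep$runner_up_shared)
  expect_lte(rep$runner_up_shared, 3)
})
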