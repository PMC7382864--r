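# minimal cohort fixture for query-level tests
mini_cohort <- function() {
  data.frame(
    person_id = paste0("P", 1:5),
    family_id = paste0("F", c(1, 1, 2, 3, 3)),
    name = c("MARIA DA SILVA", "MARIA SOUZA", "ANA MARIA LIMA",
             "JOANA PRADO", "MARIA DA SILVA"),
    dob = c("1980-01-01", "1985-05-05", "1990-09-09", "1975-03-03", NA),
    sex = c("F", "F", "F", "F", "F"),
    municipality = c("2900001", "2900001", "2900002", "3500001", "2900001"),
    state = c("29", "29", "29", "35", "29"),
    stringsAsFactors = FALSE
  )
}

test_that("index postings cover every non-missing field once, sorted", {
  idx <- build_index(mini_cohort())
  expect_identical(get("MARIA", idx$postings$name_token), c(1L, 2L, 3L, 5L))
  expect_identical(get("MARIA DA SILVA", idx$postings$name_full), c(1L, 5L))
  # record 5 has no DOB: absent from DOB postings only
  expect_false(any(vapply(ls(idx$postings$dob),
    function(k) 5L %in% get(k, idx$postings$dob), logical(1))))
  expect_identical(get("2900001", idx$postings$municipality), c(1L, 2L, 5L))
  expect_error(build_index(rbind(mini_cohort(), mini_cohort()[1, ])),
               "duplicate")
})

test_that("empty cohort builds an empty index with empty query results", {
  idx <- build_index(mini_cohort()[0, ])
  probe <- list(name = "MARIA", municipality = "2900001", dob = "1980-01-01")
  expect_length(query_exact(idx, probe), 0)
  expect_length(query_semi_fuzzy(idx, probe), 0)
  expect_identical(nrow(retrieve_candidates(idx, probe)), 0L)
})

test_that("exact tier intersects all supplied attributes", {
  idx <- build_index(mini_cohort())
  expect_identical(
    query_exact(idx, list(name = "MARIA SOUZA", municipality = "2900001",
                          dob = "1985-05-05")), 2L)
  # name matches but municipality differs everywhere
  expect_length(
    query_exact(idx, list(name = "MARIA SOUZA", municipality = "3500001")), 0)
  # duplicated attribute records both return
  expect_identical(
    query_exact(idx, list(name = "MARIA DA SILVA", municipality = "2900001")),
    c(1L, 5L))
})

test_that("semi-fuzzy tier is exactly the leave-one-out set", {
  idx <- build_index(mini_cohort())
  # agrees on name + DOB, municipality differs: semi-fuzzy, not exact
  probe <- list(name = "MARIA SOUZA", municipality = "2900002",
                dob = "1985-05-05")
  expect_false(2L %in% query_exact(idx, probe))
  expect_true(2L %in% query_semi_fuzzy(idx, probe))
  # agreeing on municipality only (two attributes differ): not returned
  probe2 <- list(name = "JOANA PRADO", municipality = "2900001",
                 dob = "1999-01-01")
  expect_false(1L %in% query_semi_fuzzy(idx, probe2))
  # fewer than two supplied attributes: empty by construction
  expect_length(query_semi_fuzzy(idx, list(name = "MARIA SOUZA",
                                           municipality = NA)), 0)
})

test_that("semi-fuzzy candidates disagree on exactly one supplied attribute", {
  pop <- tiny_population()
  idx <- build_index(pop$cohort)
  set.seed(31)
  for (b in sample(nrow(pop$births), 20)) {
    birth <- pop$births[b, ]
    probe <- list(name = birth$mother_name, municipality = birth$municipality,
                  dob = birth$mother_dob)
    for (r in query_semi_fuzzy(idx, probe)) {
      rec <- pop$cohort[r, ]
      agree <- c(rec$name == birth$mother_name,
                 rec$municipality == birth$municipality,
                 !is.na(rec$dob) && rec$dob == birth$mother_dob)
      expect_identical(sum(!agree), 1L)
    }
    for (r in query_exact(idx, probe)) {
      rec <- pop$cohort[r, ]
      expect_true(rec$name == birth$mother_name &&
                  rec$municipality == birth$municipality &&
                  (!is.na(rec$dob) && rec$dob == birth$mother_dob))
    }
  }
})

test_that("fuzzy tier requires a shared token and applies the DL floor", {
  idx <- build_index(mini_cohort())
  fz <- query_fuzzy(idx, list(name = "MARIA DE SILVA",
                              municipality = "2900001"))
  expect_true(1L %in% fz$row)
  expect_equal(fz$dl_sim[fz$row == 1L], 1 - 1 / 14, tolerance = 1e-12)
  # zero shared tokens: never retrieved
  expect_false(4L %in% fz$row)
  # dl_floor = 1 keeps only identical names
  strict <- query_fuzzy(idx, list(name = "MARIA DA SILVA",
                                  municipality = "2900001"), dl_floor = 1)
  expect_identical(sort(strict$row), integer(0))
  loose <- query_fuzzy(idx, list(name = "MARIA DA SILVA",
                                 municipality = "2900001"), dl_floor = 0.99)
  expect_identical(sort(loose$row), c(1L, 5L))
})

test_that("retrieval concatenates tiers, dedups to the highest, truncates to k", {
  idx <- build_index(mini_cohort())
  probe <- list(name = "MARIA DA SILVA", municipality = "2900001")
  cand <- retrieve_candidates(idx, probe, k = 1000L)
  expect_identical(cand$tier[cand$row == 1L], "exact")
  expect_identical(anyDuplicated(cand$row), 0L)
  expect_identical(cand$row[1], 1L)
  one <- retrieve_candidates(idx, probe, k = 1L)
  expect_identical(nrow(one), 1L)
  expect_identical(one$row, 1L)
  expect_error(retrieve_candidates(idx, probe, k = 0L), "k")
})

test_that("k >= cohort size with dl_floor 0 recovers every token-sharer", {
  pop <- tiny_population()
  idx <- build_index(pop$cohort)
  toks_by_rec <- name_tokens(pop$cohort$name)
  for (b in c(1L, 7L, 19L)) {
    birth <- pop$births[b, ]
    probe <- list(name = birth$mother_name, municipality = birth$municipality,
                  dob = birth$mother_dob)
    cand <- retrieve_candidates(idx, probe, k = nrow(pop$cohort),
                                dl_floor = 0)
    ptoks <- name_tokens(birth$mother_name)[[1]]
    sharers <- which(vapply(toks_by_rec,
                            function(t) any(t %in% ptoks), logical(1)))
    expect_setequal(cand$row, union(sharers, query_exact(idx, probe)))
  }
})

test_that("retrieval is deterministic and finds every clean true mother", {
  pop <- tiny_population()
  idx <- build_index(pop$cohort)
  t <- pop$truth[!is.na(pop$truth$true_person_id), ]
  found <- vapply(seq_len(nrow(t)), function(i) {
    b <- pop$births[match(t$birth_id[i], pop$births$birth_id), ]
    cand <- retrieve_candidates(idx, list(name = b$mother_name,
                                          municipality = b$municipality,
                                          dob = b$mother_dob))
    t$true_person_id[i] %in% pop$cohort$person_id[cand$row]
  }, logical(1))
  expect_true(all(found))
  b1 <- pop$births[1, ]
  probe <- list(name = b1$mother_name, municipality = b1$municipality,
                dob = b1$mother_dob)
  expect_identical(retrieve_candidates(idx, probe),
                   retrieve_candidates(idx, probe))
})

test_that("index round-trips through its on-disk layout", {
  pop <- tiny_population()
  idx <- build_index(pop$cohort)
  path <- withr::local_tempfile(fileext = ".idx")
  write_index(idx, path)
  expect_match(readLines(path, n = 1), "^birthlink-index v1")
  back <- read_index(path, pop$cohort)
  probe <- list(name = pop$births$mother_name[1],
                municipality = pop$births$municipality[1],
                dob = pop$births$mother_dob[1])
  expect_identical(retrieve_candidates(back, probe),
                   retrieve_candidates(idx, probe))
  expect_error(read_index(path, pop$cohort[-1, ]), "records")
})
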