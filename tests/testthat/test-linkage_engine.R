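cand_frame <- function(name, dob, muni = "2900001", state = "29") {
  data.frame(person_id = paste0("P", seq_along(name)), name = name, dob = dob,
             municipality = muni, state = state, stringsAsFactors = FALSE)
}

birth_row <- function(name, mother_dob = NA_character_, age = NA_integer_,
                      child_dob = "2012-06-15", muni = "2900001",
                      state = "29") {
  data.frame(birth_id = "B1", child_dob = child_dob, child_sex = "F",
             mother_name = name, mother_age = age, mother_dob = mother_dob,
             municipality = muni, state = state, stringsAsFactors = FALSE)
}

test_that("maternal age uses completed calendar years", {
  expect_identical(derive_maternal_age("2005-06-15", "1980-06-14"), 25L)
  expect_identical(derive_maternal_age("2005-06-15", "1980-06-16"), 24L)
  expect_identical(derive_maternal_age("2005-06-15", "1980-06-15"), 25L)
  expect_error(derive_maternal_age("2005-06-15", "2005-06-15"), "impossible")
  expect_error(derive_maternal_age("2005-06-15", "2006-01-01"), "impossible")
})

test_that("age consistency keeps exact agreement only, unless age is missing", {
  dobs <- c("1987-06-14", "1987-06-16", "1990-01-01")
  keep <- age_consistency_filter(dobs, "2012-06-15", 25L)
  expect_identical(keep, c(TRUE, FALSE, FALSE))
  expect_identical(age_consistency_filter(dobs, "2012-06-15", NA),
                   c(TRUE, TRUE, TRUE))
})

test_that("combined score is the weight-normalized mean over available attributes", {
  w <- default_weights()
  expect_identical(unname(w), c(1, 1, 0.16, 0.008))
  # all four attributes equal -> 1
  b <- birth_row("MARIA DA SILVA", mother_dob = "1985-02-03")
  cand <- cand_frame("MARIA DA SILVA", "1985-02-03")
  expect_equal(score_pairs(b, cand)$score, 1)
  # known name similarity, everything else equal
  b2 <- birth_row("MARTHA", mother_dob = "1985-02-03")
  cand2 <- cand_frame("MARHTA", "1985-02-03")
  jw <- jaro_winkler("MARTHA", "MARHTA")
  expect_equal(score_pairs(b2, cand2)$score,
               (jw * 1 + 1 + 0.16 + 0.008) / 2.168, tolerance = 1e-12)
  # stated worked example: sims 0.9 / 1 / 1 / 1
  expect_equal((0.9 + 1 + 0.16 + 0.008) / 2.168, 0.95387, tolerance = 1e-4)
  # only the name comparable -> score equals the name similarity
  b3 <- birth_row("MARTHA", muni = NA_character_, state = NA_character_)
  cand3 <- cand_frame("MARHTA", NA_character_, muni = NA_character_,
                      state = NA_character_)
  expect_equal(score_pairs(b3, cand3)$score, jw)
})

test_that("age route contributes 1 after the gate; missing age drops the attribute", {
  cand <- cand_frame("MARIA DA SILVA", "1987-06-14")
  b <- birth_row("MARIA DA SILVA", age = 25L)
  expect_equal(score_pairs(b, cand)$score, 1)
  b_na <- birth_row("MARIA DA SILVA")
  expect_equal(score_pairs(b_na, cand)$score, 1)  # renormalized without age
  expect_true(is.na(score_pairs(b_na, cand)$sim_dob_age))
})

test_that("era mode 'age' ignores an available mother DOB", {
  b <- birth_row("MARIA DA SILVA", mother_dob = "1987-06-14", age = 25L)
  cand <- cand_frame("MARIA DA SILVA", c("1987-06-14", "1987-01-01"))
  dob_route <- score_pairs(b, cand, era = "dob")
  age_route <- score_pairs(b, cand, era = "age")
  expect_lt(dob_route$score[2], dob_route$score[1])
  expect_equal(age_route$score, c(1, 1))  # gate is the caller's job here
})

test_that("corrupting one attribute never raises the combined score", {
  b <- birth_row("MARIA DA SILVA", mother_dob = "1985-02-03")
  base <- cand_frame("MARIA DA SILVA", "1985-02-03")
  worse <- list(
    cand_frame("MARIA DE SILVA", "1985-02-03"),
    cand_frame("MARIA DA SILVA", "1985-02-04"),
    cand_frame("MARIA DA SILVA", "1985-02-03", muni = "2900002"),
    cand_frame("MARIA DA SILVA", "1985-02-03", state = "35")
  )
  s0 <- score_pairs(b, base)$score
  for (w in worse) expect_lte(score_pairs(b, w)$score, s0)
})

test_that("greedy assignment resolves conflicts globally and deterministically", {
  pairs <- data.frame(
    birth_id = c("B1", "B1", "B2", "B2"),
    person_id = c("P1", "P2", "P1", "P3"),
    score = c(0.99, 0.80, 0.95, 0.70),
    stringsAsFactors = FALSE
  )
  a <- assign_best_links(pairs)
  expect_identical(a$cohort_id[a$birth_id == "B1"], "P1")
  # B2 loses P1 and falls to its next-best available candidate
  expect_identical(a$cohort_id[a$birth_id == "B2"], "P3")

  # equal scores competing for one candidate: smaller birth id wins
  tie <- data.frame(birth_id = c("B2", "B1"), person_id = c("P1", "P1"),
                    score = c(0.9, 0.9), stringsAsFactors = FALSE)
  at <- assign_best_links(tie)
  expect_identical(at$cohort_id[at$birth_id == "B1"], "P1")
  expect_true(is.na(at$cohort_id[at$birth_id == "B2"]))

  # input row order never matters
  set.seed(8)
  perm <- sample(nrow(pairs))
  expect_identical(assign_best_links(pairs[perm, ]), a)

  # disjoint candidate sets: everyone keeps their top candidate
  dis <- data.frame(birth_id = c("B1", "B2"), person_id = c("P1", "P2"),
                    score = c(0.5, 0.6), stringsAsFactors = FALSE)
  ad <- assign_best_links(dis)
  expect_identical(ad$cohort_id, c("P1", "P2"))
})

test_that("no cohort id is ever assigned twice", {
  pop <- generate_population(generator_config(n_cohort = 250L,
                                              n_births = 150L, seed = 21L))
  res <- link_records(pop$births, build_index(pop$cohort))
  ids <- res$assignments$cohort_id
  expect_identical(anyDuplicated(ids[!is.na(ids)]), 0L)
  expect_setequal(res$assignments$birth_id, pop$births$birth_id)
})

test_that("offspring search returns the unique family member, flags twins", {
  cohort <- data.frame(
    person_id = paste0("P", 1:5),
    family_id = c("F1", "F1", "F1", "F2", "F2"),
    name = c("MARIA SILVA", "JOAO SILVA", "ANA SILVA", "RITA LIMA",
             "CLARA LIMA"),
    dob = c("1980-01-01", "2012-06-15", "2012-06-15", "1985-01-01",
            "2012-06-15"),
    sex = c("F", "M", "F", "F", "F"),
    municipality = "2900001", state = "29", stringsAsFactors = FALSE
  )
  births <- data.frame(
    birth_id = c("B1", "B2"), child_dob = "2012-06-15",
    child_sex = c("F", "F"), stringsAsFactors = FALSE
  )
  asg <- data.frame(birth_id = c("B1", "B2"), cohort_id = c("P1", "P4"),
                    score = 1, stringsAsFactors = FALSE)
  off <- find_offspring(asg, births, cohort)
  expect_identical(off$offspring_id, c("P3", "P5"))
  expect_identical(off$ambiguous, c(FALSE, FALSE))

  # same-sex twins sharing the DOB: flagged, not assigned
  cohort2 <- rbind(cohort,
    data.frame(person_id = "P6", family_id = "F2", name = "LIA LIMA",
               dob = "2012-06-15", sex = "F", municipality = "2900001",
               state = "29", stringsAsFactors = FALSE))
  off2 <- find_offspring(asg, births, cohort2)
  expect_true(off2$ambiguous[2])
  expect_true(is.na(off2$offspring_id[2]))
  # no family member matches -> null
  asg3 <- data.frame(birth_id = "B1", cohort_id = "P1", score = 1)
  births3 <- births; births3$child_dob <- "2001-01-01"
  off3 <- find_offspring(asg3, births3, cohort)
  expect_true(is.na(off3$offspring_id))
  expect_false(off3$ambiguous)
})
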