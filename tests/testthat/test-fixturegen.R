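test_that("generate_corpus yields unique valid molecules of corpus size", {
  corp <- generate_corpus(fixture_spec(50, seed = 3))
  expect_length(corp$smiles, 50L)
  parsed <- parse_and_validate(corp$smiles)
  expect_true(all(parsed$is_valid))
  expect_false(anyDuplicated(parsed$canonical_smiles) > 0)
  expect_equal(corp$manifest$expected_fate, rep("kept", 50))
})

test_that("fixture generation is deterministic under the seed", {
  a <- generate_corpus(fixture_spec(30, seed = 5))
  b <- generate_corpus(fixture_spec(30, seed = 5))
  c <- generate_corpus(fixture_spec(30, seed = 6))
  expect_identical(a$smiles, b$smiles)
  expect_false(identical(a$smiles, c$smiles))
})

test_that("the two fragment pools produce chemically distinct corpora", {
  np <- np_fixture_smiles()
  drug <- druglike_fixture_smiles()
  expect_length(intersect(np, drug), 0L)
  # druglike pool introduces nitrogen/sulfur chemistry absent from the
  # oxygen-rich NP-like pool
  expect_true(mean(grepl("N|S|n|s", drug)) > 0.5)
  expect_true(mean(grepl("N|S|n|s", np)) < 0.1)
})

test_that("corruption plan counts are honoured exactly and hit distinct rows", {
  plan <- c(syntactic_break = 4L, duplicate_rewrite = 3L, add_salt = 2L,
            severe_valence = 2L)
  corp <- generate_corpus(fixture_spec(40, seed = 13, corruption_plan = plan))
  got <- table(corp$manifest$corruption)
  expect_equal(unname(got[names(plan)]), unname(plan), ignore_attr = TRUE)
  expect_equal(sum(corp$manifest$corruption == "none"), 40L - sum(plan))
})

test_that("each corruption operator produces its designed defect", {
  base <- np_fixture_smiles()[1:5]
  broken <- corrupt_smiles(base, "syntactic_break", seed = 1)
  expect_false(any(parse_and_validate(broken)$is_valid))

  rewritten <- corrupt_smiles(base, "duplicate_rewrite", seed = 1)
  ok <- !is.na(rewritten)
  expect_true(any(ok))
  expect_equal(canonical_smiles(rewritten[ok]), base[ok])
  expect_true(all(rewritten[ok] != base[ok]))

  salted <- corrupt_smiles(base, "add_salt", seed = 1)
  expect_true(all(grepl("\\.\\[", salted)))

  iso <- corrupt_smiles(base, "add_isotope", seed = 1)
  expect_true(all(grepl("\\[1[0-9]", iso[!is.na(iso)])))

  sev <- corrupt_smiles(base, "severe_valence", seed = 1)
  chk <- check_structure(sev[!is.na(sev)])
  expect_true(all(chk$max_error_score > 5L))
})

test_that("infeasible corruption plans are rejected", {
  expect_error(fixture_spec(5, corruption_plan = c(add_salt = 6L)),
               "infeasible")
  expect_error(fixture_spec(5, corruption_plan = c(not_an_op = 1L)),
               "unknown")
})
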