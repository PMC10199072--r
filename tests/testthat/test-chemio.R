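test_that("parse_and_validate classifies valid and invalid strings", {
  res <- parse_and_validate(c("CCO", "c1ccccc1", "C1CC", "xyz"))
  expect_equal(res$is_valid, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(res$failure_stage[1:2], c("none", "none"))
  expect_equal(res$failure_stage[3:4], c("parse", "parse"))
  expect_true(all(is.na(res$canonical_smiles[3:4])))
  expect_true(all(!is.na(res$inchi[1:2])))
  expect_match(res$inchikey[[1]], "^[A-Z]{14}-[A-Z]{10}-[A-Z]$")
})

test_that("canonical_smiles is idempotent and writing-invariant", {
  # two writings of ethanol and of toluene
  expect_equal(canonical_smiles("OCC"), canonical_smiles("CCO"))
  expect_equal(canonical_smiles("c1ccccc1C"), canonical_smiles("Cc1ccccc1"))
  can <- canonical_smiles("CC(=O)Oc1ccccc1C(=O)O")
  expect_equal(canonical_smiles(can), can)
})

test_that("canonical_smiles errors on invalid input", {
  expect_error(canonical_smiles(c("CCO", "C1CC")), "invalid")
})

test_that("strip_stereochemistry removes stereo and only stereo", {
  res <- strip_stereochemistry(c("C[C@H](N)C(=O)O", "C/C=C/C", "CCO"))
  expect_false(any(grepl("@|/|\\\\", res)))
  expect_equal(res[[3]], canonical_smiles("CCO"))
  # stereoisomers collapse to the same achiral parent
  expect_equal(strip_stereochemistry("C[C@H](N)C(=O)O"),
               strip_stereochemistry("C[C@@H](N)C(=O)O"))
})

test_that("smiles file round-trip preserves records", {
  path <- withr::local_tempfile(fileext = ".smi")
  smiles <- c("CCO", "c1ccccc1", "CC(=O)O")
  write_smiles_file(smiles, path, ids = c("a", "b", "c"))
  back <- read_smiles_file(path, has_ids = TRUE)
  expect_equal(back$smiles, smiles)
  expect_equal(back$source_id, c("a", "b", "c"))
  write_smiles_file(smiles, path)
  expect_equal(read_smiles_file(path)$smiles, smiles)
})

test_that("record table JSONL round-trips including list-columns", {
  records <- tibble::tibble(
    id = c("r1", "r2"),
    smiles = c("CCO", "CCN"),
    score = c(1.5, NA_real_),
    tags = list(c("a", "b"), character(0))
  )
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_record_table(records, path)
  back <- read_record_table(path)
  expect_equal(back$id, records$id)
  expect_equal(back$score, records$score)
  expect_equal(back$tags, records$tags)
})

test_that("inputs with whitespace or empty strings are rejected", {
  expect_error(parse_and_validate("C C"), "whitespace")
  expect_error(parse_and_validate(""), "empty")
})
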