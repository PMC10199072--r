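test_that("split_sizes reproduces the published partition arithmetic", {
  sizes <- split_sizes(406919)
  expect_identical(sizes[["heldout"]], 81384L)
  expect_identical(sizes[["validation"]], 32554L)
  expect_identical(sizes[["train"]], 292981L)
  expect_identical(sum(sizes), 406919L)
})

test_that("split_sizes rounds halves up and always conserves the total", {
  # 0.20 * 30 = 6, 0.08 * 30 = 2.4 -> 2
  expect_identical(split_sizes(30),
                   c(train = 22L, validation = 2L, heldout = 6L))
  for (n in c(3L, 10L, 99L, 1234L, 40692L)) {
    expect_identical(sum(split_sizes(n)), n)
  }
})

test_that("prepare_corpus validates, strips stereo and deduplicates", {
  raw <- c("CCO", "OCC", "C[C@H](N)C(=O)O", "C[C@@H](N)C(=O)O", "C1CC")
  prepared <- prepare_corpus(raw, quiet = TRUE)
  # two ethanol writings and two alanine enantiomers each collapse to one
  expect_equal(sort(prepared),
               sort(c(canonical_smiles("CCO"),
                      strip_stereochemistry("C[C@H](N)C(=O)O"))))
  log <- attr(prepared, "prepare_log")
  expect_equal(unname(log["n_input"]), 5L)
  expect_equal(unname(log["n_invalid"]), 1L)
})

test_that("split_corpus partitions are disjoint, exhaustive and seeded", {
  corpus <- np_fixture_smiles()
  sp1 <- split_corpus(corpus, seed = 7)
  sp2 <- split_corpus(corpus, seed = 7)
  sp3 <- split_corpus(corpus, seed = 8)
  all1 <- c(sp1$train, sp1$validation, sp1$heldout)
  expect_setequal(all1, corpus)
  expect_equal(length(all1), length(corpus))
  expect_identical(sp1$train, sp2$train)
  expect_false(identical(sp1$train, sp3$train))
  expect_equal(length(sp1$heldout), split_sizes(length(corpus))[["heldout"]])
})

test_that("split_corpus refuses duplicated corpora", {
  expect_error(split_corpus(c("CCO", "CCO", "CCN"), seed = 1), "deduplicated")
})

test_that("enumerate_smiles writes canonicalize back to their source", {
  smiles <- np_fixture_smiles()[1:10]
  enum <- enumerate_smiles(smiles, k = 10, seed = 3)
  expect_equal(nrow(enum), 100L)
  expect_equal(canonical_smiles(enum$variant), enum$source)
  # augmentation actually varies the writing for non-trivial molecules
  expect_true(mean(enum$variant != enum$source) > 0.5)
  # determinism
  expect_identical(enum, enumerate_smiles(smiles, k = 10, seed = 3))
})

test_that("augment_corpus grows train and validation exactly factor-fold", {
  sp <- split_corpus(np_fixture_smiles(), seed = 5)
  aug <- augment_corpus(sp, factor = 10, seed = 2)
  expect_equal(length(aug$train_aug), 10L * length(sp$train))
  expect_equal(length(aug$validation_aug), 10L * length(sp$validation))
})
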