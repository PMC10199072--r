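test_that("tokenization handles brackets, halogens and %NN closures", {
  expect_equal(smiles_tokenize("CCl")[[1]], c("C", "Cl"))
  expect_equal(smiles_tokenize("CBr")[[1]], c("C", "Br"))
  expect_equal(smiles_tokenize("C[C@@H]N")[[1]], c("C", "[C@@H]", "N"))
  expect_equal(smiles_tokenize("C%12CC%12")[[1]], c("C", "%12", "C", "C", "%12"))
  expect_equal(smiles_tokenize("c1ccccc1")[[1]],
               c("c", "1", "c", "c", "c", "c", "c", "1"))
  # B is boron, not part of Br, unless followed by r
  expect_equal(smiles_tokenize("BC")[[1]], c("B", "C"))
})

test_that("tokenize-concatenate is the identity", {
  smiles <- c("CC(=O)Oc1ccccc1C(=O)O", "C[C@H](N)C(=O)[O-]",
              "ClCCBr", "C%10CCC%10", "O=[N+]([O-])c1ccccc1")
  toks <- smiles_tokenize(smiles)
  expect_equal(vapply(toks, paste0, character(1), collapse = ""), smiles)
})

test_that("malformed token structures are rejected", {
  expect_error(smiles_tokenize("C[CH"), "dangling")
  expect_error(smiles_tokenize("C%1"), "dangling")
})

test_that("vocabulary reserves specials at indices 0..2 and sorts tokens", {
  vocab <- build_vocabulary(c("CCO", "CCl"))
  expect_equal(vocab$tokens[1:3], unname(vocab_specials()))
  expect_equal(vocab$tokens[-(1:3)], sort(c("C", "O", "Cl")))
  expect_equal(length(vocab), 6L)
})

test_that("encode/decode round-trips with START/END framing", {
  vocab <- build_vocabulary(c("CCO", "c1ccccc1Cl"))
  seqs <- encode_smiles(c("CCO", "c1ccccc1Cl"), vocab)
  expect_equal(seqs[[1]][1], 0L)                      # START
  expect_equal(seqs[[1]][length(seqs[[1]])], 1L)      # END
  expect_true(all(unlist(seqs) != 2L))                # no PAD inside
  expect_equal(decode_sequence(seqs[[1]], vocab), "CCO")
  expect_equal(decode_sequence(seqs[[2]], vocab), "c1ccccc1Cl")
})

test_that("out-of-vocabulary tokens raise a classed error", {
  vocab <- build_vocabulary("CCO")
  expect_error(encode_smiles("CCN", vocab), class = "npgen_oov_error")
  err <- tryCatch(encode_smiles("CCN", vocab), error = identity)
  expect_match(conditionMessage(err), "N")
})

test_that("vocabulary JSON round-trips", {
  vocab <- build_vocabulary(c("CC(=O)Oc1ccccc1", "ClC(Br)I"))
  path <- withr::local_tempfile(fileext = ".json")
  write_vocabulary(vocab, path)
  back <- read_vocabulary(path)
  expect_equal(back$tokens, vocab$tokens)
  expect_s3_class(back, "npgen_vocabulary")
})
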