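test_that("fragment multisets are invariant to the SMILES writing", {
  smiles <- np_fixture_smiles()[1:8]
  enum <- enumerate_smiles(smiles, k = 4, seed = 2)
  f_base <- fragment_molecules(smiles)
  f_enum <- fragment_molecules(enum$variant)
  for (i in seq_along(smiles)) {
    base_multiset <- sort(f_base$fragments[[i]])
    for (j in which(enum$source == f_base$smiles[[i]])) {
      expect_equal(sort(f_enum$fragments[[j]]), base_multiset)
    }
  }
})

test_that("fragments yield one identifier per heavy atom", {
  f <- fragment_molecules(c("CCO", "c1ccccc1"))
  expect_equal(f$n_heavy, c(3L, 6L))
  expect_equal(lengths(f$fragments), f$n_heavy)
})

test_that("score table contributions follow the Laplace log-odds formula", {
  # identical corpora: every contribution is exactly 0
  same <- train_score_table("CCO", "CCO")
  expect_true(all(same$contribution == 0))
  # one-molecule corpora: a fragment appears in one corpus or both, so the
  # only possible contributions are log10(((1+1)/2)/((0+1)/2)) = +/-log10(2)
  # (exclusive fragments) and 0 (shared fragments)
  tab <- train_score_table("CCO", "CCC")
  expect_true(all(is.finite(tab$contribution)))
  expect_true(all(vapply(tab$contribution, function(v) {
    isTRUE(all.equal(v, log10(2))) || isTRUE(all.equal(v, -log10(2))) ||
      v == 0
  }, logical(1))))
  expect_true(any(abs(tab$contribution - log10(2)) < 1e-12))
  expect_true(any(abs(tab$contribution + log10(2)) < 1e-12))
})

test_that("score table is antisymmetric under corpus swap", {
  np <- np_fixture_smiles()[1:15]
  ref <- druglike_fixture_smiles()[1:15]
  tab <- train_score_table(np, ref)
  swapped <- train_score_table(ref, np)
  common <- names(tab$contribution)
  expect_equal(swapped$contribution[common], -tab$contribution[common])
  scores <- np_score(np, tab)$np_score
  scores_swapped <- np_score(np, swapped)$np_score
  expect_equal(scores_swapped, -scores, tolerance = 1e-12)
})

test_that("np_score is invariant to the SMILES writing", {
  np <- np_fixture_smiles()[1:10]
  ref <- druglike_fixture_smiles()[1:10]
  tab <- train_score_table(np, ref)
  probe <- np_fixture_smiles()[11:14]
  enum <- enumerate_smiles(probe, k = 5, seed = 4)
  s_base <- np_score(probe, tab)
  s_enum <- np_score(enum$variant, tab)
  expect_equal(s_enum$np_score, rep(s_base$np_score, each = 5),
               tolerance = 1e-12)
})

test_that("pool separation: NP-like fixtures outscore druglike fixtures", {
  np <- np_fixture_smiles()
  drug <- druglike_fixture_smiles()
  tab <- train_score_table(np[1:40], drug[1:25])
  mean_np <- mean(np_score(np[41:60], tab)$np_score)
  mean_drug <- mean(np_score(drug[26:40], tab)$np_score)
  expect_gt(mean_np, mean_drug)
})

test_that("tail compression matches its closed form and is monotone", {
  expect_equal(compress_score_tails(9), 4 + log10(6))
  expect_equal(compress_score_tails(-9), -(4 + log10(6)))
  expect_equal(compress_score_tails(c(-3, 0, 4)), c(-3, 0, 4))
  x <- seq(-10, 10, by = 0.25)
  expect_true(all(diff(compress_score_tails(x)) > 0))
})

test_that("score tables round-trip through JSON", {
  tab <- train_score_table(np_fixture_smiles()[1:5],
                           druglike_fixture_smiles()[1:5])
  path <- withr::local_tempfile(fileext = ".json")
  write_score_table(tab, path)
  back <- read_score_table(path)
  expect_equal(back$contribution[names(tab$contribution)], tab$contribution)
  expect_equal(back$radius, tab$radius)
})
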