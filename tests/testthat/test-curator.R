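test_that("checker rules assign the expected penalties", {
  rules <- checker_rules()
  penalty_of <- function(rule) rules$penalty[rules$rule == rule]
  expect_equal(penalty_of("undefined_stereo"), 2L)
  expect_equal(penalty_of("isotope_present"), 2L)
  expect_equal(penalty_of("salt_or_multifragment"), 2L)
  expect_equal(penalty_of("valence_violation"), 6L)
  expect_equal(penalty_of("polymer_or_unsupported_element"), 7L)
})

test_that("check_structure flags cosmetic versus severe issues", {
  res <- check_structure(c(
    "C[C@H](N)C(=O)O",   # defined stereo: fine
    "CC(N)C(=O)O",       # stereocentre without assignment
    "[13CH4]",           # isotope label
    "CCO.[Na+]",         # multi-fragment salt
    "CC(C)[W](C)(C)(C)(C)C"  # exotic hypervalent metal
  ))
  expect_false("undefined_stereo" %in% res$error_types[[1]])
  expect_true("undefined_stereo" %in% res$error_types[[2]])
  expect_true("isotope_present" %in% res$error_types[[3]])
  expect_true("salt_or_multifragment" %in% res$error_types[[4]])
  expect_true("polymer_or_unsupported_element" %in% res$error_types[[5]])
  expect_equal(res$max_error_score[2:4], c(2L, 2L, 2L))
  expect_equal(res$max_error_score[[5]], 7L)
  # removal threshold: strictly greater than 5
  expect_equal(res$max_error_score > 5L, c(rep(FALSE, 4), TRUE))
})

test_that("standardize_structures neutralizes charges", {
  res <- standardize_structures(c("CC(=O)[O-]", "CC[NH3+]"))
  expect_equal(res, canonical_smiles(c("CC(=O)O", "CCN")))
  # idempotent
  expect_equal(standardize_structures(res), res)
})

test_that("get_parent_structures strips salts, solvents and isotopes", {
  res <- get_parent_structures(c("O=C(O)c1ccccc1.[Na+]", "c1ccccc1.O.O",
                                 "[13CH3]CO"))
  expect_equal(res$parent_smiles,
               canonical_smiles(c("O=C(O)c1ccccc1", "c1ccccc1", "CCO")))
  # a record that is nothing but drop-list fragments has no parent
  none <- get_parent_structures("O.[Na+].[Cl-]")
  expect_true(is.na(none$parent_smiles))
})

test_that("deduplicate_records removes later canonical or InChI copies", {
  ids <- parse_and_validate(c("CCO", "CCN", "CCO"))
  dd <- deduplicate_records(ids)
  expect_equal(dd$n_removed, 1L)
  expect_equal(dd$kept$smiles, c("CCO", "CCN"))
})

test_that("curate counts match the planted manifest exactly across seeds", {
  plan <- c(syntactic_break = 6L, duplicate_rewrite = 5L, severe_valence = 4L,
            add_isotope = 3L, add_charge = 3L, add_stereo = 3L, add_salt = 3L)
  for (seed in c(11L, 23L, 37L)) {
    spec <- fixture_spec(120, seed = seed, corruption_plan = plan)
    corp <- generate_corpus(spec)
    res <- curate(corp$smiles, ids = corp$manifest$source_id)
    fate <- table(corp$manifest$expected_fate)
    expect_identical(res$summary$n_syntactic_invalid,
                     unname(fate[["syntactic_invalid"]]))
    expect_identical(res$summary$n_duplicates, unname(fate[["duplicate"]]))
    expect_identical(res$summary$n_checker_removed,
                     unname(fate[["checker_removed"]]))
    expect_identical(res$summary$n_output, unname(fate[["kept"]]))
    # conservation
    expect_identical(
      res$summary$n_output,
      res$summary$n_input - res$summary$n_syntactic_invalid -
        res$summary$n_duplicates - res$summary$n_checker_removed)
    # cosmetic corruptions survive with their flags recorded
    kept_flags <- unlist(res$records$error_types)
    expect_true("isotope_present" %in% kept_flags)
    expect_true("salt_or_multifragment" %in% kept_flags)
  }
})

test_that("curated records carry standardized stereo-free parents", {
  plan <- c(add_salt = 4L, add_stereo = 4L, add_charge = 4L)
  corp <- generate_corpus(fixture_spec(60, seed = 9, corruption_plan = plan))
  res <- curate(corp$smiles)
  expect_false(any(grepl("@|/|\\\\|\\.", res$records$canonical_smiles)))
  expect_true(all(parse_and_validate(res$records$canonical_smiles)$is_valid))
})

test_that("salt and solvent drop list contains the common counter-ions", {
  drop <- salt_solvent_list()
  expect_true(all(c("[Na+]", "[Cl-]", "O", "CCO") %in% drop))
})
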