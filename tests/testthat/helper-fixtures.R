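# Shared fixtures, generated once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# 60 clean NP-like molecules (no corruption)
np_fixture_smiles <- function() {
  cached("np60", generate_corpus(fixture_spec(60, seed = 42))$smiles)
}

# 40 clean druglike molecules
druglike_fixture_smiles <- function() {
  cached("drug40",
         generate_corpus(fixture_spec(40, seed = 42,
                                      fragment_pool = "druglike"))$smiles)
}
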