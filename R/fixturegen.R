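# Synthetic SMILES corpora with known ground truth.
#
# Molecules are assembled by seeded concatenation of curated building-block
# units rather than random string generation, so every uncorrupted fixture is
# chemically valid by construction. Each unit is written so that its first
# atom can accept one more bond (it is grafted onto the growing chain) and
# its last top-level atom keeps a free valence (the chain can continue).
# `{r}` marks a ring-closure digit instantiated per unit, so ring labels
# never collide.

fixture_unit_pools <- function() {
  list(
    np_like = c(
      "C", "CC", "C(C)", "C(O)", "CO", "C(=O)", "CC(O)C",
      "C{r}(O)C(O)C(O)C(CO)OC{r}",   # pyranose-like sugar ring
      "c{r}cc(O)ccc{r}",             # phenol
      "C{r}OC(=O)CC{r}",             # gamma-lactone
      "C{r}CC(=O)OC{r}",             # delta-lactone variant
      "C(C)C(=O)",                   # polyketide-like propionate unit
      "c{r}ccoc{r}"                  # furan
    ),
    druglike = c(
      "C", "CC", "C(C)", "C(F)", "C(C(F)(F)F)",
      "c{r}ccccc{r}",                # benzene
      "c{r}ccncc{r}",                # pyridine
      "c{r}ccsc{r}",                 # thiophene
      "C(=O)N", "N(C)C(=O)",         # amide linkers
      "S(=O)(=O)N",                  # sulfonamide
      "C(=O)OC"                      # ester
    )
  )
}

#' Corruption operators understood by the fixture generator
#' @return Character vector of operator names.
#' @export
corruption_ops <- function() {
  c("syntactic_break", "duplicate_rewrite", "add_salt", "add_isotope",
    "add_charge", "add_stereo", "severe_valence")
}

#' Describe a synthetic fixture corpus
#'
#' @param n_molecules Number of molecules in the corpus.
#' @param seed Integer seed; generation is fully deterministic under it.
#' @param fragment_pool `"np_like"` (sugars, phenols, lactones, polyketide
#'   chains) or `"druglike"` (aryl amides, sulfonamides, heteroaryl units).
#' @param corruption_plan Named integer vector mapping operator names (see
#'   [corruption_ops()]) to counts; the counts must sum to at most
#'   `n_molecules`.
#' @return An object of class `npgen_fixture_spec`.
#' @export
fixture_spec <- function(n_molecules, seed = 1,
                         fragment_pool = c("np_like", "druglike"),
                         corruption_plan = integer(0)) {
  fragment_pool <- match.arg(fragment_pool)
  if (length(corruption_plan)) {
    bad <- setdiff(names(corruption_plan), corruption_ops())
    if (length(bad)) abort(paste("unknown corruption(s):",
                                 paste(bad, collapse = ", ")))
    if (sum(corruption_plan) > n_molecules) {
      abort("corruption counts exceed n_molecules: plan is infeasible")
    }
  }
  structure(
    list(n_molecules = as.integer(n_molecules), seed = as.integer(seed),
         fragment_pool = fragment_pool,
         corruption_plan = corruption_plan),
    class = "npgen_fixture_spec"
  )
}

assemble_unit <- function(unit, ring_digit) {
  gsub("{r}", as.character(ring_digit), unit, fixed = TRUE)
}

assemble_molecule <- function(units) {
  pieces <- character(length(units))
  ring <- 0L
  for (i in seq_along(units)) {
    u <- units[[i]]
    if (grepl("{r}", u, fixed = TRUE)) ring <- ring + 1L
    pieces[[i]] <- assemble_unit(u, ring)
  }
  paste0(pieces, collapse = "")
}

# draw one assembled SMILES from the pool under the current RNG state
draw_molecule <- function(pool_units) {
  n_units <- sample(3:6, 1)
  units <- sample(pool_units, n_units, replace = TRUE)
  assemble_molecule(units)
}

# heavy atoms counted from tokens; one per atom token (brackets hold exactly
# one heavy atom in the grammar subset the fixtures use)
count_heavy_atoms <- function(smiles) {
  atoms <- c("B", "C", "N", "O", "P", "S", "F", "I", "Cl", "Br",
             "b", "c", "n", "o", "p", "s")
  vapply(smiles_tokenize(smiles), function(tok) {
    sum(tok %in% atoms | (startsWith(tok, "[") & !grepl("^\\[[0-9]*H", tok)))
  }, integer(1))
}

#' Generate a synthetic SMILES corpus with a ground-truth manifest
#'
#' Assembles `n_molecules` unique valid molecules from the chosen
#' building-block pool, then applies the corruption plan, each corruption
#' hitting a distinct molecule. The manifest records, per record, the
#' corruption applied (if any), the canonical form of the uncorrupted base
#' molecule, and the fate the curation cascade must assign to it — the
#' oracle for curator tests.
#'
#' @param spec An [fixture_spec()] object.
#' @return A list: `smiles` (character vector, corrupted entries in place)
#'   and `manifest` (tibble: `source_id`, `smiles`, `corruption`,
#'   `base_canonical`, `expected_fate` in
#'   `{"kept","syntactic_invalid","duplicate","checker_removed"}`).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "npgen_fixture_spec"))
  pool_units <- fixture_unit_pools()[[spec$fragment_pool]]
  n <- spec$n_molecules

  base <- withr::with_seed(spec$seed, {
    out <- character(0)
    tries <- 0L
    while (length(out) < n && tries < 50L) {
      cand <- unique(vapply(seq_len(2L * n), function(i) draw_molecule(pool_units),
                            character(1)))
      can <- canonical_smiles(cand)
      # realistic corpus: 10-60 heavy atoms (also keeps every molecule off
      # the salt/solvent drop list)
      size_ok <- count_heavy_atoms(can) >= 10L & count_heavy_atoms(can) <= 60L
      keep <- size_ok & !duplicated(can) & !(can %in% attr(out, "canon"))
      new <- can[keep]
      out <- structure(c(out, new), canon = c(attr(out, "canon"), new))
      tries <- tries + 1L
    }
    if (length(out) < n) abort("fixture pool exhausted before reaching n unique molecules")
    out[seq_len(n)]
  })

  manifest <- tibble(
    source_id = sprintf("fix_%04d", seq_len(n)),
    smiles = base,
    corruption = "none",
    base_canonical = base,
    expected_fate = "kept"
  )

  plan <- spec$corruption_plan
  if (length(plan) == 0 || sum(plan) == 0) {
    return(list(smiles = manifest$smiles, manifest = manifest))
  }

  withr::with_seed(spec$seed + 1L, {
    available <- sample(seq_len(n))  # corruption targets, each used once
    take <- function(k) {
      idx <- available[seq_len(k)]
      available <<- available[-seq_len(k)]
      idx
    }
    for (op in intersect(corruption_ops(), names(plan))) {
      k <- plan[[op]]
      if (k == 0) next
      done <- 0L
      while (done < k) {
        idx <- take(1L)
        res <- corrupt_fixture(manifest, idx, op, spec$seed, available)
        if (!is.null(res)) {
          manifest[idx, ] <- res$row
          if (!is.null(res$reserve)) {
            # the source of a planted duplicate must itself stay uncorrupted
            available <- setdiff(available, res$reserve)
          }
          done <- done + 1L
        }
        if (length(available) == 0 && done < k) {
          abort(sprintf("corruption plan infeasible: no applicable molecule for %s", op))
        }
      }
    }
  })
  list(smiles = manifest$smiles, manifest = manifest)
}

# apply one corruption to manifest row `idx`; NULL when inapplicable
corrupt_fixture <- function(manifest, idx, op, seed, available) {
  base <- manifest$base_canonical[[idx]]
  if (op == "duplicate_rewrite") {
    # rewrite of a *different, uncorrupted* molecule -> a planted duplicate;
    # the source is reported back so the caller can shield it from later ops
    pool <- setdiff(which(manifest$corruption == "none"), idx)
    if (length(pool) == 0) return(NULL)
    src <- pool[[1 + (seed + idx) %% length(pool)]]
    out <- corrupt_smiles(manifest$base_canonical[[src]], op, seed + idx)
    if (is.na(out)) return(NULL)
    return(list(
      row = tibble(source_id = manifest$source_id[[idx]], smiles = out,
                   corruption = op,
                   base_canonical = manifest$base_canonical[[src]],
                   expected_fate = "duplicate"),
      reserve = src
    ))
  }
  out <- corrupt_smiles(base, op, seed + idx)
  if (is.na(out)) return(NULL)
  fate <- switch(op,
                 syntactic_break = "syntactic_invalid",
                 severe_valence = "checker_removed",
                 "kept")
  list(row = tibble(source_id = manifest$source_id[[idx]], smiles = out,
                    corruption = op, base_canonical = base,
                    expected_fate = fate),
       reserve = NULL)
}

#' Apply a single corruption operator to valid SMILES
#'
#' Each operator targets one curation filter: `syntactic_break` deletes a
#' ring-closure digit or parenthesis (guaranteed unparseable);
#' `duplicate_rewrite` emits a different valid writing of the same graph;
#' `add_salt` appends a counter-ion fragment; `add_isotope`, `add_charge`
#' and `add_stereo` insert one isotope label, (de)protonate one site, or
#' mark one stereocentre; `severe_valence` grafts a hypervalent exotic-atom
#' fragment that parses but trips the severe checker rules.
#'
#' @param smiles Character vector of valid SMILES.
#' @param op One operator name from [corruption_ops()].
#' @param seed Integer seed.
#' @return Character vector; `NA` where the operator is inapplicable to a
#'   molecule (e.g. `add_stereo` with no prochiral site), so a planner can
#'   retry another molecule.
#' @export
corrupt_smiles <- function(smiles, op, seed = 1) {
  assert_smiles_strings(smiles)
  op <- match.arg(op, corruption_ops())
  if (op == "syntactic_break") {
    return(vapply(smiles, break_syntax, character(1), USE.NAMES = FALSE))
  }
  if (op == "add_salt") {
    salt <- c(".[Na+]", ".[Cl-]")[1 + seed %% 2]
    return(paste0(smiles, salt))
  }
  out <- chem_backend("corrupt", smiles,
                      args = c("--op", op, "--seed", as.integer(seed)))
  res <- na_if_empty(out$smiles_out)
  res[out$ok != "1"] <- NA_character_
  res
}

break_syntax <- function(s) {
  ring_pos <- regexpr("[0-9]", s)
  if (ring_pos > 0) {
    return(paste0(substr(s, 1, ring_pos - 1), substr(s, ring_pos + 1, nchar(s))))
  }
  paren_pos <- regexpr("\\)", s)
  if (paren_pos > 0) {
    return(paste0(substr(s, 1, paren_pos - 1),
                  substr(s, paren_pos + 1, nchar(s))))
  }
  paste0(s, "1")  # unmatched ring-bond opening: never parseable
}
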