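#' The structure-checker rule table
#'
#' Penalties grade severity: 2 for cosmetic issues a later standardization
#' step resolves or that are expected of stereo-free generated molecules
#' (undefined stereocentres, ionized sites, isotope labels, salt/solvent
#' fragments), 5 for an identifier round-trip mismatch, 6-7 for severe
#' structural defects. Records whose maximum penalty exceeds 5 are removed
#' during curation, so exactly the penalty >= 6 rules are fatal.
#'
#' @return A tibble `rule`, `penalty`, `description`.
#' @export
checker_rules <- function() {
  tibble(
    rule = c("undefined_stereo", "needs_deprotonation_or_protonation",
             "isotope_present", "salt_or_multifragment",
             "roundtrip_mismatch", "valence_violation",
             "identifier_failure", "no_parent",
             "polymer_or_unsupported_element"),
    penalty = c(2L, 2L, 2L, 2L, 5L, 6L, 6L, 6L, 7L),
    description = c(
      "at least one potential stereocentre is unassigned",
      "an ionized site could be neutralized by (de)protonation",
      "an atom carries an isotope label",
      "the record contains more than one fragment (counter-ion/solvent)",
      "re-parsing the canonical SMILES yields a different canonical form",
      "an atom exceeds its standard valence",
      "InChI or InChIKey generation failed",
      "all fragments sit on the salt/solvent drop list",
      "element outside the supported organic set (or polymer marker)"
    )
  )
}

#' Check structures against the curation rule table
#'
#' Evaluates every rule of [checker_rules()] on each molecule and reports
#' the fired rules and the maximum penalty (0 when no rule fires).
#' Deterministic.
#'
#' @param smiles Character vector of parseable SMILES.
#' @return A tibble `smiles`, `error_types` (list-column of fired rule
#'   names), `max_error_score`.
#' @export
check_structure <- function(smiles) {
  assert_smiles_strings(smiles)
  facts <- chem_backend("checkfacts", smiles)
  if (any(!nzchar(facts$has_unspec_stereo))) {
    abort("check_structure requires parseable SMILES")
  }
  rules <- checker_rules()
  flag <- function(col) facts[[col]] == "1"
  fired <- list(
    undefined_stereo = flag("has_unspec_stereo"),
    needs_deprotonation_or_protonation = flag("uncharge_changes"),
    isotope_present = flag("has_isotope"),
    salt_or_multifragment = as.integer(facts$n_fragments) > 1L,
    roundtrip_mismatch = flag("roundtrip_mismatch"),
    valence_violation = flag("valence_violation"),
    identifier_failure = flag("identifier_failure"),
    polymer_or_unsupported_element = flag("unsupported_element")
  )
  error_types <- lapply(seq_along(smiles), function(i) {
    names(fired)[vapply(fired, `[[`, logical(1), i)]
  })
  max_score <- vapply(error_types, function(et) {
    if (length(et) == 0) 0L else max(rules$penalty[match(et, rules$rule)])
  }, integer(1))
  tibble(smiles = smiles, error_types = error_types,
         max_error_score = max_score)
}

#' Standardize structures (normalization + neutralization)
#'
#' Applies functional-group normalization (e.g. charge-separated forms are
#' rewritten uniformly), neutralization by (de)protonation wherever an
#' ionizable site allows it, and removal of redundant explicit hydrogens.
#' Idempotent.
#'
#' @param smiles Character vector of parseable SMILES.
#' @return Character vector of standardized canonical SMILES.
#' @export
standardize_structures <- function(smiles) {
  assert_smiles_strings(smiles)
  out <- na_if_empty(chem_backend("standardize", smiles)$smiles_out)
  if (anyNA(out)) abort("standardize_structures requires parseable SMILES")
  out
}

#' Extract parent structures (salt/solvent stripping, isotope clearing)
#'
#' Splits each record into fragments, drops fragments on the packaged
#' salt/solvent list (see [salt_solvent_list()]), keeps the largest
#' remaining fragment by heavy-atom count, and clears all isotope labels.
#' Idempotent. Records whose fragments are all on the drop list have no
#' parent and are flagged.
#'
#' @param smiles Character vector of parseable SMILES.
#' @return A tibble `smiles`, `parent_smiles` (`NA` when no parent remains),
#'   `no_parent` (logical).
#' @export
get_parent_structures <- function(smiles) {
  assert_smiles_strings(smiles)
  out <- chem_backend("parent", smiles,
                      args = c("--salts", shQuote(salt_solvent_file())))
  tibble(smiles = smiles,
         parent_smiles = na_if_empty(out$parent_smiles),
         no_parent = out$no_parent == "1")
}

salt_solvent_file <- function() {
  system.file("extdata", "salts_solvents.smi", package = "npgen")
}

#' The packaged salt/solvent drop list
#'
#' Halide anions, alkali and alkaline-earth cations, ammonium, water and the
#' common small solvents/counter-acids. The list ships as an editable
#' plain-text file (`inst/extdata/salts_solvents.smi`).
#'
#' @return Character vector of canonical fragment SMILES.
#' @export
salt_solvent_list <- function() {
  lines <- readLines(salt_solvent_file(), warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

#' Deduplicate molecule records by canonical SMILES or InChI
#'
#' A record is a duplicate if *either* its canonical SMILES *or* its InChI
#' matches any earlier kept record (both identity keys are applied, as in
#' the full-scale library curation). First occurrences are kept, order is
#' preserved.
#'
#' @param records A tibble with `canonical_smiles` and `inchi` columns.
#' @return A list: `kept` (tibble) and `n_removed`.
#' @export
deduplicate_records <- function(records) {
  stopifnot(is.data.frame(records))
  if (!all(c("canonical_smiles", "inchi") %in% names(records))) {
    abort("records must carry canonical_smiles and inchi columns")
  }
  if (anyNA(records$canonical_smiles) || anyNA(records$inchi)) {
    abort("identifier fields must be populated before deduplication")
  }
  dup <- duplicated(records$canonical_smiles) | duplicated(records$inchi)
  list(kept = records[!dup, , drop = FALSE], n_removed = sum(dup))
}

#' Curate a batch of generated SMILES
#'
#' The post-generation curation cascade applied to raw sampled SMILES:
#'
#' 1. syntactic validity (four-stage parse / canonical / InChI / InChIKey);
#' 2. stereochemistry removal;
#' 3. deduplication by canonical SMILES *or* InChI;
#' 4. structure-quality checking against [checker_rules()] (error types and
#'    the maximum penalty are recorded per record);
#' 5. standardization ([standardize_structures()]);
#' 6. parent extraction ([get_parent_structures()]).
#'
#' Records whose maximum penalty exceeds 5 — and records left with no parent
#' fragment — are removed. The quality check runs before standardization so
#' the recorded error types describe the structures as generated (ionized
#' sites and salts are then resolved by steps 5-6), matching how the error
#' bookkeeping of the full-scale library was compiled.
#'
#' @param smiles Character vector of raw generated SMILES.
#' @param ids Optional record IDs (defaults to `gen_<row>`).
#' @return A list with `records` (tibble of kept records: `source_id`,
#'   `raw_smiles`, `canonical_smiles`, `inchi`, `inchikey`,
#'   `max_error_score`, `error_types`) and `summary` (one-row tibble:
#'   `n_input`, `n_syntactic_invalid`, `n_duplicates`, `n_checker_removed`,
#'   `n_output`; the conservation identity
#'   `n_output = n_input - n_syntactic_invalid - n_duplicates -
#'   n_checker_removed` always holds).
#' @export
curate <- function(smiles, ids = NULL) {
  if (!is.character(smiles) || length(smiles) == 0) {
    abort("`smiles` must be a non-empty character vector")
  }
  ids <- ids %||% paste0("gen_", seq_along(smiles))
  n_input <- length(smiles)

  # 1. syntactic validity; raw samples may be empty or malformed strings,
  # which count as syntactically invalid rather than erroring
  well_formed <- nzchar(smiles) & !grepl("[[:space:]]", smiles)
  is_valid <- logical(n_input)
  if (any(well_formed)) {
    is_valid[well_formed] <-
      parse_and_validate(smiles[well_formed])$is_valid
  }
  valid_idx <- which(is_valid)
  n_syntactic_invalid <- n_input - length(valid_idx)
  if (length(valid_idx) == 0) {
    return(curation_result(tibble(), n_input, n_syntactic_invalid, 0L, 0L))
  }

  # 2. stereochemistry removal, then re-derive all identifiers
  stripped <- strip_stereochemistry(smiles[valid_idx])
  rep2 <- parse_and_validate(stripped)
  records <- tibble(
    source_id = ids[valid_idx],
    raw_smiles = smiles[valid_idx],
    canonical_smiles = rep2$canonical_smiles,
    inchi = rep2$inchi,
    inchikey = rep2$inchikey
  )

  # 3. dual-key deduplication
  dd <- deduplicate_records(records)
  records <- dd$kept

  # 4. quality check on the as-generated (stereo-free) structures
  chk <- check_structure(records$canonical_smiles)
  records$error_types <- chk$error_types
  records$max_error_score <- chk$max_error_score

  # 5-6. standardize, then extract parents
  std <- standardize_structures(records$canonical_smiles)
  par <- get_parent_structures(std)
  fatal <- records$max_error_score > 5L | par$no_parent
  records <- records[!fatal, , drop = FALSE]
  n_checker_removed <- sum(fatal)

  if (nrow(records) > 0) {
    final <- parse_and_validate(par$parent_smiles[!fatal])
    records$canonical_smiles <- final$canonical_smiles
    records$inchi <- final$inchi
    records$inchikey <- final$inchikey
    records <- records[, c("source_id", "raw_smiles", "canonical_smiles",
                           "inchi", "inchikey", "max_error_score",
                           "error_types")]
  }
  curation_result(records, n_input, n_syntactic_invalid, dd$n_removed,
                  n_checker_removed)
}

curation_result <- function(records, n_input, n_syntactic_invalid,
                            n_duplicates, n_checker_removed) {
  summary <- tibble(
    n_input = as.integer(n_input),
    n_syntactic_invalid = as.integer(n_syntactic_invalid),
    n_duplicates = as.integer(n_duplicates),
    n_checker_removed = as.integer(n_checker_removed),
    n_output = as.integer(n_input - n_syntactic_invalid - n_duplicates -
                            n_checker_removed)
  )
  stopifnot(summary$n_output == nrow(records))
  list(records = records, summary = summary)
}
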