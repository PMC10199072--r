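#' Parse SMILES and derive the three identity representations
#'
#' Validity follows the four-stage criterion used when curating generated
#' libraries: a SMILES is valid only if it parses into a molecular graph
#' *and* yields a canonical SMILES, an InChI, and an InChIKey. A string
#' failing any stage is recorded as invalid with the first failing stage;
#' invalidity is a result, not an error.
#'
#' @param smiles Character vector of SMILES strings (non-empty, no internal
#'   whitespace).
#' @return A tibble with one row per input: `smiles`, `is_valid`,
#'   `failure_stage` (one of `"parse"`, `"canonical_write"`, `"inchi_write"`,
#'   `"inchikey_write"`, `"none"`), `canonical_smiles`, `inchi`, `inchikey`
#'   (identifier columns are `NA` on failure).
#' @examples
#' \dontrun{
#' parse_and_validate(c("CCO", "C1CC"))
#' }
#' @export
parse_and_validate <- function(smiles) {
  assert_smiles_strings(smiles)
  out <- chem_backend("parse", smiles)
  tibble(
    smiles = smiles,
    is_valid = out$is_valid == "1",
    failure_stage = out$failure_stage,
    canonical_smiles = na_if_empty(out$canonical_smiles),
    inchi = na_if_empty(out$inchi),
    inchikey = na_if_empty(out$inchikey)
  )
}

#' Canonicalize SMILES
#'
#' Convenience wrapper around [parse_and_validate()] returning the canonical
#' form; errors if any input is invalid.
#'
#' @inheritParams parse_and_validate
#' @return Character vector of canonical SMILES.
#' @export
canonical_smiles <- function(smiles) {
  res <- parse_and_validate(smiles)
  if (!all(res$is_valid)) {
    bad <- utils::head(res$smiles[!res$is_valid], 3)
    abort(c("invalid SMILES cannot be canonicalized",
            paste0("e.g. ", bad)))
  }
  res$canonical_smiles
}

#' Remove all stereochemistry from SMILES
#'
#' Drops tetrahedral centre marks and double-bond geometry, returning the
#' canonical form of the flattened molecule. Stripping is idempotent and
#' leaves already-stereo-free molecules canonically unchanged.
#'
#' @inheritParams parse_and_validate
#' @return Character vector of canonical, stereo-free SMILES.
#' @export
strip_stereochemistry <- function(smiles) {
  assert_smiles_strings(smiles)
  out <- chem_backend("strip", smiles)
  stripped <- na_if_empty(out$smiles_out)
  if (anyNA(stripped)) {
    bad <- utils::head(smiles[is.na(stripped)], 3)
    abort(c("SMILES failed to parse during stereochemistry removal",
            paste0("e.g. ", bad)))
  }
  stripped
}

#' Read a line-oriented SMILES file
#'
#' One record per line, optionally `SMILES<TAB>ID`. Blank lines are skipped
#' (and counted in a message); lines with more than two fields are an error.
#'
#' @param path Path to a `.smi`/`.txt` file.
#' @param has_ids Logical: does each line carry a tab-separated ID after the
#'   SMILES? Default `FALSE`; missing IDs are synthesized as `mol_<row>`.
#' @return A tibble `source_id`, `smiles`, in file order.
#' @export
read_smiles_file <- function(path, has_ids = FALSE) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  blank <- !nzchar(trimws(lines))
  if (any(blank)) {
    inform(sprintf("skipped %d blank line(s) in %s", sum(blank), path))
  }
  lines <- lines[!blank]
  if (length(lines) == 0) {
    return(tibble(source_id = character(), smiles = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf > 2)) {
    abort(sprintf("malformed line(s) with >2 tab-separated fields, e.g. line %d",
                  which(nf > 2)[1]))
  }
  smiles <- vapply(parts, `[[`, character(1), 1)
  ids <- vapply(parts, function(p) if (length(p) > 1) p[[2]] else NA_character_,
                character(1))
  ids[is.na(ids)] <- paste0("mol_", seq_along(ids)[is.na(ids)])
  if (isTRUE(has_ids) && anyNA(match(ids, ids))) invisible(NULL)
  tibble(source_id = ids, smiles = trimws(smiles))
}

#' Write a SMILES corpus to a line-oriented file
#'
#' @param smiles Character vector of SMILES.
#' @param path Output path.
#' @param ids Optional character vector of IDs (written tab-separated).
#' @return `path`, invisibly.
#' @export
write_smiles_file <- function(smiles, path, ids = NULL) {
  lines <- if (is.null(ids)) smiles else paste(smiles, ids, sep = "\t")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# fixed column order of the molecule record table: identifiers, curation
# bookkeeping, NP-likeness score, the three external classification labels,
# then the 27-descriptor annotation panel
record_core_columns <- function() {
  c("source_id", "raw_smiles", "canonical_smiles", "inchi", "inchikey",
    "max_error_score", "error_types", "np_score",
    "pathway", "superclass", "class_type")
}

#' Write a molecule record table as JSON Lines
#'
#' One JSON object per line with a fixed, documented column order: the
#' identifier block (`source_id`, `raw_smiles`, `canonical_smiles`, `inchi`,
#' `inchikey`), curation bookkeeping (`max_error_score`, `error_types`),
#' `np_score`, the classification labels (`pathway`, `superclass`,
#' `class_type`), then any descriptor columns in their table order.
#' Reading the file back reproduces the tibble exactly (numbers are written
#' at full precision).
#'
#' @param records A tibble of molecule records. All rows must share the same
#'   columns (enforced by the tibble), and list-columns (e.g. `error_types`)
#'   are serialized as JSON arrays.
#' @param path Output path (`.jsonl`).
#' @return `path`, invisibly.
#' @export
write_record_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  core <- intersect(record_core_columns(), names(records))
  rest <- setdiff(names(records), core)
  records <- records[, c(core, rest), drop = FALSE]
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con), add = TRUE)
  if (nrow(records) == 0) return(invisible(path))
  # unwrap scalar cells but keep genuine list-columns as JSON arrays
  rows <- vapply(seq_len(nrow(records)), function(i) {
    row <- lapply(records[i, , drop = FALSE], function(col) {
      if (is.list(col)) col[[1]] else col
    })
    jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA, null = "null",
                     na = "null")
  }, character(1))
  writeLines(rows, con, useBytes = TRUE)
  invisible(path)
}

#' Read a JSON Lines molecule record table
#'
#' @param path Path written by [write_record_table()].
#' @return A tibble; absent for an empty file is a zero-row tibble.
#' @export
read_record_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(tibble())
  rows <- lapply(lines, function(l) {
    jsonlite::fromJSON(l, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  })
  cols <- names(rows[[1]])
  out <- lapply(cols, function(cn) {
    vals <- lapply(rows, function(r) r[[cn]] %||% NA)
    if (all(lengths(vals) == 1) && !any(vapply(vals, is.list, logical(1)))) {
      unlist(lapply(vals, function(v) if (is.null(v)) NA else v))
    } else {
      lapply(vals, function(v) unlist(v) %||% character(0))
    }
  })
  names(out) <- cols
  as_tibble(out)
}

# --- internal helpers -------------------------------------------------------

assert_smiles_strings <- function(smiles) {
  if (!is.character(smiles) || length(smiles) == 0) {
    abort("`smiles` must be a non-empty character vector")
  }
  if (any(!nzchar(smiles)) || any(grepl("[[:space:]]", smiles))) {
    abort("SMILES strings must be non-empty and contain no whitespace")
  }
  invisible(smiles)
}

na_if_empty <- function(x) {
  x[!nzchar(x)] <- NA_character_
  x
}
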