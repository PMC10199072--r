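#' Atom-centred fragments of molecules
#'
#' Computes one fragment identifier per heavy atom, describing the atom's
#' circular environment out to `radius` bonds (Morgan environments, the
#' widely used stand-in for HOSE codes in natural-product-likeness
#' scoring). Identifiers are invariant under atom renumbering: any SMILES
#' writing of the same molecule yields the same multiset.
#'
#' @param smiles Character vector of parseable SMILES.
#' @param radius Environment radius in bonds (default 2).
#' @return A tibble `smiles`, `n_heavy`, `fragments` (list-column of
#'   character fragment ids, one per heavy atom).
#' @export
fragment_molecules <- function(smiles, radius = 2) {
  assert_smiles_strings(smiles)
  out <- chem_backend("fragments", smiles,
                      args = c("--radius", as.integer(radius)))
  if (any(!nzchar(out$n_heavy))) abort("fragment_molecules requires parseable SMILES")
  tibble(
    smiles = smiles,
    n_heavy = as.integer(out$n_heavy),
    fragments = strsplit(out$frags, " ", fixed = TRUE)
  )
}

#' Train a fragment contribution table for natural-product-likeness
#'
#' For each fragment `f`, the contribution is the Bayesian log-odds of the
#' fragment appearing in natural-product versus reference chemical space,
#' with Laplace (+1) smoothing:
#' `log10( ((m_np + 1) / (N_np + 1)) / ((m_ref + 1) / (N_ref + 1)) )`,
#' where `m` counts *molecules containing* the fragment and `N` the corpus
#' sizes. Deterministic; every contribution is finite by construction.
#'
#' @param np_smiles Character vector: the natural-product corpus.
#' @param ref_smiles Character vector: the reference (non-NP) corpus.
#' @param radius Fragment radius in bonds (default 2).
#' @return An object of class `npgen_score_table`: list with `contribution`
#'   (named numeric), `radius`, `n_np_molecules`, `n_ref_molecules`.
#' @export
train_score_table <- function(np_smiles, ref_smiles, radius = 2) {
  if (length(np_smiles) == 0 || length(ref_smiles) == 0) {
    abort("both corpora must be non-empty")
  }
  presence_counts <- function(smiles) {
    frags <- fragment_molecules(smiles, radius)$fragments
    table(unlist(purrr::map(frags, unique)))
  }
  np_counts <- presence_counts(np_smiles)
  ref_counts <- presence_counts(ref_smiles)
  all_frags <- union(names(np_counts), names(ref_counts))
  m_np <- as.numeric(np_counts[all_frags])
  m_np[is.na(m_np)] <- 0
  m_ref <- as.numeric(ref_counts[all_frags])
  m_ref[is.na(m_ref)] <- 0
  contribution <- log10(((m_np + 1) / (length(np_smiles) + 1)) /
                          ((m_ref + 1) / (length(ref_smiles) + 1)))
  names(contribution) <- all_frags
  structure(
    list(contribution = contribution, radius = as.integer(radius),
         n_np_molecules = length(np_smiles),
         n_ref_molecules = length(ref_smiles)),
    class = "npgen_score_table"
  )
}

#' @export
print.npgen_score_table <- function(x, ...) {
  cat(sprintf(
    "<npgen_score_table: %d fragments (radius %d), trained on %d NP / %d reference molecules>\n",
    length(x$contribution), x$radius, x$n_np_molecules, x$n_ref_molecules))
  invisible(x)
}

#' @export
tidy.npgen_score_table <- function(x, ...) {
  tibble(fragment = names(x$contribution),
         contribution = unname(x$contribution))
}

#' Tail compression applied to raw natural-product-likeness scores
#'
#' Values beyond +/-4 are compressed logarithmically so scores stay in
#' roughly \[-5, 5\]: `raw > 4` maps to `4 + log10(raw - 4 + 1)` and
#' symmetrically for `raw < -4`.
#'
#' @param raw Numeric vector of raw per-atom-normalized scores.
#' @return Numeric vector of compressed scores.
#' @export
compress_score_tails <- function(raw) {
  out <- raw
  hi <- !is.na(raw) & raw > 4
  lo <- !is.na(raw) & raw < -4
  out[hi] <- 4 + log10(raw[hi] - 4 + 1)
  out[lo] <- -(4 + log10(-raw[lo] - 4 + 1))
  out
}

#' Score molecules for natural-product-likeness
#'
#' The raw score is the sum of fragment contributions over the molecule's
#' per-atom fragment multiset, normalized by heavy-atom count; fragments
#' unseen during training contribute 0. Tails are compressed with
#' [compress_score_tails()]. The score is invariant to the SMILES writing
#' of a molecule.
#'
#' @param smiles Character vector of parseable SMILES.
#' @param table An [train_score_table()] object.
#' @return A tibble `smiles`, `np_score`.
#' @export
np_score <- function(smiles, table) {
  stopifnot(inherits(table, "npgen_score_table"))
  frag <- fragment_molecules(smiles, table$radius)
  if (any(frag$n_heavy == 0)) abort("cannot score a molecule with zero heavy atoms")
  raw <- vapply(seq_len(nrow(frag)), function(i) {
    contrib <- table$contribution[frag$fragments[[i]]]
    contrib[is.na(contrib)] <- 0
    sum(contrib) / frag$n_heavy[[i]]
  }, numeric(1))
  tibble(smiles = smiles, np_score = compress_score_tails(raw))
}

#' Persist a fragment score table as JSON
#'
#' @param table An `npgen_score_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(table, path) {
  stopifnot(inherits(table, "npgen_score_table"))
  payload <- list(
    radius = table$radius,
    n_np_molecules = table$n_np_molecules,
    n_ref_molecules = table$n_ref_molecules,
    contribution = as.list(table$contribution)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Reload a score table written by [write_score_table()]
#'
#' @param path Path to the JSON score table.
#' @return An `npgen_score_table`.
#' @export
read_score_table <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(contribution = unlist(payload$contribution),
         radius = as.integer(payload$radius),
         n_np_molecules = as.integer(payload$n_np_molecules),
         n_ref_molecules = as.integer(payload$n_ref_molecules)),
    class = "npgen_score_table"
  )
}
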