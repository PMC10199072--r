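#' Prepare a raw SMILES corpus for language-model training
#'
#' Filters a raw corpus to valid SMILES, removes all stereochemistry, and
#' deduplicates by canonical form, keeping first occurrences in input order.
#' The counts of removed invalid and duplicate entries are reported in a
#' message and attached as the `"prepare_log"` attribute.
#'
#' @param raw Character vector of SMILES strings.
#' @param quiet Suppress the summary message.
#' @return Character vector of canonical, stereo-free, unique SMILES with a
#'   `"prepare_log"` attribute (named integer vector: `n_input`, `n_invalid`,
#'   `n_duplicates`, `n_output`).
#' @export
prepare_corpus <- function(raw, quiet = FALSE) {
  assert_smiles_strings(raw)
  parsed <- parse_and_validate(raw)
  valid <- parsed$smiles[parsed$is_valid]
  n_invalid <- sum(!parsed$is_valid)
  stripped <- if (length(valid)) strip_stereochemistry(valid) else character(0)
  keep <- !duplicated(stripped)
  out <- stripped[keep]
  log <- c(n_input = length(raw), n_invalid = n_invalid,
           n_duplicates = sum(!keep), n_output = length(out))
  if (!quiet) {
    inform(sprintf(
      "prepare_corpus: %d in, %d invalid removed, %d duplicates removed, %d out",
      log[["n_input"]], log[["n_invalid"]], log[["n_duplicates"]],
      log[["n_output"]]))
  }
  structure(out, prepare_log = log)
}

#' Partition sizes for the train/validation/held-out split
#'
#' The held-out partition receives `round(0.20 * n)` molecules and the
#' validation partition `round(0.08 * n)` (half-up rounding); training takes
#' the remainder (72%). For the 406,919 curated natural products this yields
#' the 292,981 / 32,554 / 81,384 partition used to train the full-scale
#' model.
#'
#' @param n Corpus size.
#' @param heldout_frac,validation_frac Partition fractions (defaults 0.20,
#'   0.08).
#' @return Named integer vector `train`, `validation`, `heldout`.
#' @export
split_sizes <- function(n, heldout_frac = 0.20, validation_frac = 0.08) {
  round_half_up <- function(x) floor(x + 0.5)
  heldout <- as.integer(round_half_up(heldout_frac * n))
  validation <- as.integer(round_half_up(validation_frac * n))
  c(train = as.integer(n - heldout - validation),
    validation = validation, heldout = heldout)
}

#' Split a deduplicated corpus into train / validation / held-out portions
#'
#' Applies a uniform random permutation under `seed`, then partitions by the
#' size rule of [split_sizes()] (20% held out, 8% validation, 72% training).
#' Deterministic for a fixed seed; the three partitions are pairwise
#' disjoint and their union is the input corpus.
#'
#' @param corpus Character vector of unique SMILES (at least 3).
#' @param seed Integer seed for the shuffle.
#' @param heldout_fraction,validation_fraction Partition fractions passed
#'   to [split_sizes()] (defaults 0.20 / 0.08).
#' @return An object of class `npgen_corpus_split`: list with `train`,
#'   `validation`, `heldout` (character vectors) and `seed`.
#' @export
split_corpus <- function(corpus, seed, heldout_fraction = 0.20,
                         validation_fraction = 0.08) {
  if (length(corpus) < 3) abort("corpus must contain at least 3 entries")
  if (anyDuplicated(corpus)) abort("corpus must be deduplicated before splitting")
  sizes <- split_sizes(length(corpus), heldout_fraction, validation_fraction)
  perm <- withr::with_seed(seed, sample.int(length(corpus)))
  shuffled <- corpus[perm]
  heldout <- shuffled[seq_len(sizes[["heldout"]])]
  validation <- shuffled[sizes[["heldout"]] + seq_len(sizes[["validation"]])]
  train <- shuffled[-seq_len(sizes[["heldout"]] + sizes[["validation"]])]
  structure(
    list(train = train, validation = validation, heldout = heldout,
         seed = as.integer(seed)),
    class = "npgen_corpus_split"
  )
}

#' @export
print.npgen_corpus_split <- function(x, ...) {
  cat(sprintf(
    "<npgen_corpus_split: %d train / %d validation / %d heldout (seed %d)>\n",
    length(x$train), length(x$validation), length(x$heldout), x$seed))
  invisible(x)
}

#' Enumerate random SMILES writings of molecules
#'
#' Writes each molecule `k` times from a uniformly chosen random atom
#' ordering (SMILES enumeration, the augmentation used before language-model
#' training). Duplicate writings are permitted for molecules with few
#' distinct writings; every output canonicalizes to the canonical form of
#' its input. Deterministic for a fixed seed.
#'
#' @param smiles Character vector of valid SMILES.
#' @param k Number of writings per molecule (>= 1).
#' @param seed Integer seed.
#' @return A tibble `source` (input SMILES, repeated `k` times each) and
#'   `variant` (the random writing).
#' @export
enumerate_smiles <- function(smiles, k, seed) {
  assert_smiles_strings(smiles)
  if (k < 1) abort("`k` must be >= 1")
  out <- chem_backend("enumerate", smiles,
                      args = c("--k", as.integer(k), "--seed", as.integer(seed)))
  variants <- na_if_empty(out$variant)
  if (anyNA(variants)) {
    abort("invalid SMILES passed to enumerate_smiles")
  }
  tibble(source = rep(smiles, each = as.integer(k)), variant = variants)
}

#' Augment the training and validation partitions with random writings
#'
#' Replaces every molecule of the training and validation partitions by
#' `factor` random SMILES writings (so the counts grow exactly
#' `factor`-fold). The held-out partition is never augmented. Augmentation
#' happens after splitting, so no molecule leaks across partitions.
#'
#' @param split An `npgen_corpus_split`.
#' @param factor Augmentation factor (>= 1); the full-scale pipeline uses 10.
#' @param seed Integer seed.
#' @return List with `train_aug` and `validation_aug` character vectors.
#' @export
augment_corpus <- function(split, factor = 10, seed = 1) {
  stopifnot(inherits(split, "npgen_corpus_split"))
  if (factor < 1) abort("`factor` must be >= 1")
  train_aug <- enumerate_smiles(split$train, factor, seed)$variant
  validation_aug <- if (length(split$validation)) {
    enumerate_smiles(split$validation, factor, seed + 1L)$variant
  } else {
    character(0)
  }
  list(train_aug = train_aug, validation_aug = validation_aug)
}
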