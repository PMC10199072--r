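#' Tokenize SMILES strings
#'
#' Splits a SMILES string into the elemental tokens consumed by the language
#' model: bracket atoms (`[...]`) are single tokens, the two-letter
#' organic-subset halogens `Cl` and `Br` are single tokens, `%NN` ring
#' closures are single tokens, and every other character is its own token.
#' Concatenating the tokens reproduces the input exactly.
#'
#' @param smiles Character vector of SMILES strings.
#' @return A list of character vectors, one per input string.
#' @examples
#' smiles_tokenize("CCl")      # "C" "Cl"
#' smiles_tokenize("C[C@@H]N") # bracket atom is one token
#' @export
smiles_tokenize <- function(smiles) {
  assert_smiles_strings(smiles)
  lapply(smiles, tokenize_one)
}

tokenize_one <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  tokens <- character(0)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) abort(sprintf("dangling '[' in SMILES: %s", s))
      tokens <- c(tokens, paste0(chars[i:j], collapse = ""))
      i <- j + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !all(grepl("[0-9]", chars[(i + 1L):(i + 2L)]))) {
        abort(sprintf("dangling '%%' ring closure in SMILES: %s", s))
      }
      tokens <- c(tokens, paste0(chars[i:(i + 2L)], collapse = ""))
      i <- i + 3L
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1L] %in% c("l", "r") &&
               paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      tokens <- c(tokens, paste0(ch, chars[i + 1L]))
      i <- i + 2L
    } else {
      tokens <- c(tokens, ch)
      i <- i + 1L
    }
  }
  tokens
}

#' Special tokens reserved by every vocabulary
#'
#' `START`, `END` and `PAD` occupy indices 0, 1 and 2 and never appear in
#' the chemical token list.
#' @return Named character vector of the three special tokens.
#' @export
vocab_specials <- function() {
  c(START = "<start>", END = "<end>", PAD = "<pad>")
}

#' Induce a token vocabulary from a SMILES corpus
#'
#' Tokens are the sorted set of all tokens observed in the corpus, preceded
#' by the three specials at reserved indices 0 (`START`), 1 (`END`) and
#' 2 (`PAD`). Construction is deterministic.
#'
#' @param corpus Character vector of SMILES strings (non-empty).
#' @return An object of class `npgen_vocabulary`: a list with `tokens`
#'   (all tokens, specials first; index of a token is its position minus 1)
#'   and `chem_tokens` (tokens excluding specials).
#' @export
build_vocabulary <- function(corpus) {
  if (length(corpus) == 0) abort("cannot build a vocabulary from an empty corpus")
  observed <- sort(unique(unlist(smiles_tokenize(corpus))))
  specials <- unname(vocab_specials())
  if (any(observed %in% specials)) {
    abort("corpus tokens collide with reserved special tokens")
  }
  structure(
    list(tokens = c(specials, observed), chem_tokens = observed),
    class = "npgen_vocabulary"
  )
}

#' @export
print.npgen_vocabulary <- function(x, ...) {
  cat(sprintf("<npgen_vocabulary: %d tokens (%d chemical + 3 special)>\n",
              length(x$tokens), length(x$chem_tokens)))
  cat(strwrap(paste(x$chem_tokens, collapse = " "), width = 70,
              prefix = "  "), sep = "\n")
  invisible(x)
}

#' @export
length.npgen_vocabulary <- function(x) length(x$tokens)

vocab_index <- function(vocab, tokens) {
  idx <- match(tokens, vocab$tokens) - 1L
  if (anyNA(idx)) {
    missing <- unique(tokens[is.na(idx)])
    abort(sprintf("token(s) not in vocabulary: %s",
                  paste(missing, collapse = ", ")),
          class = "npgen_oov_error")
  }
  idx
}

#' Encode SMILES into token-index sequences
#'
#' Each sequence is framed by the `START` (index 0) and `END` (index 1)
#' specials. Encoding a SMILES containing a token absent from the vocabulary
#' raises an error of class `npgen_oov_error` naming the offending token.
#'
#' @param smiles Character vector of SMILES.
#' @param vocab An `npgen_vocabulary`.
#' @return A list of integer vectors (0-based indices).
#' @export
encode_smiles <- function(smiles, vocab) {
  stopifnot(inherits(vocab, "npgen_vocabulary"))
  toks <- smiles_tokenize(smiles)
  lapply(toks, function(tt) c(0L, vocab_index(vocab, tt), 1L))
}

#' Decode a token-index sequence back into a SMILES string
#'
#' @param indices An integer vector (0-based) or a list of them. `START`,
#'   `END` and `PAD` indices are dropped.
#' @param vocab An `npgen_vocabulary`.
#' @return Character vector of SMILES strings.
#' @export
decode_sequence <- function(indices, vocab) {
  stopifnot(inherits(vocab, "npgen_vocabulary"))
  if (!is.list(indices)) indices <- list(indices)
  vapply(indices, function(idx) {
    if (any(idx < 0 | idx >= length(vocab$tokens))) {
      abort("index out of range for vocabulary")
    }
    keep <- idx > 2L
    paste0(vocab$tokens[idx[keep] + 1L], collapse = "")
  }, character(1))
}

#' Persist a vocabulary as plain text (one token per line, specials first)
#'
#' @param vocab An `npgen_vocabulary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vocabulary <- function(vocab, path) {
  stopifnot(inherits(vocab, "npgen_vocabulary"))
  writeLines(vocab$tokens, path, useBytes = TRUE)
  invisible(path)
}

#' Reload a vocabulary written by [write_vocabulary()]
#'
#' @param path Path to the vocabulary file.
#' @return An `npgen_vocabulary`, bit-identical to the one written.
#' @export
read_vocabulary <- function(path) {
  tokens <- readLines(path, warn = FALSE)
  specials <- unname(vocab_specials())
  if (length(tokens) < 3 || !identical(tokens[1:3], specials)) {
    abort("not a vocabulary file: specials missing or out of order")
  }
  structure(
    list(tokens = tokens, chem_tokens = tokens[-(1:3)]),
    class = "npgen_vocabulary"
  )
}
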