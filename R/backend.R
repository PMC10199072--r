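# Bridge to the bundled RDKit batch helper.
#
# Every molecule-level chemistry operation (parsing, canonicalization, InChI,
# stereochemistry removal, random SMILES writings, descriptors, Morgan
# environments, standardization, parent extraction) funnels through one
# Python process per call, exchanging tab-separated tables on stdin/stdout.
# Calls are batch-oriented: callers pass whole SMILES vectors, never loop.

chem_backend_script <- function() {
  path <- system.file("python", "chem_backend.py", package = "npgen")
  if (!nzchar(path)) {
    abort("bundled chem_backend.py not found; is npgen installed correctly?")
  }
  path
}

chem_backend_python <- function() {
  Sys.getenv("NPGEN_PYTHON", unset = "python")
}

#' @noRd
chem_backend <- function(task, smiles, args = character(), extra = NULL) {
  stopifnot(is.character(smiles))
  infile <- tempfile("npgen-in-", fileext = ".tsv")
  outfile <- tempfile("npgen-out-", fileext = ".tsv")
  errfile <- tempfile("npgen-err-", fileext = ".txt")
  on.exit(unlink(c(infile, outfile, errfile)), add = TRUE)

  ids <- seq_along(smiles)
  lines <- if (is.null(extra)) {
    paste(ids, smiles, sep = "\t")
  } else {
    paste(ids, smiles, extra, sep = "\t")
  }
  writeLines(lines, infile, useBytes = TRUE)

  status <- system2(
    chem_backend_python(),
    c(shQuote(chem_backend_script()), task, args),
    stdin = infile, stdout = outfile, stderr = errfile
  )
  if (!identical(status, 0L)) {
    abort(c(
      sprintf("chemistry backend failed (task '%s', exit %d)", task, status),
      utils::tail(readLines(errfile, warn = FALSE), 5)
    ))
  }
  out <- utils::read.delim(outfile, sep = "\t", header = TRUE,
                           colClasses = "character", na.strings = NULL,
                           quote = "", comment.char = "")
  as_tibble(out)
}
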