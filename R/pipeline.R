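# End-to-end orchestration: prepare -> split -> augment -> train -> sample
# -> curate -> score -> evaluate, under one seeded configuration.

#' Build a run configuration
#'
#' Collects everything a full pipeline run needs: the input corpus (a path
#' to a SMILES file or an in-memory character vector), the language-model
#' configuration, curation and evaluation options, and one global seed.
#' Every stochastic stage derives its own seed deterministically from the
#' global seed and the stage name, so single stages can be re-run in
#' isolation and still match the full run.
#'
#' @param corpus Path to a SMILES file (one record per line, optional
#'   tab-separated id) or a character vector of SMILES.
#' @param lm An [lm_config()] for the training stage.
#' @param n_samples Number of strings to sample from the trained model.
#' @param augmentation_factor SMILES-enumeration factor for training and
#'   validation corpora (default 10).
#' @param heldout_fraction,validation_fraction Split fractions
#'   (defaults 0.20 / 0.08; the remainder trains).
#' @param score_radius Fragment radius for the NP-likeness score table.
#' @param kl_bin_width Bin width for the NP-score KL divergence.
#' @param sample_temperature Softmax temperature at the sampling stage.
#' @param reference_corpus Optional character vector of reference (non-NP)
#'   SMILES for the score table; by default the curated generated set
#'   serves as the reference.
#' @param seed Global integer seed.
#' @param out_dir Optional directory; when set, stage outputs (curated
#'   record table, report JSON) are written there.
#' @return A list of class `npgen_run_config`.
#' @export
run_config <- function(corpus, lm = lm_config(), n_samples = 5000,
                       augmentation_factor = 10,
                       heldout_fraction = 0.20, validation_fraction = 0.08,
                       score_radius = 2, kl_bin_width = 0.1,
                       sample_temperature = 1.0, reference_corpus = NULL,
                       seed = 1, out_dir = NULL) {
  stopifnot(inherits(lm, "npgen_lm_config"))
  if (n_samples < 1) abort("`n_samples` must be >= 1")
  if (heldout_fraction + validation_fraction >= 1) {
    abort("split fractions must leave a non-empty training partition")
  }
  structure(
    list(corpus = corpus, lm = lm, n_samples = as.integer(n_samples),
         augmentation_factor = as.integer(augmentation_factor),
         heldout_fraction = heldout_fraction,
         validation_fraction = validation_fraction,
         score_radius = as.integer(score_radius),
         kl_bin_width = kl_bin_width,
         sample_temperature = sample_temperature,
         reference_corpus = reference_corpus,
         seed = as.integer(seed), out_dir = out_dir),
    class = "npgen_run_config"
  )
}

#' Read / write a run configuration as YAML
#'
#' The YAML file carries the same fields as [run_config()], with the
#' language-model block nested under `lm:`. Unspecified fields take the
#' constructor defaults.
#'
#' @param path Path to a YAML file.
#' @return An `npgen_run_config`; `write_run_config()` returns `path`
#'   invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  lm <- do.call(lm_config, raw$lm %||% list())
  raw$lm <- NULL
  do.call(run_config, c(raw, list(lm = lm)))
}

#' @rdname read_run_config
#' @param config An `npgen_run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "npgen_run_config"))
  payload <- unclass(config)
  payload$lm <- unclass(payload$lm)
  payload <- payload[!vapply(payload, is.null, logical(1))]
  yaml::write_yaml(payload, path)
  invisible(path)
}

# deterministic per-stage seed: global seed offset by a hash of the stage
# name, so stages are decoupled but individually reproducible
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage))) %% 99991L
  as.integer((seed + h) %% .Machine$integer.max)
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e)),
          class = "npgen_pipeline_error")
  })
}

#' Run the full generate-curate-characterize pipeline
#'
#' Executes, in order: corpus preparation (validity, stereo strip, dedup),
#' splitting, enumeration augmentation, language-model training, sampling,
#' curation of the samples, NP-likeness scoring, and evaluation (NP-score
#' KL divergence against the training set, held-out recovery). Each stage
#' logs its input/output counts; any stage error aborts naming the stage.
#' Fully deterministic under `config$seed`.
#'
#' @param config An [run_config()] object.
#' @param quiet Suppress per-stage progress messages (default `FALSE`).
#' @return A list of class `npgen_run_report`: `counts` (one-row tibble
#'   whose fields satisfy `n_sampled = n_valid + n_syntactic_invalid`,
#'   `n_valid = n_unique + n_duplicates`, and
#'   `n_unique = n_curated + n_checker_removed`), `metrics` (one-row
#'   tibble: `validity_pct`, `uniqueness_pct`, `best_validation_loss`,
#'   `np_score_kl_nats`, `heldout_recovery_rate`, mean NP scores),
#'   `model` (the fitted `npgen_lm`), `curation` (the [curate()] result),
#'   `np_scores` (tibble of generated-molecule scores) and `config`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "npgen_run_config"))
  say <- function(...) if (!quiet) inform(sprintf(...))

  corpus_raw <- pipeline_stage("prepare", {
    x <- config$corpus
    looks_like_path <- is.character(x) && length(x) == 1 &&
      grepl("[.]smi$|[.]txt$|/", x)
    smiles <- if (looks_like_path) {
      if (!file.exists(x)) abort(sprintf("corpus file not found: %s", x))
      read_smiles_file(x)$smiles
    } else {
      x
    }
    if (!is.character(smiles) || length(smiles) == 0) {
      abort("corpus must be a non-empty character vector or an existing file")
    }
    smiles
  })
  corpus <- pipeline_stage("prepare", prepare_corpus(corpus_raw, quiet = quiet))
  say("prepare: %d records in, %d kept", length(corpus_raw), length(corpus))

  split <- pipeline_stage("split", split_corpus(
    corpus, heldout_fraction = config$heldout_fraction,
    validation_fraction = config$validation_fraction,
    seed = stage_seed(config$seed, "split")))
  say("split: %d train / %d validation / %d heldout",
      length(split$train), length(split$validation), length(split$heldout))

  aug <- pipeline_stage("augment", augment_corpus(
    split, factor = config$augmentation_factor,
    seed = stage_seed(config$seed, "augment")))
  say("augment: x%d -> %d train / %d validation strings",
      config$augmentation_factor, length(aug$train_aug),
      length(aug$validation_aug))

  lm_cfg <- config$lm
  lm_cfg$seed <- stage_seed(config$seed, "train")
  model <- pipeline_stage("train",
                          lm_train(aug$train_aug, aug$validation_aug, lm_cfg))
  say("train: best validation loss %.4f nats/token",
      model$best_validation_loss)

  sampled <- pipeline_stage("sample", lm_sample(
    model, config$n_samples, seed = stage_seed(config$seed, "sample"),
    temperature = config$sample_temperature))
  say("sample: %d strings drawn", length(sampled))

  cur <- pipeline_stage("curate", curate(sampled))
  s <- cur$summary
  say("curate: %d invalid, %d duplicates, %d checker-removed, %d kept",
      s$n_syntactic_invalid, s$n_duplicates, s$n_checker_removed, s$n_output)

  scores <- pipeline_stage("score", {
    # the score table needs a reference (non-NP) corpus; when the run
    # supplies none, the curated generated set stands in as reference so
    # contributions discriminate training-corpus chemical space
    reference <- config$reference_corpus %||%
      (if (nrow(cur$records)) cur$records$canonical_smiles else split$heldout)
    table <- train_score_table(split$train, reference,
                               radius = config$score_radius)
    list(table = table,
         train = np_score(split$train, table),
         generated = if (nrow(cur$records))
           np_score(cur$records$canonical_smiles, table)
         else tibble(smiles = character(), np_score = numeric()))
  })
  say("score: %d generated molecules scored", nrow(scores$generated))

  metrics <- pipeline_stage("evaluate", {
    kl <- if (nrow(scores$generated) > 0) {
      kl_divergence(make_distribution(scores$train$np_score,
                                      scores$generated$np_score,
                                      bin_width = config$kl_bin_width))
    } else NA_real_
    recovery <- if (nrow(cur$records) > 0) {
      recovery_rate(cur$records$canonical_smiles, split$heldout)
    } else 0
    tibble(
      validity_pct = 100 * (s$n_input - s$n_syntactic_invalid) / s$n_input,
      uniqueness_pct = if (s$n_input - s$n_syntactic_invalid > 0) {
        100 * (s$n_input - s$n_syntactic_invalid - s$n_duplicates) /
          (s$n_input - s$n_syntactic_invalid)
      } else NA_real_,
      best_validation_loss = model$best_validation_loss,
      np_score_kl_nats = kl,
      heldout_recovery_rate = recovery,
      mean_np_score_train = mean(scores$train$np_score),
      mean_np_score_generated = if (nrow(scores$generated))
        mean(scores$generated$np_score) else NA_real_
    )
  })

  counts <- tibble(
    n_corpus_input = length(corpus_raw),
    n_corpus_prepared = length(corpus),
    n_train = length(split$train),
    n_validation = length(split$validation),
    n_heldout = length(split$heldout),
    n_train_augmented = length(aug$train_aug),
    n_sampled = s$n_input,
    n_syntactic_invalid = s$n_syntactic_invalid,
    n_valid = s$n_input - s$n_syntactic_invalid,
    n_duplicates = s$n_duplicates,
    n_unique = s$n_input - s$n_syntactic_invalid - s$n_duplicates,
    n_checker_removed = s$n_checker_removed,
    n_curated = s$n_output
  )
  stopifnot(
    counts$n_sampled == counts$n_valid + counts$n_syntactic_invalid,
    counts$n_valid == counts$n_unique + counts$n_duplicates,
    counts$n_unique == counts$n_curated + counts$n_checker_removed
  )

  report <- structure(
    list(counts = counts, metrics = metrics, model = model, curation = cur,
         np_scores = scores$generated, score_table = scores$table,
         config = config),
    class = "npgen_run_report"
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_record_table(cur$records,
                       file.path(config$out_dir, "curated_records.jsonl"))
    jsonlite::write_json(
      c(as.list(counts), as.list(metrics)),
      file.path(config$out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.npgen_run_report <- function(x, ...) {
  c_ <- x$counts
  m <- x$metrics
  cat("<npgen_run_report>\n")
  cat(sprintf("  corpus: %d prepared (of %d); split %d/%d/%d\n",
              c_$n_corpus_prepared, c_$n_corpus_input, c_$n_train,
              c_$n_validation, c_$n_heldout))
  cat(sprintf("  sampled %d: %d invalid, %d duplicates, %d checker-removed, %d curated\n",
              c_$n_sampled, c_$n_syntactic_invalid, c_$n_duplicates,
              c_$n_checker_removed, c_$n_curated))
  cat(sprintf("  validity %.1f%%, uniqueness %.1f%%, NP-score KL %.4f nats, recovery %.3f\n",
              m$validity_pct, m$uniqueness_pct, m$np_score_kl_nats,
              m$heldout_recovery_rate))
  invisible(x)
}

#' @export
tidy.npgen_run_report <- function(x, ...) {
  tidyr::pivot_longer(dplyr::bind_cols(x$counts, x$metrics),
                      cols = dplyr::everything(),
                      names_to = "quantity", values_to = "value")
}

#' @export
glance.npgen_run_report <- function(x, ...) {
  dplyr::bind_cols(x$counts[c("n_sampled", "n_curated")], x$metrics)
}
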