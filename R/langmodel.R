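#' Language-model training configuration
#'
#' Defaults follow the full-scale training setup: a 3-layer LSTM with
#' hidden dimension 512 and no dropout, batch size 128, learning rate
#' 0.001 with the Adam optimizer, at most 1,000 epochs, and early stopping
#' after 10,000 minibatches without validation improvement. The embedding
#' dimension (128), validation cadence (every 500 minibatches) and sampling
#' length cap (250 tokens) are package defaults, all exposed here.
#'
#' @param n_layers,hidden_dim,embedding_dim Network architecture.
#' @param batch_size,learning_rate,max_epochs Optimization settings.
#' @param patience_minibatches Early-stopping patience, counted in
#'   minibatches.
#' @param eval_every_minibatches Validation-loss evaluation cadence.
#' @param max_sample_length Token cap for autoregressive sampling.
#' @param seed Integer seed covering initialization and minibatch order.
#' @return A list of class `npgen_lm_config`.
#' @export
lm_config <- function(n_layers = 3, hidden_dim = 512, embedding_dim = 128,
                      batch_size = 128, learning_rate = 0.001,
                      max_epochs = 1000, patience_minibatches = 10000,
                      eval_every_minibatches = 500, max_sample_length = 250,
                      seed = 1) {
  cfg <- list(
    n_layers = as.integer(n_layers), hidden_dim = as.integer(hidden_dim),
    embedding_dim = as.integer(embedding_dim),
    batch_size = as.integer(batch_size), learning_rate = learning_rate,
    max_epochs = as.integer(max_epochs),
    patience_minibatches = as.integer(patience_minibatches),
    eval_every_minibatches = as.integer(eval_every_minibatches),
    max_sample_length = as.integer(max_sample_length),
    seed = as.integer(seed)
  )
  counts <- unlist(cfg[c("n_layers", "hidden_dim", "embedding_dim",
                         "batch_size", "max_epochs", "patience_minibatches",
                         "eval_every_minibatches", "max_sample_length")])
  if (any(counts <= 0) || cfg$learning_rate <= 0) {
    abort("all configuration counts and the learning rate must be positive")
  }
  structure(cfg, class = "npgen_lm_config")
}

encode_corpus <- function(smiles, vocab, what) {
  tryCatch(
    encode_smiles(smiles, vocab),
    npgen_oov_error = function(e) {
      abort(c(sprintf("out-of-vocabulary token in %s corpus", what),
              conditionMessage(e)), class = "npgen_oov_error")
    }
  )
}

#' Train the SMILES language model
#'
#' Teacher-forced next-token training (cross-entropy in nats/token, PAD
#' positions masked) with Adam; the validation loss is evaluated every
#' `eval_every_minibatches` minibatches and the parameters at the best
#' validation loss are returned. Training stops at `max_epochs` or when the
#' validation loss has not improved for `patience_minibatches` minibatches.
#' Fully deterministic under `config$seed`.
#'
#' @param train_smiles,validation_smiles Character vectors of (augmented)
#'   training and validation SMILES.
#' @param config An [lm_config()].
#' @param vocab Optional `npgen_vocabulary`; by default built from the
#'   union of the two corpora.
#' @return An object of class `npgen_lm`: list with `params` (learned
#'   weights), `config`, `vocab`, `best_validation_loss` (nats/token) and
#'   `training_log` (tibble `minibatch`, `train_loss`, `validation_loss`).
#' @export
lm_train <- function(train_smiles, validation_smiles, config = lm_config(),
                     vocab = NULL) {
  stopifnot(inherits(config, "npgen_lm_config"))
  if (length(train_smiles) == 0 || length(validation_smiles) == 0) {
    abort("training and validation corpora must be non-empty")
  }
  vocab <- vocab %||% build_vocabulary(c(train_smiles, validation_smiles))
  train_seqs <- encode_corpus(train_smiles, vocab, "training")
  valid_seqs <- encode_corpus(validation_smiles, vocab, "validation")
  params <- cpp_lstm_init(length(vocab), config$embedding_dim,
                          config$hidden_dim, config$n_layers, config$seed)
  fit <- cpp_lstm_train(params, train_seqs, valid_seqs,
                        config$batch_size, config$learning_rate,
                        config$max_epochs, config$patience_minibatches,
                        config$eval_every_minibatches, config$seed)
  structure(
    list(params = fit$params, config = config, vocab = vocab,
         best_validation_loss = fit$best_validation_loss,
         training_log = as_tibble(fit$log)),
    class = "npgen_lm"
  )
}

#' Create an untrained language model (random initialization)
#'
#' Useful as a baseline: with its near-zero output projection the untrained
#' model predicts (almost) uniformly, so its loss is close to `ln(V)`
#' nats/token for a vocabulary of `V` tokens.
#'
#' @inheritParams lm_train
#' @param vocab An `npgen_vocabulary`.
#' @return An `npgen_lm` with empty training log.
#' @export
lm_untrained <- function(vocab, config = lm_config()) {
  stopifnot(inherits(vocab, "npgen_vocabulary"),
            inherits(config, "npgen_lm_config"))
  params <- cpp_lstm_init(length(vocab), config$embedding_dim,
                          config$hidden_dim, config$n_layers, config$seed)
  structure(
    list(params = params, config = config, vocab = vocab,
         best_validation_loss = NA_real_,
         training_log = tibble(minibatch = numeric(), train_loss = numeric(),
                               validation_loss = numeric())),
    class = "npgen_lm"
  )
}

#' @export
print.npgen_lm <- function(x, ...) {
  cat(sprintf(
    "<npgen_lm: %d-layer LSTM, hidden %d, vocabulary %d tokens>\n",
    x$config$n_layers, x$config$hidden_dim, length(x$vocab)))
  if (!is.na(x$best_validation_loss)) {
    cat(sprintf("  best validation loss: %.4f nats/token (%d evaluations)\n",
                x$best_validation_loss, nrow(x$training_log)))
  } else {
    cat("  untrained\n")
  }
  invisible(x)
}

#' @export
tidy.npgen_lm <- function(x, ...) x$training_log

#' @export
glance.npgen_lm <- function(x, ...) {
  tibble(
    n_layers = x$config$n_layers,
    hidden_dim = x$config$hidden_dim,
    vocab_size = length(x$vocab),
    n_parameters = sum(vapply(
      Filter(is.matrix, x$params), length, numeric(1))),
    best_validation_loss = x$best_validation_loss,
    n_evaluations = nrow(x$training_log)
  )
}

#' Sample SMILES strings from a language model
#'
#' Generates each string autoregressively from the START token by
#' multinomial draws over the next-token distribution (logits scaled by
#' `temperature`; `temperature = 0` gives greedy argmax decoding) until END
#' or `max_sample_length` tokens. Returns exactly `n` strings; syntactic
#' validity is *not* guaranteed and must be established by curation.
#'
#' @param model An `npgen_lm`.
#' @param n Number of samples (>= 1).
#' @param seed Integer seed.
#' @param temperature Softmax temperature (default 1.0).
#' @return Character vector of `n` sampled strings (possibly invalid,
#'   possibly empty).
#' @export
lm_sample <- function(model, n, seed = 1, temperature = 1.0) {
  stopifnot(inherits(model, "npgen_lm"))
  if (n < 1) abort("`n` must be >= 1")
  seqs <- cpp_lstm_sample(model$params, as.integer(n),
                          model$config$max_sample_length, temperature,
                          as.integer(seed))
  purrr::map_chr(seqs, function(idx) {
    paste0(model$vocab$tokens[idx + 1L], collapse = "")
  })
}

#' Mean per-token cross-entropy of a corpus under a model (nats/token)
#'
#' @param model An `npgen_lm`.
#' @param smiles Character vector of SMILES encodable under the model's
#'   vocabulary.
#' @return Mean next-token negative log-likelihood in nats per token.
#' @export
lm_evaluate_loss <- function(model, smiles) {
  stopifnot(inherits(model, "npgen_lm"))
  if (length(smiles) == 0) abort("corpus must be non-empty")
  seqs <- encode_corpus(smiles, model$vocab, "evaluation")
  cpp_lstm_loss(model$params, seqs, model$config$batch_size)
}

#' Next-token probability distribution after a prefix
#'
#' Exposes the model's per-step predictive distribution (used, e.g., to
#' verify the batched loss against a direct probability walk).
#'
#' @param model An `npgen_lm`.
#' @param prefix_tokens Character vector of tokens already consumed
#'   (without specials); the START token is prepended automatically.
#' @return Named numeric vector over the vocabulary, summing to 1.
#' @export
lm_step_probs <- function(model, prefix_tokens = character(0)) {
  stopifnot(inherits(model, "npgen_lm"))
  idx <- c(0L, if (length(prefix_tokens)) vocab_index(model$vocab, prefix_tokens))
  probs <- cpp_lstm_step_probs(model$params, idx)
  stats::setNames(probs, model$vocab$tokens)
}

#' Save / load a fitted language model
#'
#' The checkpoint is a plain-JSON file carrying the configuration, the
#' vocabulary and all weight matrices at full precision.
#'
#' @param model An `npgen_lm`.
#' @param path Output path (`.json`).
#' @return `path` invisibly; `lm_load()` returns the restored `npgen_lm`.
#' @export
lm_save <- function(model, path) {
  stopifnot(inherits(model, "npgen_lm"))
  mats <- Filter(is.matrix, model$params)
  payload <- list(
    config = unclass(model$config),
    vocab = model$vocab$tokens,
    n_layers = model$params$n_layers,
    best_validation_loss = model$best_validation_loss,
    training_log = as.list(model$training_log),
    weights = lapply(mats, function(m) list(dim = dim(m), data = as.numeric(m)))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname lm_save
#' @export
lm_load <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(payload$weights, function(w) {
    matrix(w$data, nrow = w$dim[1], ncol = w$dim[2])
  })
  params$n_layers <- as.integer(payload$n_layers)
  vocab <- structure(
    list(tokens = payload$vocab, chem_tokens = payload$vocab[-(1:3)]),
    class = "npgen_vocabulary"
  )
  structure(
    list(params = params, config = do.call(lm_config, as.list(payload$config)),
         vocab = vocab,
         best_validation_loss = payload$best_validation_loss,
         training_log = as_tibble(payload$training_log)),
    class = "npgen_lm"
  )
}
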