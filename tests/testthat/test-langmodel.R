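small_cfg <- function(...) {
  lm_config(n_layers = 1, hidden_dim = 32, embedding_dim = 16,
            batch_size = 8, learning_rate = 0.01, max_epochs = 50,
            patience_minibatches = 400, eval_every_minibatches = 10,
            max_sample_length = 60, seed = 11, ...)
}

test_that("lm_config validates its fields", {
  expect_error(lm_config(hidden_dim = 0), "positive")
  expect_error(lm_config(learning_rate = -1), "positive")
  expect_s3_class(lm_config(), "npgen_lm_config")
  expect_equal(lm_config()$n_layers, 3L)
  expect_equal(lm_config()$hidden_dim, 512L)
})

test_that("untrained model loss is ln(V) within 5%", {
  vocab <- build_vocabulary(np_fixture_smiles()[1:20])
  model <- lm_untrained(vocab, small_cfg())
  loss <- lm_evaluate_loss(model, np_fixture_smiles()[1:20])
  expect_equal(loss, log(length(vocab)), tolerance = 0.05)
})

test_that("batched loss equals a direct per-token probability walk", {
  vocab <- build_vocabulary(c("CCO", "CNC"))
  model <- lm_untrained(vocab, small_cfg())
  walk_nll <- function(smiles) {
    toks <- c(smiles_tokenize(smiles)[[1]], vocab_specials()[["END"]])
    prefix <- character(0)
    nll <- 0
    for (tok in toks) {
      p <- lm_step_probs(model, prefix)
      nll <- nll - log(p[[tok]])
      if (tok != vocab_specials()[["END"]]) prefix <- c(prefix, tok)
    }
    c(nll = nll, n = length(toks))
  }
  w1 <- walk_nll("CCO")
  w2 <- walk_nll("CNC")
  direct <- (w1[["nll"]] + w2[["nll"]]) / (w1[["n"]] + w2[["n"]])
  expect_equal(lm_evaluate_loss(model, c("CCO", "CNC")), direct,
               tolerance = 1e-10)
})

test_that("analytic gradient matches finite differences", {
  vocab <- build_vocabulary(c("CCO", "CNO"))
  cfg <- small_cfg()
  params <- npgen:::cpp_lstm_init(length(vocab), 4L, 6L, 2L, 3L)
  seqs <- encode_smiles(c("CCO", "CNO"), vocab)
  grad <- npgen:::cpp_lstm_grad(params, seqs)
  eps <- 1e-6
  for (key in c("E", "W1", "U2", "b1", "Wy", "by")) {
    m <- params[[key]]
    for (flat in c(1L, length(m))) {
      bump <- function(sign) {
        p2 <- params
        p2[[key]][flat] <- p2[[key]][flat] + sign * eps
        npgen:::cpp_lstm_loss(p2, seqs, 8L)
      }
      numeric_grad <- (bump(1) - bump(-1)) / (2 * eps)
      expect_equal(grad[[key]][flat], numeric_grad, tolerance = 1e-4)
    }
  }
})

test_that("training is deterministic under the seed and improves the loss", {
  corpus <- np_fixture_smiles()[1:20]
  cfg <- small_cfg()
  cfg$max_epochs <- 5L
  f1 <- lm_train(corpus, corpus, cfg)
  f2 <- lm_train(corpus, corpus, cfg)
  expect_identical(f1$params$Wy, f2$params$Wy)
  expect_identical(f1$best_validation_loss, f2$best_validation_loss)
  vocab <- build_vocabulary(corpus)
  expect_lt(f1$best_validation_loss,
            lm_evaluate_loss(lm_untrained(vocab, cfg), corpus))
})

test_that("a converged model memorizes a one-string corpus", {
  cfg <- lm_config(n_layers = 1, hidden_dim = 32, embedding_dim = 16,
                   batch_size = 4, learning_rate = 0.01, max_epochs = 400,
                   patience_minibatches = 4000, eval_every_minibatches = 50,
                   max_sample_length = 20, seed = 5)
  corpus <- rep("CCO", 4)
  fit <- lm_train(corpus, corpus, cfg)
  samples <- lm_sample(fit, 100, seed = 21)
  expect_gte(sum(samples == "CCO"), 95)
})

test_that("sampling respects n, the length cap and greedy decoding", {
  vocab <- build_vocabulary(np_fixture_smiles()[1:10])
  model <- lm_untrained(vocab, small_cfg())
  s <- lm_sample(model, 25, seed = 3)
  expect_length(s, 25L)
  max_tokens <- model$config$max_sample_length
  expect_true(all(lengths(lapply(s, function(x)
    if (nzchar(x)) smiles_tokenize(x)[[1]] else character(0))) <= max_tokens))
  g1 <- lm_sample(model, 5, seed = 1, temperature = 0)
  g2 <- lm_sample(model, 5, seed = 99, temperature = 0)
  expect_identical(g1, g2)           # greedy decoding ignores the seed
  expect_identical(lm_sample(model, 10, seed = 4), lm_sample(model, 10, seed = 4))
})

test_that("checkpoints round-trip through JSON", {
  corpus <- np_fixture_smiles()[1:10]
  cfg <- small_cfg()
  cfg$max_epochs <- 2L
  fit <- lm_train(corpus, corpus, cfg)
  path <- withr::local_tempfile(fileext = ".json")
  lm_save(fit, path)
  back <- lm_load(path)
  expect_equal(back$params$Wy, fit$params$Wy)
  expect_equal(back$vocab$tokens, fit$vocab$tokens)
  expect_equal(lm_evaluate_loss(back, corpus), lm_evaluate_loss(fit, corpus))
  expect_identical(lm_sample(back, 5, seed = 2), lm_sample(fit, 5, seed = 2))
})

test_that("out-of-vocabulary corpora are rejected with the stage named", {
  vocab <- build_vocabulary("CCO")
  model <- lm_untrained(vocab, small_cfg())
  expect_error(lm_evaluate_loss(model, "CCS"), "evaluation")
})
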