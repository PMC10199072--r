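# npgen

Generation, curation and characterization of natural-product-like
compound libraries.

Natural products occupy regions of chemical space that typical synthetic
screening collections barely touch, which makes them valuable templates
for drug discovery — and makes *expanding* natural-product-like chemical
space a useful goal in itself. npgen implements the workflow that does
this with a generative language model:

1. **Prepare** a corpus of natural-product SMILES (four-stage validity,
   stereochemistry removal, deduplication), split it 72/8/20 into
   training/validation/held-out partitions, and augment the training
   strings tenfold by SMILES enumeration.
2. **Train** a token-level LSTM language model on the augmented strings
   (teacher forcing, PAD-masked cross-entropy in nats/token, Adam with
   gradient clipping, early stopping on validation loss).
3. **Sample** new SMILES autoregressively and **curate** them: syntactic
   validity, canonical-SMILES/InChI deduplication, structure-quality
   checking against a penalty rule table (penalties above 5 are fatal),
   standardization, and parent extraction — with every record accounted
   for by an exact conservation identity.
4. **Characterize** the library against the training distribution:
   natural-product-likeness scores from atom-centred fragment
   frequencies, KL divergence between score distributions, held-out
   recovery, descriptor panels, and t-SNE chemical-space density maps.

Molecule-level chemistry (parsing, canonicalization, InChI, descriptors,
enumeration, standardization) is delegated to RDKit through a bundled
Python batch script; everything else is R and C++ (RcppArmadillo for the
LSTM).

## Worked example

At desk scale the package generates its own study corpus: seeded
assembly of NP-like molecules (sugar rings, phenols, lactones,
polyketide chains) that are valid and unique by construction. The
following runs the full workflow in about ten minutes on one CPU; all
output below is real.

```r
library(npgen)

corpus <- generate_corpus(fixture_spec(2000, seed = 1))$smiles
head(corpus, 3)
#> [1] "CCC1OC(=O)CC1CC(O)Cc1ccco1"     "CCCCOCOC1CCC(=O)O1"
#> [3] "O=C1CC(CC(O)Cc2cc(O)ccc2CO)CO1"

split <- split_corpus(corpus, seed = 1)
split
#> <npgen_corpus_split: 1440 train / 160 validation / 400 heldout (seed 1)>

aug <- augment_corpus(split, factor = 10, seed = 1)
length(aug$train_aug)
#> [1] 14400

cfg <- lm_config(n_layers = 1, hidden_dim = 64, embedding_dim = 64,
                 batch_size = 64, learning_rate = 0.003, max_epochs = 30,
                 eval_every_minibatches = 225)
fit <- lm_train(aug$train_aug, aug$validation_aug, cfg)
fit
#> <npgen_lm: 1-layer LSTM, hidden 64, vocabulary 16 tokens>
#>   best validation loss: 0.5743 nats/token (30 evaluations)

sampled <- lm_sample(fit, 5000, seed = 7)
head(sampled, 3)
#> [1] "C(CC(O)C)C(C(C)C1CC(=O)OC1)O"  "C(C)C(C1COC(=O)C1)=O"
#> [3] "OC1C(O)C(O)C(CO)OCC1OCOCC(O)C"

res <- curate(sampled)
res$summary
#> # A tibble: 1 × 5
#>   n_input n_syntactic_invalid n_duplicates n_checker_removed n_output
#>     <int>               <int>        <int>             <int>    <int>
#> 1    5000                1065          186                 0     3749

tab <- train_score_table(split$train, res$records$canonical_smiles)
pair <- make_distribution(np_score(split$train, tab)$np_score,
                          np_score(res$records$canonical_smiles, tab)$np_score)
kl_divergence(pair)
#> [1] 1.528226

recovery_rate(res$records$canonical_smiles, split$heldout)
#> [1] 0.055
```

78.7% of the raw samples are syntactically valid, the model re-generates
5.5% of molecules it never saw during training, and every input record is
accounted for: `5000 = 1065 invalid + 186 duplicates + 0 checker-removed
+ 3749 curated`. The full-scale configuration (`lm_config()` defaults:
3 layers, hidden 512, batch 128) is sized for corpora of hundreds of
thousands of natural products; at desk scale the 1×64 model above is the
package's reference configuration (see the vignette for the rationale and
limitations).

`run_pipeline(run_config(...))` performs all of the above as one seeded,
logged run, and `inst/cli/npgen` exposes each stage as a subcommand:

```sh
npgen fixtures --n 2000 --seed 1 --out corpus.smi --manifest manifest.jsonl
npgen run --config run.yaml --out-dir results/
```

## Package layout

- `R/` — corpus I/O and identifiers (`chemio`), tokenizer and vocabulary,
  corpus preparation/splitting/augmentation, LSTM language model,
  curation cascade, NP-likeness scoring, evaluation metrics and
  embeddings, synthetic fixture generator, pipeline orchestration, ggplot
  helpers.
- `src/` — the LSTM (forward, full BPTT, Adam, sampling) in
  RcppArmadillo.
- `inst/python/chem_backend.py` — the RDKit batch helper.
- `inst/cli/npgen` — command-line front end.
- `tests/testthat/` — oracle-based test suite; `test-acceptance.R` holds
  the headline acceptance properties.
- `vignettes/` — methods vignette describing the science and the
  package's parameter choices.
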