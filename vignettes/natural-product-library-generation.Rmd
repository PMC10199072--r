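---
title: "Generating and curating natural-product-like compound libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating and curating natural-product-like compound libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

npgen implements a generate–curate–characterize workflow for
natural-product-like (NP-like) molecules: a SMILES-level LSTM language
model is trained on a corpus of known natural products, new SMILES are
sampled from it, the samples are curated into a clean library, and the
library is characterized against the training distribution. This vignette
explains each stage, the parameters the package fixes, and the choices it
makes at desk scale.

## 1. The corpus and its preparation

The workflow starts from a corpus of natural-product SMILES.
`prepare_corpus()` applies three operations:

1. **Four-stage validity.** A string counts as valid only if it parses to
   a molecular graph *and* yields a canonical SMILES, an InChI, and an
   InChIKey (`parse_and_validate()`). Failing any stage marks the record
   invalid; invalidity is a result, not an error.
2. **Stereochemistry removal.** SMILES language models are usually
   trained on stereo-free strings, so `strip_stereochemistry()` removes
   tetrahedral and double-bond stereo-descriptors and re-canonicalizes.
3. **Deduplication.** Records are unique by canonical SMILES.

`split_corpus()` then partitions the corpus 72% / 8% / 20% into training,
validation and held-out sets. Partition sizes use round-half-up on the
held-out and validation fractions, with the training set taking the
remainder, so the three sizes always sum to the corpus size:

```{r}
library(npgen)
split_sizes(406919)
#> train validation    heldout
#> 292981      32554      81384
```

Before training, the training and validation partitions are augmented
tenfold by SMILES enumeration (`augment_corpus()`): each molecule is
rewritten from 10 random atom orderings. Every variant canonicalizes back
to its source molecule, so augmentation enlarges the string corpus without
changing its chemistry. The held-out partition is never augmented, and
augmentation happens after splitting, so no molecule leaks across
partitions.

## 2. Tokenization

`smiles_tokenize()` splits SMILES into the units the model predicts:
bracket atoms (`[C@@H]`, `[nH]`, ...) are single tokens, the two-letter
halogens `Cl`/`Br` are single tokens, `%NN` ring closures are single
tokens, and every other character stands alone. Concatenating the tokens
reproduces the input exactly. A vocabulary built with `build_vocabulary()`
reserves `<start>`, `<end>` and `<pad>` at indices 0–2 and sorts the
chemical tokens after them; encoding frames each string as
`<start> … <end>`.

## 3. The language model

`lm_train()` fits a multi-layer LSTM by teacher forcing: at each position
the network predicts the next token, and the loss is the PAD-masked
cross-entropy in nats per token. Optimization uses Adam with gradient
clipping at global norm 5. The validation loss is evaluated on a fixed
cadence, the parameters at the best validation loss are kept, and
training stops early when validation has not improved for a set number of
minibatches.

The `lm_config()` defaults mirror the full-scale setup: 3 layers, hidden
dimension 512, no dropout, batch size 128, learning rate 0.001, at most
1,000 epochs, and early-stopping patience of 10,000 minibatches. That
configuration is sized for a corpus of hundreds of thousands of molecules
and GPU-scale training; at full scale it reaches a best validation loss
of roughly 0.55 nats/token.

**Desk-scale configuration.** On a 2,000-molecule synthetic corpus
(14,400 augmented training strings) a 3×512 network trains far too slowly
on one CPU to be useful. The package's scaled-down reference
configuration is therefore:

```{r}
cfg <- lm_config(n_layers = 1, hidden_dim = 64, embedding_dim = 64,
                 batch_size = 64, learning_rate = 0.003, max_epochs = 30,
                 eval_every_minibatches = 225)
```

One layer with hidden dimension 64 converges in minutes where deeper
stacks stall in their warm-up phase; the learning rate was picked from a
coarse short-horizon probe over {1e-3, 3e-3}, and 30 epochs fits a
roughly 8-minute CPU budget. Under these settings the model reaches a
validation loss near 0.57 nats/token and about three quarters of its
samples are syntactically valid — a deliberately soft mirror of the
full-scale behaviour (the published full-scale run reports 89–90%
validity), not a reproduction of it.

`lm_sample()` generates strings autoregressively from `<start>` by
multinomial draws over the temperature-scaled next-token distribution
(temperature 0 gives greedy decoding), stopping at `<end>` or a 250-token
cap. Sampled strings are raw: validity is established afterwards by
curation, never assumed.

## 4. Curation

`curate()` turns raw samples into a library and accounts for every
record:

1. four-stage syntactic validity (empty and malformed strings count as
   invalid);
2. stereochemistry removal;
3. deduplication by canonical SMILES *or* InChI (either key matching an
   earlier record removes the newcomer);
4. structure-quality checking against the rule table in
   `checker_rules()`;
5. standardization (functional-group normalization plus neutralization);
6. parent extraction (salt/solvent stripping against a packaged drop
   list, largest-fragment selection, isotope clearing).

The checker grades issues by penalty: 2 for cosmetic findings that later
stages resolve or that are expected of stereo-free generated molecules
(undefined stereocentres, ionizable sites, isotope labels, counter-ion
fragments), 5 for an identifier round-trip mismatch, and 6–7 for severe
defects (valence violations, identifier failures, unsupported elements).
Records whose maximum penalty exceeds 5 are removed, as are records left
with no parent fragment. The check runs before standardization so the
recorded error types describe structures as generated.

The summary counts always satisfy the conservation identity

```
n_output = n_input - n_syntactic_invalid - n_duplicates - n_checker_removed
```

and `run_pipeline()` additionally reports them as
`n_sampled = n_valid + n_syntactic_invalid`,
`n_valid = n_unique + n_duplicates`,
`n_unique = n_curated + n_checker_removed`.

## 5. Natural-product-likeness

`train_score_table()` learns per-fragment contributions from an NP corpus
and a reference (non-NP) corpus. Fragments are atom-centred circular
environments of radius 2 bonds, one per heavy atom, invariant under atom
renumbering. Each fragment's contribution is the Laplace-smoothed
log-odds of appearing in NP versus reference space:

```
log10( ((m_np + 1) / (N_np + 1)) / ((m_ref + 1) / (N_ref + 1)) )
```

where `m` counts molecules containing the fragment and `N` the corpus
sizes. `np_score()` sums contributions over a molecule's fragments,
normalizes by heavy-atom count, and compresses tails beyond ±4
logarithmically (`compress_score_tails()`), keeping scores in roughly
[-5, 5]. The construction makes the score antisymmetric under swapping
the two training corpora and invariant to the SMILES writing of a
molecule — both properties are enforced by tests.

## 6. Characterization

The generated library is compared to the training distribution with:

- **KL divergence** (`kl_divergence()`) between binned NP-score
  distributions, `D(P‖Q) = Σ P ln(P/Q)` over P's support, bins of width
  0.1 anchored at 0. When a bin has `P > 0` but `Q = 0`, one pseudo-count
  is added to every candidate bin in P's support and Q is renormalized —
  a documented smoothing that requires the pair to carry counts.
- **Held-out recovery** (`recovery_rate()`): the fraction of held-out
  molecules that the model re-generated, an indicator that it learned the
  underlying chemistry rather than memorizing training strings.
- **Descriptor panels** (`compute_descriptors()`): a 10-descriptor
  physicochemical panel (ring counts, logP, molecular weight, H-bond
  donors/acceptors, heteroatoms, TPSA, rotatable bonds, valence
  electrons) for distribution comparisons, and a 27-descriptor panel for
  annotation.
- **Chemical-space maps** (`embed_chemical_space()`, `density_grid()`):
  descriptors are standardized, embedded to 2-D by t-SNE with PCA
  initialization under a fixed seed, and counted on a 50×50 grid;
  `plot_density_map()` renders the density.

## 7. Synthetic fixtures as study material

At desk scale the package supplies its own study material:
`generate_corpus()` assembles molecules from curated building blocks
(sugar rings, phenols, lactones and polyketide units for the NP-like
pool; aryl, amide, sulfonamide and heteroaryl units for the druglike
pool), each 10–60 heavy atoms, unique by canonical SMILES, and valid by
construction. A corruption plan plants defects with known ground truth —
unparseable strings, duplicate rewritings, salts, isotopes, charges,
stereocentres, and severe valence defects — and the manifest records the
fate the curation cascade must assign to each record. This is what makes
exact, oracle-based testing of the curator possible.

One corruption deserves a note: RDKit-style toolkits reject valence
violations on organic atoms at parse time, so a "severe valence" fixture
is built instead around a hypervalent exotic-metal bracket atom, which
parses but fires the severity-7 unsupported-element rule — the fixture
still exercises the checker rather than the parser.

## 8. Reproducibility and limitations

Every stochastic stage is seeded, and `run_pipeline()` derives each
stage's seed from the global seed and the stage name, so stages can be
re-run in isolation. `scripts/acceptance.R` runs the full scaled-down
pipeline against the installed package and writes all computed quantities
as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

Limitations to keep in mind:

- The desk-scale model is a 1×64 LSTM trained on thousands of strings; it
  demonstrates the workflow's behaviour, not the capability of the
  full-scale 3×512 model trained on hundreds of thousands of natural
  products.
- Held-out recovery at desk scale is a few percent; the full-scale
  counterpart (37%) requires sampling many millions of strings.
- Chemistry (parsing, canonicalization, InChI, descriptors, enumeration,
  standardization) is delegated to a bundled Python helper script run
  through a batch interface; a Python interpreter with RDKit must be on
  the PATH (`NPGEN_PYTHON` overrides the interpreter).
- The NP-likeness score table needs a reference corpus; inside a
  single-corpus pipeline run the curated generated set stands in as the
  reference unless `reference_corpus` is supplied.
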