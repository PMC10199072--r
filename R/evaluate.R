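panel10_names <- function() {
  c(n_aromatic_rings = "NumAromaticRings",
    n_aliphatic_rings = "NumAliphaticRings",
    logp = "MolLogP",
    molecular_weight = "MolWt",
    n_h_acceptors = "NumHAcceptors",
    n_h_donors = "NumHDonors",
    n_heteroatoms = "NumHeteroatoms",
    tpsa = "TPSA",
    n_rotatable_bonds = "NumRotatableBonds",
    n_valence_electrons = "NumValenceElectrons")
}

#' Compute molecular descriptor panels
#'
#' `panel10` is the physicochemical panel used for chemical-space
#' comparison: aromatic/aliphatic ring counts, Wildman-Crippen logP,
#' molecular weight (g/mol), H-bond acceptor/donor counts, heteroatom
#' count, TPSA (A^2), rotatable-bond count and valence-electron count.
#' `panel27` is the wider 27-descriptor annotation panel (columns keep
#' their toolkit names, e.g. `BalabanJ`, `BertzCT`, `FractionCSP3`).
#' Deterministic and invariant to the SMILES writing of a molecule.
#'
#' @param smiles Character vector of parseable SMILES.
#' @param panel `"panel10"` (default) or `"panel27"`.
#' @return A tibble with a `smiles` column plus one column per descriptor.
#' @export
compute_descriptors <- function(smiles, panel = c("panel10", "panel27")) {
  panel <- match.arg(panel)
  assert_smiles_strings(smiles)
  out <- chem_backend("descriptors", smiles, args = c("--panel", panel))
  if (any(out[[2]] == "")) abort("compute_descriptors requires parseable SMILES")
  vals <- lapply(out[-1], as.numeric)
  if (panel == "panel10") {
    names(vals) <- names(panel10_names())[match(names(vals), panel10_names())]
  }
  dplyr::bind_cols(tibble(smiles = smiles), as_tibble(vals))
}

#' Build a reference/candidate distribution pair over a common support
#'
#' Continuous values are binned on a shared grid of width `bin_width`
#' anchored at 0 (bin `k` covers `[k*w, (k+1)*w)`); categorical values
#' (character/factor inputs) are mapped over the union of observed labels,
#' `"none"` being an ordinary first-class label. Both probability vectors
#' are normalized over the union support.
#'
#' @param values_ref Reference sample (numeric, or character for
#'   categorical data): the distribution `P`.
#' @param values_cand Candidate sample: the distribution `Q`.
#' @param bin_width Bin width for continuous values (default 0.1).
#' @return An object of class `npgen_distribution_pair`: tibble with
#'   columns `support`, `count_ref`, `count_cand`, `P`, `Q`.
#' @export
make_distribution <- function(values_ref, values_cand, bin_width = 0.1) {
  if (length(values_ref) == 0 || length(values_cand) == 0) {
    abort("both value sets must be non-empty")
  }
  categorical <- is.character(values_ref) || is.factor(values_ref)
  if (categorical) {
    values_ref <- as.character(values_ref)
    values_cand <- as.character(values_cand)
    support <- sort(union(unique(values_ref), unique(values_cand)))
    key_ref <- values_ref
    key_cand <- values_cand
  } else {
    bin_of <- function(x) as.integer(floor(x / bin_width + 1e-9))
    key_ref <- bin_of(values_ref)
    key_cand <- bin_of(values_cand)
    support <- sort(union(unique(key_ref), unique(key_cand)))
  }
  count_ref <- as.integer(table(factor(key_ref, levels = support)))
  count_cand <- as.integer(table(factor(key_cand, levels = support)))
  pair <- tibble(
    support = if (categorical) as.character(support) else support,
    count_ref = count_ref,
    count_cand = count_cand,
    P = count_ref / sum(count_ref),
    Q = count_cand / sum(count_cand)
  )
  structure(pair, class = c("npgen_distribution_pair", class(pair)),
            bin_width = if (categorical) NA_real_ else bin_width)
}

#' Construct a distribution pair from explicit probability vectors
#'
#' Mainly for analytic work and testing; [make_distribution()] is the
#' data-driven constructor.
#'
#' @param P,Q Probability vectors over the same support (must each sum
#'   to 1 within 1e-9).
#' @param support Optional support labels.
#' @return An `npgen_distribution_pair`.
#' @export
new_distribution_pair <- function(P, Q, support = seq_along(P)) {
  stopifnot(length(P) == length(Q), all(P >= 0), all(Q >= 0))
  if (abs(sum(P) - 1) > 1e-9 || abs(sum(Q) - 1) > 1e-9) {
    abort("P and Q must each sum to 1")
  }
  pair <- tibble(support = support, count_ref = NA_integer_,
                 count_cand = NA_integer_, P = P, Q = Q)
  structure(pair, class = c("npgen_distribution_pair", class(pair)),
            bin_width = NA_real_)
}

#' Kullback-Leibler divergence of a distribution pair (nats)
#'
#' `D(P || Q) = sum over x with P(x) > 0 of P(x) * ln(P(x) / Q(x))`.
#' The formula is undefined when some bin has `P(x) > 0` but `Q(x) = 0`;
#' in that case one pseudo-count is added to every candidate bin within
#' P's support and Q is renormalized before summation (documented
#' smoothing; it requires the pair to carry counts). `D >= 0`, and
#' `D(P || P) = 0`.
#'
#' @param pair An `npgen_distribution_pair`.
#' @return KL divergence in nats.
#' @export
kl_divergence <- function(pair) {
  stopifnot(inherits(pair, "npgen_distribution_pair"))
  P <- pair$P
  Q <- pair$Q
  sup <- P > 0
  if (any(Q[sup] == 0)) {
    if (anyNA(pair$count_cand)) {
      abort("Q is zero inside P's support and the pair carries no counts to smooth")
    }
    counts <- pair$count_cand
    counts[sup] <- counts[sup] + 1L
    Q <- counts / sum(counts)
  }
  sum(P[sup] * log(P[sup] / Q[sup]))
}

#' Fraction of a held-out set recovered among generated molecules
#'
#' Both inputs must be canonical, stereo-free SMILES; the rate is
#' `|generated intersect heldout| / |heldout|`.
#'
#' @param generated Character vector (or set) of generated canonical SMILES.
#' @param heldout Character vector of held-out canonical SMILES (non-empty).
#' @return A number in \[0, 1\].
#' @export
recovery_rate <- function(generated, heldout) {
  if (length(heldout) == 0) abort("held-out set must be non-empty")
  length(intersect(unique(generated), unique(heldout))) / length(unique(heldout))
}

#' Embed a descriptor matrix into 2-D chemical space
#'
#' Columns are standardized to zero mean and unit variance (constant
#' columns are dropped with a warning), the embedding is initialized from
#' the first two principal components, and t-SNE (Barnes-Hut) projects the
#' panel to 2-D under a fixed seed, mirroring the settings used for
#' full-scale chemical-space maps (2 components, PCA init, random state 7).
#'
#' @param descriptors A data frame of numeric descriptor columns (a
#'   `smiles` column, if present, is carried through unchanged).
#' @param perplexity t-SNE perplexity (default 30; the input must have at
#'   least `3 * perplexity + 2` rows).
#' @param seed Random state (default 7).
#' @return A tibble with `tsne1`, `tsne2` (plus `smiles` when supplied);
#'   attribute `"params"` records the settings.
#' @export
embed_chemical_space <- function(descriptors, perplexity = 30, seed = 7) {
  stopifnot(is.data.frame(descriptors))
  smiles <- descriptors[["smiles"]]
  mat <- as.matrix(descriptors[setdiff(names(descriptors), "smiles")])
  storage.mode(mat) <- "double"
  if (nrow(mat) < 3 * perplexity + 2) {
    abort("too few rows for the requested perplexity")
  }
  sds <- apply(mat, 2, stats::sd)
  if (any(sds == 0)) {
    warn(paste("dropping constant descriptor column(s):",
               paste(colnames(mat)[sds == 0], collapse = ", ")))
    mat <- mat[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  mat <- scale(mat)
  pca_init <- stats::prcomp(mat, rank. = 2)$x
  pca_init <- pca_init / stats::sd(pca_init[, 1]) * 1e-4
  coords <- withr::with_seed(seed, {
    Rtsne::Rtsne(mat, dims = 2, perplexity = perplexity,
                 Y_init = pca_init, pca = FALSE,
                 check_duplicates = FALSE, verbose = FALSE)$Y
  })
  out <- tibble(tsne1 = coords[, 1], tsne2 = coords[, 2])
  if (!is.null(smiles)) out <- dplyr::bind_cols(tibble(smiles = smiles), out)
  structure(out, params = list(n_components = 2, init = "pca",
                               random_state = seed, perplexity = perplexity))
}

#' Count embedded points on a square density grid
#'
#' @param embedding A tibble with `tsne1`, `tsne2` (from
#'   [embed_chemical_space()]).
#' @param bins Number of bins per axis (default 50, spanning the bounding
#'   box of the embedding).
#' @return A tibble `xbin`, `ybin`, `x`, `y`, `count`; counts sum to the
#'   number of embedded points.
#' @export
density_grid <- function(embedding, bins = 50) {
  stopifnot(all(c("tsne1", "tsne2") %in% names(embedding)))
  cut_axis <- function(v) {
    brk <- seq(min(v), max(v), length.out = bins + 1)
    idx <- findInterval(v, brk, rightmost.closed = TRUE, all.inside = TRUE)
    list(idx = idx, mid = (brk[-1] + brk[-length(brk)]) / 2)
  }
  cx <- cut_axis(embedding$tsne1)
  cy <- cut_axis(embedding$tsne2)
  counts <- table(factor(cx$idx, levels = seq_len(bins)),
                  factor(cy$idx, levels = seq_len(bins)))
  grid <- expand.grid(xbin = seq_len(bins), ybin = seq_len(bins))
  tibble(
    xbin = grid$xbin, ybin = grid$ybin,
    x = cx$mid[grid$xbin], y = cy$mid[grid$ybin],
    count = as.integer(counts[cbind(grid$xbin, grid$ybin)])
  )
}
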