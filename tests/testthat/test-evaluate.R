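test_that("panel10 descriptors take hand-checkable values on small molecules", {
  d <- compute_descriptors(c("c1ccccc1", "CCO"))
  benzene <- d[1, ]
  expect_equal(benzene$n_aromatic_rings, 1)
  expect_equal(benzene$n_aliphatic_rings, 0)
  expect_equal(benzene$n_heteroatoms, 0)
  expect_equal(benzene$n_valence_electrons, 30)
  expect_equal(benzene$molecular_weight, 78.114, tolerance = 1e-3)
  ethanol <- d[2, ]
  expect_equal(ethanol$n_h_donors, 1)
  expect_equal(ethanol$n_h_acceptors, 1)
  expect_equal(ethanol$tpsa, 20.23, tolerance = 1e-6)
  expect_equal(ethanol$n_rotatable_bonds, 0)
})

test_that("panel27 returns 27 descriptor columns, writing-invariantly", {
  d1 <- compute_descriptors("CC(=O)Oc1ccccc1C(=O)O", panel = "panel27")
  d2 <- compute_descriptors("OC(=O)c1ccccc1OC(C)=O", panel = "panel27")
  expect_equal(ncol(d1), 28L)  # smiles + 27 descriptors
  expect_equal(d1[-1], d2[-1], tolerance = 1e-12)
})

test_that("make_distribution bins continuous data on a shared grid", {
  pair <- make_distribution(c(0.05, 0.15, 0.15, 0.95), c(0.05, 0.25),
                            bin_width = 0.1)
  expect_equal(pair$support, c(0L, 1L, 2L, 9L))
  expect_equal(pair$count_ref, c(1L, 2L, 0L, 1L))
  expect_equal(pair$count_cand, c(1L, 0L, 1L, 0L))
  expect_equal(sum(pair$P), 1)
  expect_equal(sum(pair$Q), 1)
})

test_that("make_distribution treats categorical labels incl. 'none'", {
  pair <- make_distribution(c("a", "b", "none", "none"), c("a", "c"))
  expect_setequal(pair$support, c("a", "b", "c", "none"))
  expect_equal(pair$P[pair$support == "none"], 0.5)
  expect_equal(pair$Q[pair$support == "c"], 0.5)
})

test_that("kl_divergence matches direct summation to 1e-12", {
  P <- c(0.5, 0.3, 0.2)
  Q <- c(0.25, 0.25, 0.5)
  pair <- new_distribution_pair(P, Q)
  expect_equal(kl_divergence(pair), sum(P * log(P / Q)), tolerance = 1e-12)
  expect_identical(kl_divergence(new_distribution_pair(P, P)), 0)
})

test_that("kl_divergence is non-negative over 1000 random pairs", {
  set.seed(99)
  for (i in seq_len(1000)) {
    k <- sample(2:12, 1)
    P <- stats::runif(k); P <- P / sum(P)
    Q <- stats::runif(k); Q <- Q / sum(Q)
    expect_gte(kl_divergence(new_distribution_pair(P, Q)), 0)
  }
})

test_that("zero-Q bins inside P's support trigger count smoothing", {
  pair <- make_distribution(c(0.05, 0.15, 0.95), c(0.05, 0.15),
                            bin_width = 0.1)
  # bin 9 has P > 0 but Q = 0: one pseudo-count per support bin of P
  counts <- pair$count_cand
  counts[pair$P > 0] <- counts[pair$P > 0] + 1L
  Qs <- counts / sum(counts)
  sup <- pair$P > 0
  expect_equal(kl_divergence(pair), sum(pair$P[sup] * log(pair$P[sup] / Qs[sup])),
               tolerance = 1e-12)
  # without counts the same situation is an error
  bad <- new_distribution_pair(c(0.5, 0.5), c(1, 0))
  expect_error(kl_divergence(bad), "counts")
})

test_that("recovery_rate counts held-out molecules found among generated", {
  heldout <- c("CCO", "CCN", "CCC", "CCCC")
  generated <- c("CCO", "CCO", "CCC", "c1ccccc1")
  expect_equal(recovery_rate(generated, heldout), 0.5)
  expect_equal(recovery_rate(character(0), heldout), 0)
  expect_error(recovery_rate(generated, character(0)), "non-empty")
})

test_that("chemical-space embedding is seeded and shaped correctly", {
  corpus <- c(np_fixture_smiles(), druglike_fixture_smiles())
  desc <- compute_descriptors(corpus)
  emb1 <- embed_chemical_space(desc, perplexity = 10, seed = 7)
  emb2 <- embed_chemical_space(desc, perplexity = 10, seed = 7)
  expect_equal(nrow(emb1), length(corpus))
  expect_named(emb1, c("smiles", "tsne1", "tsne2"))
  expect_identical(emb1$tsne1, emb2$tsne1)
  expect_equal(attr(emb1, "params")$n_components, 2)
})

test_that("density_grid conserves the number of embedded points", {
  set.seed(1)
  emb <- tibble::tibble(tsne1 = stats::rnorm(500), tsne2 = stats::rnorm(500))
  grid <- density_grid(emb, bins = 50)
  expect_equal(nrow(grid), 2500L)
  expect_equal(sum(grid$count), 500L)
})
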